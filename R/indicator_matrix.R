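#' Construct a region-by-indicator rate matrix
#'
#' The central input container: a numeric grid with one row per region and one
#' column per schema indicator, holding nonnegative finite rates expressed per
#' 1,000 population. Construction validates shape, region names and cell
#' values; downstream scoring assumes a validated matrix.
#'
#' @param values Numeric matrix (or coercible) of rates per 1,000, regions in
#'   rows, indicators in columns (schema order).
#' @param schema An [indicator_schema()] (or path / plain data frame).
#' @param regions Character vector of unique region names; defaults to the
#'   rownames of `values`.
#' @return An object of class `indicator_matrix` with elements `values`
#'   (named numeric matrix) and `schema`.
#' @export
indicator_matrix <- function(values, schema, regions = rownames(values)) {
  schema <- as_indicator_schema(schema)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("indicator values must be numeric", call. = FALSE)
  }
  if (ncol(values) != nrow(schema)) {
    stop("matrix has ", ncol(values), " columns but schema declares ",
         nrow(schema), " indicators", call. = FALSE)
  }
  if (is.null(regions)) {
    stop("region names are required (rownames or 'regions')", call. = FALSE)
  }
  regions <- trimws(as.character(regions))
  if (length(regions) != nrow(values)) {
    stop("length of 'regions' must equal the number of rows", call. = FALSE)
  }
  if (any(!nzchar(regions))) stop("region names must be nonempty", call. = FALSE)
  if (anyDuplicated(regions)) {
    dup <- unique(regions[duplicated(regions)])
    stop("duplicate region name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid cell value(s) (must be finite and >= 0): ",
         format_cells(regions[bad[, 1L]], schema$id[bad[, 2L]]), call. = FALSE)
  }
  dimnames(values) <- list(regions, schema$id)
  structure(list(values = values, schema = schema), class = "indicator_matrix")
}

format_cells <- function(regions, indicators, max_show = 5L) {
  cells <- paste0("(", regions, ", ", indicators, ")")
  if (length(cells) > max_show) {
    cells <- c(cells[seq_len(max_show)],
               paste0("... and ", length(cells) - max_show, " more"))
  }
  paste(cells, collapse = ", ")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  tab <- table(factor(x$schema$cluster, levels = indicator_clusters()))
  cat("indicator_matrix: ", nrow(x$values), " regions x ",
      ncol(x$values), " indicators (", paste(tab, collapse = "/"),
      " per cluster), rates per 1,000 population\n", sep = "")
  invisible(x)
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

#' Read a region-by-indicator table from delimited text
#'
#' The table must be UTF-8 delimited text (comma or tab, auto-detected from
#' the header) whose first column is `region`, followed by one column per
#' schema indicator id. All rates are re-expressed per 1,000 persons: a column
#' whose schema denominator is 10,000 is divided by 10 on read.
#'
#' @param path Path to the delimited table.
#' @param schema An [indicator_schema()], a schema file path, or a plain data
#'   frame with the schema columns.
#' @param missing `"error"` (default, strict): any blank/NA cell aborts with
#'   the offending (region, indicator). `"impute_min"` (permissive): missing
#'   cells take the indicator's observed minimum -- the conservative
#'   "negative condition" reading -- with a warning.
#' @return A validated [indicator_matrix()].
#' @export
read_indicator_table <- function(path, schema,
                                 missing = c("error", "impute_min")) {
  missing <- match.arg(missing)
  schema <- as_indicator_schema(schema)
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- read_delim_auto(path, as_character = TRUE)
  if (ncol(df) < 2L || tolower(trimws(names(df)[1L])) != "region") {
    stop("first column of the table must be 'region'", call. = FALSE)
  }
  regions <- trimws(df[[1L]])
  if (any(!nzchar(regions))) stop("empty region name in table", call. = FALSE)
  if (anyDuplicated(regions)) {
    dup <- unique(regions[duplicated(regions)])
    stop("duplicate region name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cols <- trimws(names(df)[-1L])
  unknown <- setdiff(cols, schema$id)
  if (length(unknown)) {
    stop("table column(s) not declared in the schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(schema$id, cols)
  if (length(absent)) {
    stop("schema indicator(s) missing from the table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- length(regions)
  values <- matrix(NA_real_, n, nrow(schema),
                   dimnames = list(regions, schema$id))
  for (j in seq_len(nrow(schema))) {
    id <- schema$id[j]
    raw <- trimws(df[[which(cols == id) + 1L]])
    num <- suppressWarnings(as.numeric(raw))
    nonnum <- which(nzchar(raw) & !(raw %in% c("NA", "na")) & is.na(num))
    if (length(nonnum)) {
      stop("non-numeric cell(s): ", format_cells(regions[nonnum], rep(id, length(nonnum))),
           call. = FALSE)
    }
    miss <- which(is.na(num))
    if (length(miss)) {
      if (missing == "error") {
        stop("missing cell(s): ", format_cells(regions[miss], rep(id, length(miss))),
             call. = FALSE)
      }
      if (length(miss) == n) {
        stop("indicator '", id, "' has no observed values to impute from",
             call. = FALSE)
      }
      num[miss] <- min(num, na.rm = TRUE)
      warning("imputed observed minimum for ",
              format_cells(regions[miss], rep(id, length(miss))), call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop("negative cell(s): ", format_cells(regions[neg], rep(id, length(neg))),
           call. = FALSE)
    }
    values[, j] <- num * 1000 / schema$denominator[j]
  }
  # values are now per 1,000; record that in the schema carried forward
  schema$denominator <- rep(1000, nrow(schema))
  indicator_matrix(values, schema, regions = regions)
}

#' Write an indicator matrix to delimited text
#'
#' Writes per-1,000 rates with a `region` first column, tab-separated by
#' default. Values are formatted so that re-reading reproduces the doubles
#' exactly and preserves region and indicator order.
#'
#' @param x An [indicator_matrix()].
#' @param path Output path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "indicator_matrix"))
  fmt <- matrix(sprintf("%.17g", x$values), nrow(x$values), ncol(x$values))
  out <- cbind(region = rownames(x$values), as.data.frame(fmt))
  names(out) <- c("region", colnames(x$values))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert raw facility/staff counts to rates per 1,000 population
#'
#' @param counts Numeric matrix of raw counts, regions in rows, indicators in
#'   columns (schema order).
#' @param population Positive per-region population counts, in row order (or
#'   named by region when `counts` has rownames).
#' @param schema An [indicator_schema()].
#' @return An [indicator_matrix()] with `value = count * 1000 / population`.
#' @export
normalize_counts <- function(counts, population, schema) {
  counts <- as.matrix(counts)
  schema <- as_indicator_schema(schema)
  regions <- rownames(counts)
  if (!is.null(names(population)) && !is.null(regions)) {
    if (!all(regions %in% names(population))) {
      stop("population is missing region(s): ",
           paste(setdiff(regions, names(population)), collapse = ", "),
           call. = FALSE)
    }
    population <- population[regions]
  }
  if (length(population) != nrow(counts)) {
    stop("need one population count per region", call. = FALSE)
  }
  bad <- which(!is.finite(population) | population <= 0)
  if (length(bad)) {
    lab <- if (is.null(regions)) paste("row", bad) else regions[bad]
    stop("population must be > 0; offending region(s): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  values <- sweep(counts * 1000, 1L, population, `/`)
  schema$denominator <- rep(1000, nrow(schema))
  indicator_matrix(values, schema,
                   regions = regions %||% sprintf("region_%02d", seq_len(nrow(counts))))
}
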