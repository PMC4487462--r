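#' Allowed indicator clusters and orientations
#'
#' The scalogram groups structural indicators into three clusters:
#' `institutional` (facilities: treatment centres, beds, pharmacies, ...),
#' `human_resource` (specialist and general staff densities) and
#' `rural_institutional` (rural health houses and centres, village coverage).
#'
#' @return Character vector of allowed values.
#' @export
indicator_clusters <- function() {
  c("institutional", "human_resource", "rural_institutional")
}

#' @rdname indicator_clusters
#' @export
indicator_orientations <- function() {
  c("higher_is_better", "higher_is_worse")
}

#' Build an indicator schema
#'
#' An indicator schema declares, for every indicator column of a region table:
#' a unique `id`, a human-readable `label`, the `cluster` it belongs to, the
#' `denominator` its rate is expressed per (persons; e.g. 1000 or 10000 --
#' all values are re-expressed per 1,000 on read), and its `orientation`
#' (resource densities are `higher_is_better`; adverse indicators may be
#' declared `higher_is_worse` and are scored reversed).
#'
#' @param id Character vector of unique, nonempty indicator keys.
#' @param label Human-readable names (defaults to `id`).
#' @param cluster One of [indicator_clusters()] per indicator.
#' @param denominator Positive population denominator per indicator
#'   (default 1000).
#' @param orientation One of [indicator_orientations()] per indicator.
#' @return A data frame of class `indicator_schema`.
#' @examples
#' indicator_schema(
#'   id = c("pharmacy", "internist"),
#'   cluster = c("institutional", "human_resource")
#' )
#' @export
indicator_schema <- function(id, label = id,
                             cluster,
                             denominator = 1000,
                             orientation = "higher_is_better") {
  schema <- data.frame(
    id = as.character(id),
    label = as.character(label),
    cluster = as.character(cluster),
    denominator = as.numeric(denominator),
    orientation = as.character(orientation),
    stringsAsFactors = FALSE
  )
  validate_indicator_schema(schema)
}

#' Validate an indicator schema
#'
#' @param schema A data frame with columns `id`, `label`, `cluster`,
#'   `denominator`, `orientation` (missing `label`/`denominator`/`orientation`
#'   are filled with defaults).
#' @return The validated schema, classed `indicator_schema`.
#' @export
validate_indicator_schema <- function(schema) {
  if (!is.data.frame(schema) || nrow(schema) < 1L) {
    stop("schema must be a data frame with at least one indicator", call. = FALSE)
  }
  if (is.null(schema$id)) stop("schema must have an 'id' column", call. = FALSE)
  schema$id <- trimws(as.character(schema$id))
  if (any(!nzchar(schema$id))) stop("indicator ids must be nonempty", call. = FALSE)
  if (anyDuplicated(schema$id)) {
    dup <- unique(schema$id[duplicated(schema$id)])
    stop("duplicate indicator id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  schema$label <- as.character(schema$label %||% schema$id)
  schema$label[is.na(schema$label) | !nzchar(schema$label)] <-
    schema$id[is.na(schema$label) | !nzchar(schema$label)]
  if (is.null(schema$cluster)) stop("schema must declare a cluster per indicator", call. = FALSE)
  schema$cluster <- as.character(schema$cluster)
  bad <- setdiff(unique(schema$cluster), indicator_clusters())
  if (length(bad)) {
    stop("unknown cluster(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(indicator_clusters(), collapse = ", "), ")",
         call. = FALSE)
  }
  schema$denominator <- as.numeric(schema$denominator %||% 1000)
  schema$denominator[is.na(schema$denominator)] <- 1000
  if (any(!is.finite(schema$denominator) | schema$denominator <= 0)) {
    stop("denominator must be a positive finite number for every indicator",
         call. = FALSE)
  }
  schema$orientation <- as.character(schema$orientation %||% "higher_is_better")
  schema$orientation[is.na(schema$orientation) | !nzchar(schema$orientation)] <-
    "higher_is_better"
  bad <- setdiff(unique(schema$orientation), indicator_orientations())
  if (length(bad)) {
    stop("unknown orientation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  schema <- schema[, c("id", "label", "cluster", "denominator", "orientation")]
  rownames(schema) <- NULL
  class(schema) <- c("indicator_schema", "data.frame")
  schema
}

#' Read an indicator schema from a config file
#'
#' Accepts YAML (either a top-level list of indicator entries, or a mapping
#' with an `indicators:` list) or delimited text (comma or tab, auto-detected)
#' with one row per indicator. Fields: `id` (required), `cluster` (required),
#' `label`, `denominator`, `orientation` (optional, defaulted).
#'
#' @param path Path to the schema file.
#' @return An `indicator_schema`.
#' @export
read_indicator_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$indicators)) raw <- raw$indicators
    if (!is.list(raw) || length(raw) == 0L) {
      stop("schema YAML must contain a list of indicator entries", call. = FALSE)
    }
    rows <- lapply(raw, function(e) {
      if (is.null(e$id)) stop("schema entry without an 'id' field", call. = FALSE)
      data.frame(
        id = as.character(e$id),
        label = as.character(e$label %||% e$id),
        cluster = as.character(e$cluster %||% NA_character_),
        denominator = as.numeric(e$denominator %||% 1000),
        orientation = as.character(e$orientation %||% "higher_is_better"),
        stringsAsFactors = FALSE
      )
    })
    schema <- do.call(rbind, rows)
  } else {
    schema <- read_delim_auto(path)
  }
  validate_indicator_schema(schema)
}

as_indicator_schema <- function(x) {
  if (inherits(x, "indicator_schema")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_indicator_schema(x))
  validate_indicator_schema(x)
}

# delimited reader shared by schema and table io: comma or tab, sniffed from
# the header line; cells kept as character so validation can name offenders
read_delim_auto <- function(path, as_character = FALSE) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(
    path, header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE,
    comment.char = "", fileEncoding = "UTF-8",
    colClasses = if (as_character) "character" else NA
  )
}
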