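#' Write ranked-region and tier-summary reports
#'
#' Emits three files into `dir`:
#' * `regions.tsv` -- one row per region, sorted by rank: `rank`, `region`,
#'   one column per cluster score, `total`, `tier`.
#' * `tiers.tsv` -- one row per tier, highest development first: `tier`,
#'   `count`, `percent` (2 decimals), `members`, `interval` (exact half-open)
#'   and `interval_display` (published-table style, upper bound shown as the
#'   next lower bound minus one reporting unit).
#' * `metadata.json` -- run metadata: binning, Sturges parameters, score
#'   range, seed, and an MD5 digest of the input rate matrix. No timestamps,
#'   so identical inputs give byte-identical reports.
#'
#' @param result A [scalogram_rank()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "scalogram_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  cls <- result$classification
  regions <- cls$regions
  cluster_cols <- setdiff(names(regions), c("region", "total", "tier", "rank"))
  reg_out <- regions[, c("rank", "region", cluster_cols, "total", "tier")]
  reg_out$tier <- as.character(reg_out$tier)
  regions_path <- file.path(dir, "regions.tsv")
  utils::write.table(reg_out, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  tiers_path <- file.path(dir, "tiers.tsv")
  tiers_out <- cls$summary
  tiers_out$percent <- sprintf("%.2f", tiers_out$percent)
  utils::write.table(tiers_out, tiers_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  scheme <- result$scheme
  meta <- list(
    binning = result$binning,
    n_regions = nrow(regions),
    n_indicators = nrow(result$matrix$schema),
    sturges = list(N = scheme$n_items, R = scheme$score_max - scheme$score_min,
                   width = scheme$width, step = scheme$step),
    score_range = c(scheme$score_min, scheme$score_max),
    lower_bounds = scheme$lower_bounds,
    tier_labels = scheme$labels,
    theoretical_bounds = as.list(attr(result$aggregates, "bounds")),
    seed = result$seed,
    input_digest = matrix_digest(result$matrix$values)
  )
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(regions = regions_path, tiers = tiers_path,
              metadata = meta_path))
}

# content digest of a numeric matrix: md5 of its full-precision text form,
# including dimnames, so reordered or renamed inputs digest differently
matrix_digest <- function(values) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  txt <- c(paste(rownames(values), collapse = "\t"),
           paste(colnames(values), collapse = "\t"),
           apply(values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a regions report back into a data frame
#'
#' Convenience reader for `regions.tsv` as written by [write_report()].
#'
#' @param path Path to a `regions.tsv` file.
#' @return Data frame with the report's columns.
#' @export
read_regions_report <- function(path) {
  read_delim_auto(path)
}
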