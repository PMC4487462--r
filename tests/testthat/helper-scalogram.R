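# Shared fixtures and independent oracles for the test suite.

# a small three-cluster schema built in code
make_schema <- function(n_inst = 2L, n_hum = 2L, n_rural = 1L,
                        denominator = 1000, orientation = "higher_is_better") {
  n <- n_inst + n_hum + n_rural
  indicator_schema(
    id = sprintf("ind_%02d", seq_len(n)),
    cluster = rep(indicator_clusters(), times = c(n_inst, n_hum, n_rural)),
    denominator = denominator,
    orientation = orientation
  )
}

make_matrix <- function(values, schema = NULL,
                        regions = sprintf("reg_%02d", seq_len(nrow(values)))) {
  values <- as.matrix(values)
  if (is.null(schema)) {
    m <- ncol(values)
    schema <- make_schema(n_inst = m - 1L, n_hum = 1L, n_rural = 0L)
    if (m == 1L) schema <- make_schema(n_inst = 1L, n_hum = 0L, n_rural = 0L)
  }
  indicator_matrix(values, schema, regions = regions)
}

write_temp_table <- function(df, sep = ",", ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# exhaustive interval-membership oracle for equal-width 1-4 scoring: for each
# value, test the four explicit sub-intervals of [lo, hi]
oracle_equal_width <- function(values) {
  lo <- min(values)
  hi <- max(values)
  w <- (hi - lo) / 4
  vapply(values, function(v) {
    if (v >= lo && v < lo + w) 1L
    else if (v >= lo + w && v < lo + 2 * w) 2L
    else if (v >= lo + 2 * w && v < lo + 3 * w) 3L
    else if (v >= lo + 3 * w && v <= hi) 4L
    else stop("value outside range")
  }, integer(1))
}

# independent rendering of the Sturges closed form (log via natural log)
oracle_sturges <- function(R, N) R / (1 + 3.3 * (log(N) / log(10)))

# brute-force double-loop summation of a score grid by cluster
oracle_totals <- function(scores, clusters) {
  n <- nrow(scores)
  out <- list(total = numeric(n))
  for (cl in unique(clusters)) out[[cl]] <- numeric(n)
  for (r in seq_len(n)) {
    for (j in seq_len(ncol(scores))) {
      out$total[r] <- out$total[r] + scores[r, j]
      out[[clusters[j]]][r] <- out[[clusters[j]]][r] + scores[r, j]
    }
  }
  out
}

# competition ranking oracle: 1 + number of strictly greater totals
oracle_competition_rank <- function(totals) {
  vapply(totals, function(t) 1L + sum(totals > t), integer(1))
}
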