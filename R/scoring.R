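#' Score one indicator's rates ordinally from 1 to 4
#'
#' Maps a vector of per-region rates to ordinal scores in \{1, 2, 3, 4\}
#' (4 = positive condition, 1 = negative condition). Two binning rules:
#'
#' * `equal_width` (default): the observed \[min, max\] range is split into
#'   four equal sub-intervals; bins are half-open \[low, high) with the top
#'   bin closed, so every value falls in exactly one bin. A value in bin
#'   \eqn{k} from the low end scores \eqn{k} when `higher_is_better`,
#'   \eqn{5 - k} when `higher_is_worse`.
#' * `quartile`: empirical quartile classes -- values \eqn{\le Q_1} score 1,
#'   \eqn{\le Q_2} score 2, \eqn{\le Q_3} score 3, above \eqn{Q_3} score 4
#'   (orientation-adjusted). Quartiles use [stats::quantile()] type 7.
#'
#' A constant column (zero observed range) cannot discriminate regions and
#' scores 4 everywhere, with a warning, so that a non-informative indicator
#' penalises nobody.
#'
#' @param values Numeric vector of finite, nonnegative rates, one per region.
#' @param orientation `"higher_is_better"` (default) or `"higher_is_worse"`.
#' @param binning `"equal_width"` or `"quartile"`.
#' @return Integer vector of scores in \{1, 2, 3, 4\}.
#' @examples
#' score_indicator(c(0, 10, 20, 30)) # 1 2 3 4
#' @export
score_indicator <- function(values,
                            orientation = c("higher_is_better", "higher_is_worse"),
                            binning = c("equal_width", "quartile")) {
  orientation <- match.arg(orientation)
  binning <- match.arg(binning)
  if (length(values) < 1L) stop("at least one value is required", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    warning("constant indicator (zero observed range): all regions scored 4",
            call. = FALSE)
    return(rep(4L, length(values)))
  }
  if (binning == "equal_width") {
    edges <- lo + (0:4) / 4 * (hi - lo)
    edges[5L] <- hi # guard against floating-point drift at the top edge
    k <- findInterval(values, edges, rightmost.closed = TRUE)
  } else {
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    k <- 1L + (values > qs[1L]) + (values > qs[2L]) + (values > qs[3L])
  }
  k <- as.integer(k)
  if (orientation == "higher_is_worse") k <- 5L - k
  k
}

#' Score every indicator of a rate matrix
#'
#' Applies [score_indicator()] independently to each indicator column, using
#' each indicator's schema orientation.
#'
#' @param x A validated [indicator_matrix()].
#' @param binning Passed to [score_indicator()].
#' @return An object of class `score_matrix`: integer grid `scores` (same
#'   shape and dimnames as the input), the `schema`, and the `binning` used.
#' @export
score_matrix <- function(x, binning = c("equal_width", "quartile")) {
  stopifnot(inherits(x, "indicator_matrix"))
  binning <- match.arg(binning)
  n <- nrow(x$values)
  scores <- vapply(
    seq_len(ncol(x$values)),
    function(j) score_indicator(x$values[, j], x$schema$orientation[j], binning),
    integer(n)
  )
  scores <- matrix(as.integer(scores), nrow = n,
                   dimnames = dimnames(x$values))
  structure(list(scores = scores, schema = x$schema, binning = binning),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix: ", nrow(x$scores), " regions x ", ncol(x$scores),
      " indicators, scores 1-4, binning = ", x$binning, "\n", sep = "")
  invisible(x)
}

#' Aggregate ordinal scores per cluster and in total
#'
#' Sums each region's scores within each indicator cluster and across all
#' indicators. With \eqn{n} indicators the total is bounded by
#' \eqn{[n, 4n]} (e.g. 30 indicators give bounds 30 and 120).
#'
#' @param scores A [score_matrix()].
#' @return A data frame of class `aggregate_scores` with columns `region`,
#'   one integer column per cluster present, and `total`; theoretical bounds
#'   are attached as `attr(, "bounds")`.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  schema <- scores$schema
  clusters <- intersect(indicator_clusters(), unique(schema$cluster))
  out <- data.frame(region = rownames(scores$scores),
                    stringsAsFactors = FALSE)
  for (cl in clusters) {
    out[[cl]] <- as.integer(
      rowSums(scores$scores[, schema$cluster == cl, drop = FALSE])
    )
  }
  out$total <- as.integer(rowSums(scores$scores))
  attr(out, "bounds") <- theoretical_bounds(nrow(schema))
  attr(out, "binning") <- scores$binning
  class(out) <- c("aggregate_scores", "data.frame")
  out
}

#' Theoretical bounds of the composite score
#'
#' With every indicator scored in \{1, 2, 3, 4\}, the composite total of a
#' region with `n_indicators` indicators lies between `n_indicators` (all
#' scores 1) and `4 * n_indicators` (all scores 4).
#'
#' @param n_indicators Positive integer count of scored indicators.
#' @return Named numeric vector `c(min_total, max_total)`.
#' @examples
#' theoretical_bounds(30) # 30 and 120
#' @export
theoretical_bounds <- function(n_indicators) {
  if (length(n_indicators) != 1L || !is.finite(n_indicators) ||
      n_indicators < 1 || n_indicators != round(n_indicators)) {
    stop("n_indicators must be a positive integer", call. = FALSE)
  }
  c(min_total = as.numeric(n_indicators),
    max_total = 4 * as.numeric(n_indicators))
}
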