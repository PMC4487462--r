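#' Run the full scalogram pipeline on a rate matrix
#'
#' One call from validated rates to ranked, tiered regions: scores every
#' indicator 1--4, aggregates per cluster and in total, builds the Sturges
#' five-tier scheme, and classifies and ranks the regions.
#'
#' @param x A validated [indicator_matrix()].
#' @param binning Binning rule, `"equal_width"` (default) or `"quartile"`.
#' @param n_classes Number of development tiers (default 5).
#' @param sturges_n `N` for the Sturges rule; default: the number of regions.
#' @param score_range Length-2 numeric `c(min, max)` endpoints of the class
#'   scheme; default: the observed range of the composite totals. Published
#'   schemes with pinned endpoints can be reproduced by passing them here.
#' @param decimals Reporting precision of class bounds (default 1).
#' @param seed Optional seed recorded in report metadata (the pipeline itself
#'   is deterministic).
#' @return An object of class `scalogram_result` bundling the input matrix,
#'   the score matrix, aggregate scores, the class scheme and the
#'   classification (see [rank_and_summarize()]).
#' @examples
#' sim <- simulate_indicator_matrix(synthetic_config(seed = 7))
#' res <- scalogram_rank(sim$matrix)
#' res$classification$summary
#' @export
scalogram_rank <- function(x,
                           binning = c("equal_width", "quartile"),
                           n_classes = 5L,
                           sturges_n = NULL,
                           score_range = NULL,
                           decimals = 1L,
                           seed = NULL) {
  stopifnot(inherits(x, "indicator_matrix"))
  scores <- score_matrix(x, binning)
  aggregates <- aggregate_scores(scores)
  if (is.null(sturges_n)) sturges_n <- nrow(aggregates)
  if (is.null(score_range)) score_range <- range(aggregates$total)
  scheme <- build_class_scheme(score_range[1L], score_range[2L],
                               n_items = sturges_n, n_classes = n_classes,
                               decimals = decimals)
  classification <- rank_and_summarize(aggregates, scheme)
  structure(
    list(matrix = x, scores = scores, aggregates = aggregates,
         scheme = scheme, classification = classification,
         binning = scores$binning, seed = seed),
    class = "scalogram_result"
  )
}

#' @export
print.scalogram_result <- function(x, ...) {
  cat("scalogram_result (binning = ", x$binning, ")\n", sep = "")
  print(x$classification)
  invisible(x)
}
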