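#' Sturges class-interval width
#'
#' The Sturges rule gives the class-interval width
#' \eqn{i = R / (1 + 3.3 \log_{10} N)}, where \eqn{R} is the amplitude
#' (range) of the scores to be classified and \eqn{N} the number of items
#' classified.
#'
#' @param R Positive score range (max minus min).
#' @param N Integer number of classified items, at least 2.
#' @return The interval width (same units as `R`).
#' @examples
#' sturges_width(56.4, 21) # about 10.52
#' @export
sturges_width <- function(R, N) {
  if (length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("R must be a positive finite number", call. = FALSE)
  }
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N)) {
    stop("N must be an integer >= 2", call. = FALSE)
  }
  R / (1 + 3.3 * log10(N))
}

default_tier_labels <- function() {
  c("under_development", "less_development", "moderate_development",
    "semi_development", "development")
}

#' Build a five-tier development class scheme
#'
#' Divides the score range \[`score_min`, `score_max`\] into `n_classes`
#' ordered development tiers. The interval width comes from the Sturges rule
#' on the range and `n_items`, rounded to `decimals` (the reporting
#' precision); lower bounds step by that rounded width from `score_min`.
#' Intervals are half-open \[low, next low) except the top tier, which is
#' closed at `score_max` and absorbs any remainder when `n_classes` rounded
#' widths fall short of the full range. Accumulating the rounded width keeps
#' the printed bounds and the bounds actually used for assignment identical,
#' so a reported scheme can be reproduced exactly from its table.
#'
#' @param score_min,score_max Endpoints of the score range
#'   (`score_max > score_min`). Observed totals are typical; published
#'   schemes may pin other endpoints.
#' @param n_items `N` entering the Sturges rule, usually the number of
#'   regions classified.
#' @param n_classes Number of tiers (default 5).
#' @param decimals Reporting precision for bounds (default 1).
#' @param labels Tier labels in ascending development order; defaults to
#'   under/less/moderate/semi/development for 5 classes.
#' @return An object of class `class_scheme`: `lower_bounds` (ascending),
#'   `score_min`, `score_max`, exact `width`, rounded `step`, `n_items`,
#'   `n_classes`, `decimals`, `labels`.
#' @examples
#' build_class_scheme(33, 89.4, n_items = 21)$lower_bounds
#' # 33.0 43.5 54.0 64.5 75.0
#' @export
build_class_scheme <- function(score_min, score_max, n_items,
                               n_classes = 5L, decimals = 1L,
                               labels = NULL) {
  if (!is.finite(score_min) || !is.finite(score_max) || score_max <= score_min) {
    stop("score_max must exceed score_min", call. = FALSE)
  }
  if (n_classes < 2L || n_classes != round(n_classes)) {
    stop("n_classes must be an integer >= 2", call. = FALSE)
  }
  width <- sturges_width(score_max - score_min, n_items)
  step <- round(width, decimals)
  # the lowest bound is the range minimum itself; only the stepped bounds
  # are rounded, so the scheme always covers [score_min, score_max]
  lower <- c(score_min,
             round(score_min + seq_len(n_classes - 1L) * step, decimals))
  if (any(diff(lower) <= 0) || lower[n_classes] >= score_max) {
    stop("class bounds do not increase within the score range at ", decimals,
         " decimal(s); increase 'decimals'", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (n_classes == 5L) default_tier_labels()
              else sprintf("class_%d", seq_len(n_classes))
  }
  if (length(labels) != n_classes) {
    stop("need exactly ", n_classes, " labels", call. = FALSE)
  }
  structure(
    list(lower_bounds = lower, score_min = score_min, score_max = score_max,
         width = width, step = step, n_items = as.integer(n_items),
         n_classes = as.integer(n_classes), decimals = as.integer(decimals),
         labels = as.character(labels)),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("class_scheme: ", x$n_classes, " tiers over [",
      format(x$score_min), ", ", format(x$score_max), "], Sturges N = ",
      x$n_items, ", width = ", format(round(x$width, 4)),
      " (step ", format(x$step), ")\n", sep = "")
  iv <- scheme_intervals(x)
  for (k in rev(seq_len(x$n_classes))) {
    cat("  ", format(x$labels[k], width = max(nchar(x$labels))), "  ",
        iv$exact[k], "\n", sep = "")
  }
  invisible(x)
}

# per-element number formatting that drops trailing zeros ("75", "43.5")
fmt_num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, drop0trailing = TRUE),
         character(1))
}

# interval renderings: exact half-open notation, and the display style used
# in published tables (upper bound shown as next lower bound minus one
# reporting unit, top tier as "max-lower")
scheme_intervals <- function(scheme) {
  lb <- scheme$lower_bounds
  n <- scheme$n_classes
  upper_exact <- c(lb[-1L], scheme$score_max)
  unit <- 10^(-scheme$decimals)
  upper_disp <- c(round(lb[-1L] - unit, scheme$decimals), scheme$score_max)
  exact <- sprintf("[%s, %s%s", fmt_num(lb), fmt_num(upper_exact),
                   c(rep(")", n - 1L), "]"))
  display <- sprintf("%s-%s", fmt_num(upper_disp), fmt_num(lb))
  list(exact = exact, display = display,
       lower = lb, upper = upper_exact)
}

#' Assign development tiers to composite scores
#'
#' Each score is placed in the unique scheme interval containing it
#' (half-open \[low, next low), top tier closed at the range maximum).
#' Scores outside \[`score_min`, `score_max`\] are an error.
#'
#' @param total_score Numeric vector of composite scores.
#' @param scheme A [build_class_scheme()] result.
#' @return Ordered factor of tier labels (ascending development order).
#' @export
assign_class <- function(total_score, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (any(!is.finite(total_score))) stop("scores must be finite", call. = FALSE)
  eps <- 1e-9 * max(1, abs(scheme$score_max))
  out <- total_score < scheme$score_min - eps | total_score > scheme$score_max + eps
  if (any(out)) {
    stop("score(s) outside the scheme range [", format(scheme$score_min), ", ",
         format(scheme$score_max), "]: ",
         paste(format(total_score[out], trim = TRUE), collapse = ", "),
         call. = FALSE)
  }
  k <- findInterval(total_score, scheme$lower_bounds)
  k[k < 1L] <- 1L # scores at score_min when it sits below lower_bounds[1] + eps
  factor(scheme$labels[k], levels = scheme$labels, ordered = TRUE)
}

#' Rank regions and summarise tier occupancy
#'
#' Sorts regions by total composite score (descending; ties broken
#' alphabetically for determinism), assigns competition ranks (tied totals
#' share the smaller rank, the next rank is offset by the tie count) and
#' tiers, and tabulates tier occupancy with percentages to 2 decimals.
#'
#' @param aggregates An [aggregate_scores()] data frame (any data frame with
#'   `region` and `total` columns is accepted).
#' @param scheme A [build_class_scheme()] result covering all totals.
#' @return An object of class `scalogram_classification`: `regions` (region,
#'   cluster scores, total, tier, rank, sorted by rank) and `summary` (one
#'   row per tier, highest development first: tier, count, percent, members,
#'   interval, interval_display).
#' @export
rank_and_summarize <- function(aggregates, scheme) {
  stopifnot(is.data.frame(aggregates),
            all(c("region", "total") %in% names(aggregates)),
            inherits(scheme, "class_scheme"))
  if (nrow(aggregates) < 1L) stop("at least one region is required", call. = FALSE)
  regions <- as.data.frame(aggregates)
  regions$tier <- assign_class(regions$total, scheme)
  regions$rank <- as.integer(rank(-regions$total, ties.method = "min"))
  regions <- regions[order(-regions$total, regions$region), , drop = FALSE]
  rownames(regions) <- NULL

  n <- nrow(regions)
  iv <- scheme_intervals(scheme)
  tiers <- rev(scheme$labels) # highest development first, table style
  idx <- match(tiers, scheme$labels)
  counts <- vapply(tiers, function(t) sum(regions$tier == t), integer(1))
  summary <- data.frame(
    tier = tiers,
    count = as.integer(counts),
    percent = round(100 * counts / n, 2),
    members = vapply(tiers, function(t) {
      paste(regions$region[regions$tier == t], collapse = ", ")
    }, character(1)),
    interval = iv$exact[idx],
    interval_display = iv$display[idx],
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(regions = regions, summary = summary, scheme = scheme),
            class = "scalogram_classification")
}

#' @export
print.scalogram_classification <- function(x, ...) {
  cat("scalogram classification of ", nrow(x$regions), " regions into ",
      x$scheme$n_classes, " tiers\n\n", sep = "")
  print(x$summary[, c("tier", "count", "percent", "interval_display")],
        row.names = FALSE)
  top <- x$regions[1L, ]
  bot <- x$regions[nrow(x$regions), ]
  cat("\nhighest: ", top$region, " (", top$total, "); lowest: ",
      bot$region, " (", bot$total, ")\n", sep = "")
  invisible(x)
}
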