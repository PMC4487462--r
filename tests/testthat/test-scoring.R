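test_that("equal-width scoring places one value per bin and handles degenerate columns", {
  expect_equal(score_indicator(c(0, 10, 20, 30)), c(1L, 2L, 3L, 4L))
  expect_warning(s <- score_indicator(c(5, 5, 5, 5)), "constant indicator")
  expect_equal(s, rep(4L, 4))
  # a constant column never penalises, whatever the orientation
  expect_warning(s2 <- score_indicator(rep(2, 3), orientation = "higher_is_worse"))
  expect_equal(s2, rep(4L, 3))
  expect_error(score_indicator(numeric(0)), "at least one")
  expect_error(score_indicator(c(1, NA)), "finite")
  expect_error(score_indicator(c(1, -1)), ">= 0")
})

test_that("equal-width scores match the exhaustive interval-membership oracle", {
  for (seed in c(11, 12, 13, 14, 15)) {
    set.seed(seed)
    v <- runif(8)
    expect_equal(score_indicator(v), oracle_equal_width(v),
                 info = paste("seed", seed))
  }
})

test_that("quartile binning follows the empirical-quartile class rule", {
  set.seed(21)
  v <- rexp(15)
  qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  expected <- 1L + (v > qs[1]) + (v > qs[2]) + (v > qs[3])
  expect_equal(score_indicator(v, binning = "quartile"), as.integer(expected))
  expect_true(all(score_indicator(v, binning = "quartile") %in% 1:4))
})

test_that("flipping orientation maps scores to 5 - s on a non-degenerate column", {
  set.seed(31)
  v <- runif(12, 0, 50)
  s <- score_indicator(v, "higher_is_better")
  expect_equal(score_indicator(v, "higher_is_worse"), 5L - s)
})

test_that("score_matrix applies the single-indicator scorer column by column", {
  set.seed(7)
  vals <- matrix(runif(20), 5, 4)
  sm <- score_matrix(make_matrix(vals))
  expect_equal(dim(sm$scores), dim(vals))
  for (j in 1:4) {
    expect_equal(unname(sm$scores[, j]), oracle_equal_width(vals[, j]))
  }
  expect_true(all(sm$scores %in% 1:4))
})

test_that("a region dominating every indicator attains the maximum total", {
  set.seed(8)
  vals <- matrix(runif(21, 0, 10), 7, 3)
  vals[3, ] <- apply(vals, 2, max) + 1
  agg <- aggregate_scores(score_matrix(make_matrix(vals)))
  expect_equal(which.max(agg$total), 3L)
  expect_equal(agg$total[3], 12L) # 3 indicators, all top bin
})

test_that("raising one cell never lowers that region's score or total", {
  set.seed(9)
  for (rep in 1:20) {
    vals <- matrix(runif(24, 0, 100), 6, 4)
    r <- sample(6, 1)
    j <- sample(4, 1)
    before <- aggregate_scores(score_matrix(make_matrix(vals)))
    s_before <- score_matrix(make_matrix(vals))$scores[r, j]
    vals2 <- vals
    vals2[r, j] <- vals2[r, j] + runif(1, 0, 50)
    after <- aggregate_scores(score_matrix(make_matrix(vals2)))
    s_after <- score_matrix(make_matrix(vals2))$scores[r, j]
    expect_gte(s_after, s_before)
    expect_gte(after$total[r], before$total[r])
  }
})

test_that("permuting region order permutes scores identically", {
  set.seed(10)
  vals <- matrix(runif(18), 6, 3, dimnames = list(paste0("r", 1:6), NULL))
  sm <- score_matrix(make_matrix(vals, regions = rownames(vals)))
  perm <- sample(6)
  sm_p <- score_matrix(make_matrix(vals[perm, ], regions = rownames(vals)[perm]))
  expect_equal(sm_p$scores, sm$scores[perm, ])
})

test_that("aggregation sums per cluster and in total, matching a double-loop oracle", {
  # one region scoring 2 everywhere over clusters of size 8/19/3
  schema <- make_schema(8, 19, 3)
  sm <- structure(
    list(scores = matrix(2L, 2, 30, dimnames = list(c("A", "B"), schema$id)),
         schema = schema, binning = "equal_width"),
    class = "score_matrix"
  )
  agg <- aggregate_scores(sm)
  expect_equal(agg$institutional[1], 16L)
  expect_equal(agg$human_resource[1], 38L)
  expect_equal(agg$rural_institutional[1], 6L)
  expect_equal(agg$total[1], 60L)
  expect_equal(attr(agg, "bounds"), c(min_total = 30, max_total = 120))

  set.seed(12)
  schema2 <- make_schema(3, 5, 2)
  scores <- matrix(sample(1:4, 60, replace = TRUE), 6, 10,
                   dimnames = list(paste0("r", 1:6), schema2$id))
  sm2 <- structure(list(scores = scores, schema = schema2,
                        binning = "equal_width"), class = "score_matrix")
  agg2 <- aggregate_scores(sm2)
  oracle <- oracle_totals(scores, schema2$cluster)
  expect_equal(agg2$total, as.integer(oracle$total))
  for (cl in indicator_clusters()) {
    expect_equal(agg2[[cl]], as.integer(oracle[[cl]]))
  }
  # total is always the sum of the cluster scores
  expect_equal(agg2$total,
               agg2$institutional + agg2$human_resource + agg2$rural_institutional)
})

test_that("theoretical bounds are n and 4n", {
  expect_equal(theoretical_bounds(1), c(min_total = 1, max_total = 4))
  expect_equal(theoretical_bounds(11), c(min_total = 11, max_total = 44))
  expect_error(theoretical_bounds(0), "positive integer")
  expect_error(theoretical_bounds(2.5), "positive integer")
})
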