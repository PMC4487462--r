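test_that("schema validation enforces uniqueness, clusters and denominators", {
  expect_s3_class(make_schema(), "indicator_schema")
  expect_error(
    indicator_schema(id = c("a", "a"), cluster = c("institutional", "institutional")),
    "duplicate indicator id"
  )
  expect_error(
    indicator_schema(id = "a", cluster = "facilities"),
    "unknown cluster.*facilities"
  )
  expect_error(
    indicator_schema(id = "a", cluster = "institutional", denominator = 0),
    "denominator"
  )
  expect_error(
    indicator_schema(id = "a", cluster = "institutional", orientation = "up"),
    "orientation"
  )
})

test_that("YAML and delimited schema files read with defaults filled", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "indicators:",
    "  - id: pharmacies",
    "    cluster: institutional",
    "  - id: pathologist",
    "    label: Pathologists",
    "    cluster: human_resource",
    "    denominator: 10000"
  ), yml)
  schema <- read_indicator_schema(yml)
  expect_equal(schema$id, c("pharmacies", "pathologist"))
  expect_equal(schema$denominator, c(1000, 10000))
  expect_equal(schema$orientation, rep("higher_is_better", 2))
  expect_equal(schema$label, c("pharmacies", "Pathologists"))

  csv <- write_temp_table(data.frame(id = "beds", cluster = "institutional"))
  schema2 <- read_indicator_schema(csv)
  expect_equal(schema2$denominator, 1000)
})

test_that("tables read with validation and per-1,000 unit normalisation", {
  schema <- indicator_schema(
    id = c("beds", "pathologist"),
    cluster = c("institutional", "human_resource"),
    denominator = c(1000, 10000)
  )
  path <- write_temp_table(data.frame(
    region = c("A", "B"), beds = c(1.5, 0), pathologist = c(20, 5)
  ))
  mat <- read_indicator_table(path, schema)
  expect_s3_class(mat, "indicator_matrix")
  # per-10,000 column divided by 10 on read
  expect_equal(unname(mat$values[, "pathologist"]), c(2.0, 0.5))
  expect_equal(unname(mat$values[, "beds"]), c(1.5, 0))

  # unit invariance: per-10,000 table equals the same table pre-divided by 10
  schema1k <- indicator_schema(
    id = c("beds", "pathologist"),
    cluster = c("institutional", "human_resource")
  )
  path2 <- write_temp_table(data.frame(
    region = c("A", "B"), beds = c(1.5, 0), pathologist = c(2.0, 0.5)
  ))
  expect_equal(read_indicator_table(path2, schema1k)$values, mat$values)
})

test_that("a single-region single-indicator zero table is valid", {
  schema <- indicator_schema(id = "beds", cluster = "institutional")
  path <- write_temp_table(data.frame(region = "Solo", beds = 0))
  mat <- read_indicator_table(path, schema)
  expect_equal(dim(mat), c(1L, 1L))
  expect_equal(unname(mat$values[1, 1]), 0)
})

test_that("table errors name the offending column or cell", {
  schema <- indicator_schema(id = "beds", cluster = "institutional")
  p_unknown <- write_temp_table(data.frame(region = "A", beds = 1, extra = 2))
  expect_error(read_indicator_table(p_unknown, schema), "extra")

  schema2 <- indicator_schema(id = c("beds", "docs"),
                              cluster = c("institutional", "human_resource"))
  p_missing_col <- write_temp_table(data.frame(region = "A", docs = 1))
  expect_error(read_indicator_table(p_missing_col, schema2),
               "missing from the table.*beds")

  p_neg <- write_temp_table(data.frame(region = c("A", "B"), beds = c(1, -2)))
  expect_error(read_indicator_table(p_neg, schema), "\\(B, beds\\)")

  p_nonnum <- write_temp_table(data.frame(region = c("A", "B"), beds = c("1", "x")))
  expect_error(read_indicator_table(p_nonnum, schema), "\\(B, beds\\)")

  p_dup <- write_temp_table(data.frame(region = c("A", "A"), beds = c(1, 2)))
  expect_error(read_indicator_table(p_dup, schema), "duplicate region")
})

test_that("missing cells error in strict mode and impute the minimum in permissive mode", {
  schema <- indicator_schema(id = "beds", cluster = "institutional")
  path <- write_temp_table(data.frame(region = c("A", "B", "C"),
                                      beds = c("2", "", "5")))
  expect_error(read_indicator_table(path, schema), "\\(B, beds\\)")
  expect_warning(
    mat <- read_indicator_table(path, schema, missing = "impute_min"),
    "imputed observed minimum"
  )
  expect_equal(unname(mat$values[, 1]), c(2, 2, 5))
})

test_that("write/read round-trip preserves values and ordering exactly", {
  set.seed(41)
  schema <- make_schema(2, 2, 1)
  vals <- matrix(rexp(5 * 5), 5, 5)
  mat <- make_matrix(vals, schema, regions = c("E", "c b", "A", "d", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indicator_table(mat, path)
  back <- read_indicator_table(path, mat$schema)
  expect_identical(back$values, mat$values)
  expect_identical(rownames(back$values), rownames(mat$values))
})

test_that("normalize_counts matches an element-wise scalar oracle", {
  schema <- make_schema(1, 1, 0)
  # count 5 over 10,000 persons is 0.5 per 1,000; zero counts stay zero
  mat <- normalize_counts(matrix(c(5, 0), 1, 2, dimnames = list("A", NULL)),
                          c(A = 10000), schema)
  expect_equal(unname(mat$values[1, ]), c(0.5, 0))

  set.seed(42)
  counts <- matrix(rpois(6, 20), 3, 2,
                   dimnames = list(c("A", "B", "C"), NULL))
  pop <- c(A = 12000, B = 5400, C = 73000)
  got <- normalize_counts(counts, pop, schema)$values
  for (r in 1:3) for (j in 1:2) {
    expect_equal(unname(got[r, j]), unname(counts[r, j] * 1000 / pop[r]))
  }

  expect_error(normalize_counts(counts, c(A = 12000, B = 0, C = 73000), schema),
               "B")
})

test_that("the packaged Fars fixture has 31 indicators in three clusters", {
  schema <- fars_schema()
  expect_equal(nrow(schema), 31L)
  expect_equal(as.vector(table(factor(schema$cluster, indicator_clusters()))),
               c(8L, 20L, 3L))
  expect_equal(length(fars_regions()), 22L)
  rates <- fars_base_rates()
  expect_true(all(rates > 0))
  expect_equal(names(rates), schema$id)
})
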