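test_that("TSV/CSV expression files parse into validated datasets", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t1\t2", "EGFR\t3\t4", "MYC\t5\t6"), tsv)
  ds <- read_expression(tsv, phenotype = "nbl")
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(rownames(ds$values), c("TP53", "EGFR", "MYC"))
  expect_equal(ds$values["MYC", "s2"], 6)

  csv <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1", "A1,0.5", "B2,1.5"), csv)
  expect_equal(unname(read_expression(csv)$values[, 1]), c(0.5, 1.5))
})

test_that("duplicate symbols collapse case-insensitively by the configured policy", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "EGFR\t1\t8", "egfr\t5\t2"), tsv)
  expect_warning(ds <- read_expression(tsv), "duplicate")
  expect_equal(nrow(ds$values), 1L)
  expect_equal(unname(ds$values["EGFR", ]), c(5, 8))  # element-wise max

  expect_warning(dm <- read_expression(tsv, aggregate = "mean"), "duplicate")
  expect_equal(unname(dm$values["EGFR", ]), c(3, 5))
  expect_error(suppressWarnings(read_expression(tsv, aggregate = "error")),
               "duplicate")
})

test_that("GCT v1.2 parses and flags NA cells as missing", {
  gct <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t4",
               paste(c("Name", "Description", paste0("s", 1:4)), collapse = "\t"),
               paste(c("G1", "d", 1, 2, 3, 4), collapse = "\t"),
               paste(c("G2", "d", 5, "NA", 7, 8), collapse = "\t"),
               paste(c("G3", "d", 1, 1, 1, 1), collapse = "\t"),
               paste(c("G4", "d", 2, 2, 2, 2), collapse = "\t"),
               paste(c("G5", "d", 3, 3, 3, 3), collapse = "\t")), gct)
  ds <- read_expression(gct, format = "gct")
  expect_equal(dim(ds), c(5L, 4L))
  expect_true(is.na(ds$values["G2", "s2"]))
  expect_equal(sum(is.na(ds$values)), 1L)
  bad <- tempfile(); writeLines("gene\ts1", bad)
  expect_error(read_expression(bad, format = "gct"), "GCT")
})

test_that("summary statistics match hand arithmetic and handle edge cases", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("A", paste0("s", 1:3)))
  ds <- expression_dataset(m, "toy")
  s <- summarize_genes(ds, c("mean", "median", "max"))
  expect_equal(unname(s["A", ]), c(2, 2, 3))

  one <- expression_dataset(matrix(5, 1, dimnames = list("B", "s1")), "toy")
  expect_equal(unname(summarize_genes(one, "mean")[1, 1]), 5)

  fe <- expression_dataset(matrix(c(0, 0, 4), 1,
                                  dimnames = list("C", paste0("s", 1:3))), "toy")
  expect_equal(unname(summarize_genes(fe, "frac_expressed", threshold = 1)[1, 1]),
               1 / 3)

  expect_error(summarize_genes(ds, character()), "empty")
  expect_error(summarize_genes(ds, "variance"), "unknown")
})

test_that("summaries ignore sample order and propagate all-missing genes", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:5)))
  m[2, ] <- NA
  ds1 <- suppressWarnings(expression_dataset(m, "toy"))
  ds2 <- suppressWarnings(expression_dataset(m[, c(3, 1, 5, 2, 4)], "toy"))
  s1 <- summarize_genes(ds1)
  s2 <- summarize_genes(ds2)
  expect_equal(s1, s2)
  expect_true(all(is.na(s1["G2", ])))
})

test_that("degenerate expression inputs are rejected", {
  expect_error(expression_dataset(matrix(1, 1, 0,
                                         dimnames = list("A", NULL)), "t"),
               "zero samples")
  expect_error(read_expression(tempfile()), "not found")
})
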