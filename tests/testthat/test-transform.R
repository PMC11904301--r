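test_that("rescaling maps into [0,1] with stated conventions", {
  expect_equal(rescale_feature(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  expect_equal(rescale_feature(c(10, 20, 30, 40), "rank_percentile"),
               c(0, 1 / 3, 2 / 3, 1))
  expect_equal(rescale_feature(c(7, 7, 7), "minmax"), c(0.5, 0.5, 0.5))
  expect_equal(rescale_feature(c(7, 7, 7), "rank_percentile"), c(0.5, 0.5, 0.5))
  # ties share their average percentile
  expect_equal(rescale_feature(c(1, 2, 2, 3), "rank_percentile"),
               c(0, 0.5, 0.5, 1))
  # missing stays missing
  expect_equal(rescale_feature(c(1, NA, 3), "minmax"), c(0, NA, 1))
  expect_error(rescale_feature(c(NA_real_, NA), "minmax"), "all-missing")
})

test_that("imputation fills on the rescaled scale", {
  expect_equal(impute_feature(c(0.2, NA, 0.8), "zero"), c(0.2, 0, 0.8))
  expect_equal(impute_feature(c(0.2, NA, 0.8), "neutral"), c(0.2, 0.5, 0.8))
  expect_equal(impute_feature(c(0.2, NA, 0.8), "median"), c(0.2, 0.5, 0.8))
  expect_equal(impute_feature(c(0.2, NA, 0.8), "min"), c(0.2, 0.2, 0.8))
  x <- c(0.1, 0.9)
  expect_identical(impute_feature(x, "zero"), x)  # no missing -> identity
})

test_that("curving is the identity at 0, hits its closed-form values, and is monotone", {
  v <- seq(0, 1, length.out = 1000)
  expect_equal(curve_value(v, 0), v)
  expect_equal(curve_value(0.5, log(2)), 0.25)
  expect_equal(curve_value(0.25, -log(2)), 0.5)
  for (c in c(-3, -1.2, 0.7, 3)) {
    cv <- curve_value(v, c)
    expect_true(all(diff(cv) > 0))          # strictly increasing
    expect_equal(cv[c(1, 1000)], c(0, 1))   # fixes the endpoints
    expect_true(all(cv >= 0 & cv <= 1))
  }
  expect_error(curve_value(1.2, 0), "\\[0, 1\\]")
  expect_error(curve_value(0.5, Inf), "finite")
})

test_that("positive curves are convex (accentuate high values), negative concave", {
  for (c in c(0.3, 1, 2.5)) {
    expect_gt(curve_value(0.9, c) - curve_value(0.8, c),
              curve_value(0.2, c) - curve_value(0.1, c))
    expect_lt(curve_value(0.9, -c) - curve_value(0.8, -c),
              curve_value(0.2, -c) - curve_value(0.1, -c))
  }
  # grid check of the convexity inequality at many interior pairs
  g <- seq(0.05, 0.85, by = 0.1)
  for (c in c(0.5, 2)) {
    d <- curve_value(g + 0.1, c) - curve_value(g, c)
    expect_true(all(diff(d) > 0))
    d2 <- curve_value(g + 0.1, -c) - curve_value(g, -c)
    expect_true(all(diff(d2) < 0))
  }
})

test_that("gene scores are the normalized weighted average of curved features", {
  # anchor rows pin the minmax rescale so g1 keeps values (0.2, 0.6)
  vals <- matrix(c(0.2, 0, 1,
                   0.6, 0, 1), 3, 2,
                 dimnames = list(c("g1", "lo", "hi"), c("fa", "fb")))
  rep <- score_genes(toy_fm(vals))
  expect_equal(rep$score[rep$gene == "g1"], 0.4)
  expect_equal(sort(rep$rank), 1:3)
  expect_true(all(diff(rep$score) <= 0))  # non-increasing in rank

  # single enabled feature: score equals its curved value, every curve
  cat1 <- toy_catalog(c("fa", "fb"))
  cat1$enabled[2] <- FALSE
  for (cc in c(-2, 0, 1.5)) {
    cat1$curve[1] <- cc
    r1 <- score_genes(toy_fm(vals), catalog = cat1)
    expect_equal(r1$score[match(c("g1", "lo", "hi"), r1$gene)],
                 curve_value(c(0.2, 0, 1), cc))
    expect_equal(r1$gene[1], "hi")  # ranking follows the feature itself
  }

  # a zero-weight feature changes nothing
  cat0 <- toy_catalog(c("fa", "fb"), weight = c(1, 0))
  just_a <- toy_catalog(c("fa", "fb")); just_a$enabled[2] <- FALSE
  expect_equal(score_genes(toy_fm(vals), catalog = cat0)$score,
               score_genes(toy_fm(vals), catalog = just_a)$score)

  allz <- toy_catalog(c("fa", "fb"), weight = 0)
  expect_error(score_genes(toy_fm(vals), catalog = allz), "zero")
})

test_that("scores are invariant to feature order and positive weight rescaling", {
  set.seed(3)
  vals <- matrix(runif(60), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), c("f1", "f2", "f3")))
  cat3 <- toy_catalog(c("f1", "f2", "f3"), weight = c(2, -1, 0.5),
                      curve = c(0.3, -0.7, 0))
  r <- score_genes(toy_fm(vals), catalog = cat3)
  # permute the feature columns and catalog rows
  perm <- c(3, 1, 2)
  r_perm <- score_genes(toy_fm(vals[, perm], cat3[perm, ]))
  expect_equal(r_perm$score, r$score, tolerance = 1e-12)
  expect_identical(r_perm$rank, r$rank)
  expect_identical(r_perm$gene, r$gene)
  # multiply all weights by k > 0
  for (k in c(0.01, 3, 250)) {
    ck <- cat3; ck$weight <- ck$weight * k
    rk <- score_genes(toy_fm(vals), catalog = ck)
    expect_equal(rk$score, r$score, tolerance = 1e-12)
    expect_identical(rk$rank, r$rank)
  }
  # signed weights keep scores in [-1, 1]
  expect_true(all(abs(r$score) <= 1))
  # all-nonnegative weights keep scores in [0, 1]
  catp <- toy_catalog(c("f1", "f2", "f3"), weight = c(2, 1, 0.5))
  expect_true(all(score_genes(toy_fm(vals), catalog = catp)$score >= 0))
})

test_that("score ties break deterministically by gene symbol", {
  vals <- matrix(c(1, 1, 0, 1), 4, 1,
                 dimnames = list(c("ZZ", "AA", "MM", "BB"), "f"))
  rep <- score_genes(toy_fm(vals))
  expect_equal(rep$gene, c("AA", "BB", "ZZ", "MM"))
  expect_equal(rep$percentile, c(100, 200 / 3, 100 / 3, 0))
})

test_that("reports round-trip through TSV and JSON", {
  set.seed(9)
  vals <- matrix(runif(30), 10, 3,
                 dimnames = list(sprintf("G%02d", 1:10), c("f1", "f2", "f3")))
  labels <- label_set(c("G01", "G07"), phenotype = "toy")
  rep <- score_genes(toy_fm(vals), labels = labels)
  for (fmt in c("tsv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_report(rep, path, fmt)
    back <- read_report(path, fmt)
    expect_equal(back$score, rep$score, tolerance = 1e-12)
    expect_identical(back$rank, rep$rank)
    expect_identical(back$gene, rep$gene)
    expect_equal(back$feat.f2, rep$feat.f2, tolerance = 1e-12)
  }
  # JSON carries the MAP when labels were present
  jp <- tempfile(fileext = ".json")
  write_report(rep, jp, "json")
  expect_equal(jsonlite::read_json(jp)$map, attr(rep, "map"))
  # empty report: header-only file, no error
  ep <- tempfile(fileext = ".tsv")
  write_report(rep[0, ], ep, "tsv")
  expect_equal(nrow(read_report(ep)), 0L)
})
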