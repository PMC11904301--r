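write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("snapshots load with schema validation and max-collapse of duplicates", {
  gtex <- write_tsv(data.frame(gene = c("A", "B", "C"),
                               t1 = 1:3, t2 = 4:6, t3 = 7:9,
                               t4 = 0.1 * (1:3), t5 = 2:4))
  snap <- load_snapshot(gtex, "gtex_like")
  expect_equal(ncol(snap$table), 5L)
  expect_equal(rownames(snap$table), c("A", "B", "C"))

  drug <- write_tsv(data.frame(gene = "A", phenotype = "NBL",
                               modality = "ADC", status = "clinical"))
  ds <- load_snapshot(drug, "drugdb")
  expect_equal(ds$table$phenotype, "nbl")  # case-folded
  expect_s3_class(ds$table, "data.frame")  # categorical columns preserved

  dup <- write_tsv(data.frame(gene = c("MYC", "MYC"), t1 = c(1, 5), t2 = c(9, 2)))
  expect_warning(sd <- load_snapshot(dup, "gtex_like"), "duplicate")
  expect_equal(unname(sd$table["MYC", ]), c(5, 9))

  expect_error(load_snapshot(gtex, "no_such_schema"), "unregistered")
  bad <- write_tsv(data.frame(gene = "A", x = 1))
  expect_error(load_snapshot(bad, "surface_evidence"), "missing required")
})

make_snaps <- function() {
  genes <- c("A", "B", "C", "D")
  list(
    gtex_like = snapshot_from_df(
      data.frame(gene = c("A", "B", "D"), t1 = c(1, 10, 3), t2 = c(5, 20, 1),
                 t3 = c(2, 15, 2)), "gtex_like"),
    surface_evidence = snapshot_from_df(
      data.frame(gene = c("A", "B"), evidence_score = c(5, 1),
                 compartments_score = c(4, 2)), "surface_evidence"),
    depmap_like = snapshot_from_df(
      data.frame(gene = genes, nbl.l1 = c(0.9, 0.1, 0.6, 0.2),
                 nbl.l2 = c(0.7, 0.3, 0.8, 0.1), ews.l1 = c(0, 0, 0, 0.9),
                 check.names = FALSE), "depmap_like"),
    pmtl_like = snapshot_from_df(
      data.frame(gene = genes, pmtl_flag = c(1, 0, 0, 1)), "pmtl_like"),
    drugdb = snapshot_from_df(
      data.frame(gene = c("A", "B", "C", "D", "D"),
                 phenotype = c("ews", "nbl", "nbl", "nbl", "ews"),
                 modality = c("ADC", "mAb", "ADC", "CAR-T", "ADC"),
                 status = c("approved", "clinical", "discontinued",
                            "discontinued", "clinical")), "drugdb"))
}

toy_summary <- function(genes = c("A", "B", "C", "D")) {
  m <- matrix(seq_along(genes), length(genes), 5,
              dimnames = list(genes, c("mean", "median", "max", "q75",
                                       "frac_expressed")))
  m
}

test_that("enrich left-joins on dataset genes with missing (not zero) for absences", {
  snaps <- make_snaps()
  fm <- enrich(toy_summary(), snaps, default_catalog(), phenotype = "nbl")
  expect_equal(rownames(fm$values), c("A", "B", "C", "D"))
  expect_equal(ncol(fm$values), sum(default_catalog()$enabled))
  # A present everywhere -> fully populated
  expect_false(anyNA(fm$values["A", ]))
  # C absent from the surface snapshot -> missing, not zero
  expect_true(is.na(fm$values["C", "surface_evidence"]))
  # normal tissues (1, 5, 2) for A -> max 5
  expect_equal(unname(fm$values["A", "normal_expr_max"]), 5)
  # C absent from gtex -> missing normal features
  expect_true(is.na(fm$values["C", "normal_expr_max"]))
  # nbl-matched dependency for A: mean(0.9, 0.7)
  expect_equal(unname(fm$values["A", "dependency_mean"]), 0.8)
  expect_equal(unname(fm$values["A", "essentiality_frac"]), 1)
  # therapeutic availability counts only non-nbl records: A (ews ADC) yes
  expect_equal(unname(fm$values["A", c("has_drug", "has_adc")]), c(1, 1))
  # B's only record is nbl -> no cross-indication availability
  expect_equal(unname(fm$values["B", "has_drug"]), 0)
  # D: ews clinical ADC record -> available
  expect_equal(unname(fm$values["D", "has_adc"]), 1)
})

test_that("enrich preserves gene order/count and ignores snapshot list order", {
  snaps <- make_snaps()
  fm1 <- enrich(toy_summary(), snaps, default_catalog(), "nbl")
  fm2 <- enrich(toy_summary(), rev(snaps), default_catalog(), "nbl")
  expect_identical(fm1$values, fm2$values)
  expect_equal(nrow(fm1$values), 4L)
})

test_that("enrich fails on unresolvable enabled features", {
  snaps <- make_snaps()
  expect_error(enrich(toy_summary(), snaps[-1], default_catalog(), "nbl"),
               "snapshot 'gtex_like'")
  cat2 <- default_catalog()
  cat2$column[cat2$name == "expr_mean"] <- "nope"
  expect_error(enrich(toy_summary(), snaps, cat2, "nbl"), "resolvable")
})

test_that("labels derive by status precedence and stay disjoint", {
  drug <- snapshot_from_df(
    data.frame(gene = c("A", "B", "C", "C"),
               phenotype = c("nbl", "nbl", "nbl", "nbl"),
               modality = c("ADC", "ADC", "CAR-T", "ADC"),
               status = c("clinical", "discontinued", "discontinued",
                          "approved")), "drugdb")
  ls <- derive_labels("NBL", drug)
  expect_setequal(ls$positives, c("A", "C"))  # C: active beats discontinued
  expect_setequal(ls$negatives, "B")

  lm <- derive_labels("nbl", drug, modalities = "ADC")
  expect_setequal(lm$positives, c("A", "C"))

  # property: disjoint by construction for random tables
  set.seed(42)
  for (i in 1:20) {
    tab <- data.frame(
      gene = sample(LETTERS[1:8], 15, replace = TRUE),
      phenotype = sample(c("nbl", "ews"), 15, replace = TRUE),
      modality = sample(c("ADC", "mAb"), 15, replace = TRUE),
      status = sample(c("approved", "clinical", "discontinued"), 15,
                      replace = TRUE))
    lr <- derive_labels("nbl", snapshot_from_df(tab, "drugdb"))
    expect_length(intersect(lr$positives, lr$negatives), 0)
  }

  badtab <- data.frame(gene = "A", phenotype = "nbl", modality = "ADC",
                       status = "withdrawn")
  expect_error(snapshot_from_df(badtab, "drugdb"), "unknown drug status")
})

test_that("restricted normal filter cuts strictly below the interpolated percentile", {
  vals <- matrix(c(1, 2, 3, 4, 100), 5, 1,
                 dimnames = list(paste0("g", 1:5), "normal_expr_max"))
  fm <- toy_fm(vals, toy_catalog("normal_expr_max"))
  report <- data.frame(gene = paste0("g", 1:5), stringsAsFactors = FALSE)
  # 20th percentile of {1,2,3,4,100} by linear interpolation = 1.8
  expect_equal(restricted_normal_filter(report, fm, "normal_expr_max", 20), "g1")
  # pct = 100: everything strictly below the max
  expect_setequal(restricted_normal_filter(report, fm, "normal_expr_max", 100),
                  paste0("g", 1:4))
  # missing values never pass
  vals[2, 1] <- NA
  fm2 <- toy_fm(vals, toy_catalog("normal_expr_max"))
  expect_false("g2" %in%
    restricted_normal_filter(report, fm2, "normal_expr_max", 90))
  # report order is preserved
  rev_report <- data.frame(gene = paste0("g", 5:1), stringsAsFactors = FALSE)
  out <- restricted_normal_filter(rev_report, fm, "normal_expr_max", 100)
  expect_equal(out, paste0("g", 4:1))
  expect_error(restricted_normal_filter(report, fm, "nope", 20), "not in matrix")
})
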