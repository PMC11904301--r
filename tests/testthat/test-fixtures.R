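test_that("fixture generation is byte-identical under one seed", {
  cfg <- fixture_config(n_genes = 60, n_samples = 4, n_phenotypes = 2,
                        n_planted = 4, seed = 7)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  generate_fixture(cfg, d1)
  generate_fixture(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 7)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- file.path(tempfile(), "c")
  generate_fixture(fixture_config(n_genes = 60, n_samples = 4,
                                  n_phenotypes = 2, n_planted = 4, seed = 8), d3)
  expect_false(identical(readLines(file.path(d1, "expression_pheno1.tsv")),
                         readLines(file.path(d3, "expression_pheno1.tsv"))))
})

test_that("ground truth bookkeeping matches the configuration", {
  cfg <- fixture_config(n_genes = 80, n_samples = 4, n_phenotypes = 2,
                        n_planted = 5, coverage = 1, decoy_fraction = 0,
                        seed = 3)
  dir <- tempfile()
  generate_fixture(cfg, dir)
  truth <- fixture_truth(dir)
  for (p in names(truth$labels)) {
    expect_length(truth$labels[[p]]$positives, 5)   # coverage 1.0
    expect_length(truth$labels[[p]]$negatives, 0)   # no decoys
    expect_true(all(truth$planted[[p]] %in%
                      rownames(load_fixture(dir)[[p]]$fm$values)))
  }
  cfg2 <- fixture_config(n_genes = 80, n_planted = 10, decoy_fraction = 0.3,
                         seed = 3)
  fix2 <- build_fixture(cfg2)
  expect_length(fix2$truth$pheno1$negatives, 3)
  expect_error(fixture_truth(tempfile()), "not found")
})

test_that("planted effects appear in the generated data and vanish at zero effect", {
  cfg <- fixture_config(n_genes = 100, n_samples = 10, n_phenotypes = 1,
                        n_planted = 8, seed = 5)
  fix <- build_fixture(cfg)
  planted <- fix$truth$pheno1$planted
  expr <- fix$datasets$pheno1$values
  bg <- setdiff(rownames(expr), planted)
  # ~3 log2 units of planted tumor shift
  expect_gt(mean(expr[planted, ]) - mean(expr[bg, ]), 1.5)
  # suppressed normal expression
  gtex <- fix$snapshots$gtex_like$table
  expect_lt(mean(log2(rowMeans(gtex[planted, ]))),
            mean(log2(rowMeans(gtex[bg, ]))))

  null_cfg <- fixture_config(n_genes = 100, n_samples = 10, n_phenotypes = 1,
                             n_planted = 8, seed = 5, null_effects = TRUE)
  nfix <- build_fixture(null_cfg)
  nplanted <- nfix$truth$pheno1$planted
  nexpr <- nfix$datasets$pheno1$values
  nbg <- setdiff(rownames(nexpr), nplanted)
  expect_lt(abs(mean(nexpr[nplanted, ]) - mean(nexpr[nbg, ])), 1.5)
  # labels still exist under the null
  expect_length(nfix$truth$pheno1$positives, 8)
})

test_that("fixture projects carry disjoint planted sets and derived labels", {
  cfg <- fixture_config(n_genes = 120, n_samples = 5, n_phenotypes = 2,
                        n_planted = 6, seed = 9)
  fix <- build_fixture(cfg)
  expect_length(intersect(fix$truth$pheno1$planted,
                          fix$truth$pheno2$planted), 0)
  projs <- fixture_projects(fix)
  expect_named(projs, c("pheno1", "pheno2"))
  for (p in names(projs)) {
    expect_setequal(projs[[p]]$labels$positives, fix$truth[[p]]$positives)
    expect_setequal(projs[[p]]$labels$negatives, fix$truth[[p]]$negatives)
  }
})

test_that("written fixtures reload to the same scores as in-memory ones", {
  cfg <- fixture_config(n_genes = 50, n_samples = 4, n_phenotypes = 1,
                        n_planted = 4, seed = 13)
  fix <- build_fixture(cfg)
  dir <- tempfile()
  generate_fixture(cfg, dir)
  mem <- fixture_projects(fix)
  disk <- load_fixture(dir)
  rm_ <- score_genes(mem$pheno1$fm, keep_features = FALSE)
  rd_ <- score_genes(disk$pheno1$fm, keep_features = FALSE)
  expect_identical(rm_$gene, rd_$gene)
  expect_equal(rm_$score, rd_$score, tolerance = 1e-9)
})

test_that("invalid fixture configurations are rejected", {
  expect_error(fixture_config(n_genes = 10, n_planted = 6, n_phenotypes = 2),
               "n_planted")
  expect_error(fixture_config(coverage = 1.5), "coverage")
})
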