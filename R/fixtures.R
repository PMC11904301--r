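#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the criteria of an ideal immunotherapy target:
#' planted genes get high and homogeneous tumor expression, minimal
#' normal-tissue expression, strong surface-localization evidence, elevated
#' tumor dependency, and drug records that yield known-positive labels;
#' decoy genes get only discontinued records (known-negatives). Defaults are
#' the strong-signal benchmark conditions: a 3-log2-unit tumor shift (three
#' noise standard deviations), 5-fold normal-tissue suppression, 0.9
#' surface-evidence boost probability, full drug coverage of planted genes
#' and 3 discontinued decoys per ten planted.
#'
#' @param n_genes,n_samples,n_phenotypes,n_planted Universe sizes.
#' @param effect_size Log2 shift added to planted genes' tumor expression.
#' @param noise_sd Log2 sample noise standard deviation.
#' @param normal_suppression Fold suppression of planted genes' normal-tissue
#'   expression (1 = none).
#' @param surface_boost_p,base_surface_p Probability of strong surface
#'   evidence for planted vs background genes.
#' @param dependency_boost Shift added to planted genes' dependency in their
#'   own phenotype's cell lines.
#' @param coverage Fraction of planted genes receiving an active
#'   phenotype-matched drug record (these become the known positives).
#' @param decoy_fraction Discontinued-only decoy genes per phenotype, as a
#'   fraction of `n_planted`.
#' @param xdrug_p,base_xdrug_p Probability of an active cross-indication drug
#'   record for planted vs background genes (feeds the therapeutic features).
#' @param pmtl_boost_p,base_pmtl_p Pediatric target list membership
#'   probability for planted vs background genes.
#' @param n_tissues Normal-tissue columns in the gtex-like snapshot.
#' @param lines_per_phenotype Cell-line columns per phenotype in the
#'   depmap-like snapshot.
#' @param seed Mandatory integer seed; the whole fixture is a deterministic
#'   function of the configuration.
#' @param null_effects If TRUE, all planted boosts collapse to the background
#'   rates (effect-free fixture: labels exist but no feature carries signal).
#' @return A validated `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 1000, n_samples = 20, n_phenotypes = 2,
                           n_planted = 10, effect_size = 3, noise_sd = 1,
                           normal_suppression = 5,
                           surface_boost_p = 0.9, base_surface_p = 0.15,
                           dependency_boost = 0.6,
                           coverage = 1.0, decoy_fraction = 0.3,
                           xdrug_p = 0.7, base_xdrug_p = 0.02,
                           pmtl_boost_p = 0.5, base_pmtl_p = 0.05,
                           n_tissues = 10, lines_per_phenotype = 3,
                           seed = 7, null_effects = FALSE) {
  if (null_effects) {
    effect_size <- 0
    normal_suppression <- 1
    surface_boost_p <- base_surface_p
    dependency_boost <- 0
    xdrug_p <- base_xdrug_p
    pmtl_boost_p <- base_pmtl_p
  }
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              n_phenotypes = n_phenotypes, n_planted = n_planted,
              effect_size = effect_size, noise_sd = noise_sd,
              normal_suppression = normal_suppression,
              surface_boost_p = surface_boost_p,
              base_surface_p = base_surface_p,
              dependency_boost = dependency_boost,
              coverage = coverage, decoy_fraction = decoy_fraction,
              xdrug_p = xdrug_p, base_xdrug_p = base_xdrug_p,
              pmtl_boost_p = pmtl_boost_p, base_pmtl_p = base_pmtl_p,
              n_tissues = n_tissues,
              lines_per_phenotype = lines_per_phenotype,
              seed = as.integer(seed))
  stopifnot(cfg$n_planted * cfg$n_phenotypes < cfg$n_genes,
            cfg$coverage >= 0, cfg$coverage <= 1,
            cfg$decoy_fraction >= 0, cfg$decoy_fraction <= 1,
            cfg$normal_suppression >= 1, cfg$noise_sd >= 0,
            !is.na(cfg$seed), cfg$seed >= 0)
  class(cfg) <- "fixture_config"
  cfg
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Build a synthetic benchmark in memory
#'
#' Returns the datasets, shared snapshots and ground truth for a
#' [fixture_config()], without touching disk. Planted gene sets are disjoint
#' across phenotypes.
#'
#' @param cfg A [fixture_config()].
#' @return A `tr_fixture`: list(datasets, snapshots, truth, cfg). `truth`
#'   holds, per phenotype, the planted genes, labeled positives and decoy
#'   negatives.
#' @export
build_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    phenos <- sprintf("pheno%d", seq_len(cfg$n_phenotypes))
    planted <- list()
    pool <- genes
    for (p in phenos) {
      planted[[p]] <- sort(sample(pool, cfg$n_planted))
      pool <- setdiff(pool, planted[[p]])
    }
    planted_all <- unlist(planted, use.names = FALSE)

    # tumor expression, log2 scale: gene baseline + sample noise (+ effect)
    datasets <- list()
    for (p in phenos) {
      mu <- stats::rnorm(cfg$n_genes, 5, 2)
      names(mu) <- genes
      mu[planted[[p]]] <- mu[planted[[p]]] + cfg$effect_size
      vals <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, mu, cfg$noise_sd),
                     cfg$n_genes, cfg$n_samples,
                     dimnames = list(genes, sprintf("%s_s%02d", p,
                                                    seq_len(cfg$n_samples))))
      datasets[[p]] <- expression_dataset(vals, phenotype = p, units = "log2")
    }

    # gtex-like normal tissue medians, linear scale
    nmu <- stats::rnorm(cfg$n_genes, 5, 2)
    gtex <- matrix(2^(nmu + stats::rnorm(cfg$n_genes * cfg$n_tissues, 0, 0.5)),
                   cfg$n_genes, cfg$n_tissues,
                   dimnames = list(genes, sprintf("tissue_%02d",
                                                  seq_len(cfg$n_tissues))))
    gtex[planted_all, ] <- gtex[planted_all, ] / cfg$normal_suppression

    # surface localization evidence, 0-5 discrete
    surf_hi <- stats::runif(cfg$n_genes) < cfg$base_surface_p
    names(surf_hi) <- genes
    surf_hi[planted_all] <- stats::runif(length(planted_all)) < cfg$surface_boost_p
    evidence <- ifelse(surf_hi, sample(3:5, cfg$n_genes, replace = TRUE),
                       sample(0:2, cfg$n_genes, replace = TRUE))
    compartments <- pmin(5, pmax(0, evidence + sample(-1:1, cfg$n_genes,
                                                      replace = TRUE)))
    surface <- cbind(evidence_score = evidence,
                     compartments_score = compartments)
    rownames(surface) <- genes

    # depmap-like dependency per <phenotype>.<line> column
    dep_cols <- unlist(lapply(phenos, function(p)
      sprintf("%s.line%d", p, seq_len(cfg$lines_per_phenotype))))
    dep <- matrix(stats::rnorm(cfg$n_genes * length(dep_cols), 0.1, 0.1),
                  cfg$n_genes, length(dep_cols),
                  dimnames = list(genes, dep_cols))
    for (p in phenos) {
      cols <- grep(paste0("^", p, "\\."), dep_cols)
      dep[planted[[p]], cols] <- dep[planted[[p]], cols] + cfg$dependency_boost
    }

    # pediatric target list membership
    pmtl_p <- rep(cfg$base_pmtl_p, cfg$n_genes)
    names(pmtl_p) <- genes
    pmtl_p[planted_all] <- cfg$pmtl_boost_p
    pmtl <- cbind(pmtl_flag = as.numeric(stats::runif(cfg$n_genes) < pmtl_p))
    rownames(pmtl) <- genes

    # drug records: phenotype-matched actives (-> positives), discontinued
    # decoys (-> negatives), cross-indication actives (-> features)
    recs <- list()
    truth <- list()
    n_decoys <- round(cfg$decoy_fraction * cfg$n_planted)
    decoy_pool <- setdiff(genes, planted_all)
    for (p in phenos) {
      covered <- planted[[p]][stats::runif(cfg$n_planted) < cfg$coverage]
      for (g in covered) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, phenotype = p,
          modality = sample(c("ADC", "CAR-T", "mAb"), 1),
          status = sample(c("approved", "clinical"), 1),
          stringsAsFactors = FALSE)
      }
      decoys <- if (n_decoys > 0) sort(sample(decoy_pool, n_decoys)) else character()
      decoy_pool <- setdiff(decoy_pool, decoys)
      for (g in decoys) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, phenotype = p,
          modality = sample(c("ADC", "CAR-T", "mAb"), 1),
          status = "discontinued", stringsAsFactors = FALSE)
      }
      truth[[p]] <- list(planted = planted[[p]], positives = covered,
                         negatives = decoys)
    }
    xp <- rep(cfg$base_xdrug_p, cfg$n_genes)
    names(xp) <- genes
    xp[planted_all] <- cfg$xdrug_p
    xdrug <- genes[stats::runif(cfg$n_genes) < xp]
    for (g in xdrug) {
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, phenotype = "other_cancer",
        modality = sample(c("ADC", "mAb"), 1),
        status = sample(c("approved", "clinical"), 1),
        stringsAsFactors = FALSE)
    }
    drug_df <- do.call(rbind, recs)

    snapshots <- list(
      gtex_like = snapshot_from_df(
        data.frame(gene = genes, gtex, check.names = FALSE), "gtex_like",
        source = "fixture"),
      surface_evidence = snapshot_from_df(
        data.frame(gene = genes, surface, check.names = FALSE),
        "surface_evidence", source = "fixture"),
      depmap_like = snapshot_from_df(
        data.frame(gene = genes, dep, check.names = FALSE), "depmap_like",
        source = "fixture"),
      pmtl_like = snapshot_from_df(
        data.frame(gene = genes, pmtl, check.names = FALSE), "pmtl_like",
        source = "fixture"),
      drugdb = snapshot_from_df(drug_df, "drugdb", source = "fixture")
    )
    structure(list(datasets = datasets, snapshots = snapshots,
                   truth = truth, cfg = cfg),
              class = "tr_fixture")
  })
}

#' Assemble scoring projects from a fixture
#'
#' Runs the standard path — per-gene summaries, snapshot enrichment, label
#' derivation from the drug table — for every fixture phenotype.
#'
#' @param fixture A `tr_fixture` from [build_fixture()].
#' @param catalog Feature catalog (default [default_catalog()]).
#' @return Named list of [tr_project()]s.
#' @export
fixture_projects <- function(fixture, catalog = default_catalog()) {
  stopifnot(inherits(fixture, "tr_fixture"))
  out <- list()
  for (p in names(fixture$datasets)) {
    ds <- fixture$datasets[[p]]
    summ <- summarize_genes(ds)
    fm <- enrich(summ, fixture$snapshots, catalog, phenotype = p)
    labels <- derive_labels(p, fixture$snapshots$drugdb)
    out[[p]] <- tr_project(fm, labels)
  }
  out
}

#' Write a fixture as a self-contained project directory
#'
#' Emits one expression TSV per phenotype, the five snapshot TSVs and a YAML
#' manifest holding the configuration and ground truth. Numbers are printed
#' with fixed 15-significant-digit formatting so identical configurations
#' produce byte-identical directories.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly; the built fixture as attribute.
#' @export
generate_fixture <- function(cfg, dir) {
  fix <- build_fixture(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, path) {
    df <- data.frame(gene = rownames(m),
                     apply(m, 2, function(v) sprintf("%.15g", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (p in names(fix$datasets)) {
    wm(fix$datasets[[p]]$values, file.path(dir, paste0("expression_", p, ".tsv")))
  }
  for (s in c("gtex_like", "surface_evidence", "depmap_like", "pmtl_like")) {
    wm(fix$snapshots[[s]]$table, file.path(dir, paste0(s, ".tsv")))
  }
  utils::write.table(fix$snapshots$drugdb$table, file.path(dir, "drugdb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(fix$cfg), truth = fix$truth)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  structure(invisible(dir), fixture = fix)
}

#' Read ground truth back from a fixture manifest
#'
#' @param dir Fixture directory containing `manifest.yaml` (or the manifest
#'   path itself).
#' @return list(labels = per-phenotype [label_set()]s, planted = per-phenotype
#'   planted genes, config = generator configuration).
#' @export
fixture_truth <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.yaml") else dir
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  if (is.null(man$truth) || is.null(man$config)) stop("corrupt manifest: ", path)
  labels <- lapply(names(man$truth), function(p) {
    tr <- man$truth[[p]]
    label_set(as.character(tr$positives %||% character()),
              as.character(tr$negatives %||% character()),
              phenotype = p, provenance = "drug_snapshot")
  })
  names(labels) <- names(man$truth)
  list(labels = labels,
       planted = lapply(man$truth, function(tr) as.character(tr$planted)),
       config = man$config)
}

#' Load a fixture directory into scoring projects
#'
#' @param dir Directory written by [generate_fixture()].
#' @param catalog Feature catalog.
#' @return Named list of [tr_project()]s.
#' @export
load_fixture <- function(dir, catalog = default_catalog()) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  snapshots <- list(
    gtex_like = load_snapshot(file.path(dir, "gtex_like.tsv"), "gtex_like"),
    surface_evidence = load_snapshot(file.path(dir, "surface_evidence.tsv"),
                                     "surface_evidence"),
    depmap_like = load_snapshot(file.path(dir, "depmap_like.tsv"), "depmap_like"),
    pmtl_like = load_snapshot(file.path(dir, "pmtl_like.tsv"), "pmtl_like"),
    drugdb = load_snapshot(file.path(dir, "drugdb.tsv"), "drugdb"))
  out <- list()
  for (p in names(man$truth)) {
    ds <- read_expression(file.path(dir, paste0("expression_", p, ".tsv")),
                          format = "tsv", units = "log2", phenotype = p)
    fm <- enrich(summarize_genes(ds), snapshots, catalog, phenotype = p)
    labels <- derive_labels(p, snapshots$drugdb)
    out[[p]] <- tr_project(fm, labels)
  }
  out
}
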