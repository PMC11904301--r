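config_keys <- c("datasets", "snapshots", "features", "labels",
                 "optimization", "seed")
opt_keys <- c("strategy", "sfs_threshold", "population", "generations",
              "mutation_sd", "mutation_rate", "crossover_rate", "tournament",
              "elitism", "nm_every", "nm_improve_threshold",
              "weight_bounds", "curve_bounds")

#' Read and validate a project-parameters YAML file
#'
#' One YAML document configuring a prioritization project. Top-level keys
#' (unknown keys are an error, catching typos):
#' \describe{
#'   \item{datasets}{list of \{path, format, units, phenotype\} entries.}
#'   \item{snapshots}{map of schema name (see [snapshot_schemas()]) to TSV
#'     path.}
#'   \item{features}{list of per-feature overrides \{name, enabled, weight,
#'     curve, rescale, impute\} applied to the default catalog.}
#'   \item{labels}{either \{source: drug_snapshot, modalities: [...]\} or
#'     \{source: explicit, phenotypes: \{<phenotype>: \{positives: [...],
#'     negatives: [...]\}\}\}.}
#'   \item{optimization}{strategy plus any [tr_control()] setting.}
#'   \item{seed}{nonnegative integer driving every stochastic routine.}
#' }
#'
#' @param path YAML file path.
#' @return A validated `tr_config` list with a `base_dir` attribute for
#'   resolving relative paths.
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) stop("unknown project config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L) {
    stop("project config needs at least one dataset")
  }
  for (d in cfg$datasets) {
    if (is.null(d$path)) stop("dataset entry without a path")
  }
  if (!is.null(cfg$optimization)) {
    bad <- setdiff(names(cfg$optimization), opt_keys)
    if (length(bad)) stop("unknown optimization key(s): ",
                          paste(bad, collapse = ", "))
    for (k in c("sfs_threshold", "nm_improve_threshold")) {
      v <- cfg$optimization[[k]]
      if (!is.null(v) && v < 0) stop(k, " must be a nonnegative fraction")
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed) || cfg$seed < 0) stop("seed must be a nonnegative integer")
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  class(cfg) <- "tr_config"
  cfg
}

resolve_path <- function(p, base) {
  if (file.exists(p) || grepl("^/", p)) p else file.path(base, p)
}

#' Build catalog and scoring projects from a validated config
#'
#' @param config A `tr_config` from [read_project_config()].
#' @return list(catalog, projects).
#' @export
config_projects <- function(config) {
  stopifnot(inherits(config, "tr_config"))
  base <- attr(config, "base_dir") %||% "."
  catalog <- apply_catalog_overrides(default_catalog(), config$features %||% list())
  snapshots <- list()
  for (nm in names(config$snapshots %||% list())) {
    snapshots[[nm]] <- load_snapshot(resolve_path(config$snapshots[[nm]], base), nm)
  }
  label_cfg <- config$labels %||% list(source = "drug_snapshot")
  projects <- list()
  for (d in config$datasets) {
    ds <- read_expression(resolve_path(d$path, base),
                          format = d$format %||% "auto",
                          units = d$units %||% "log2",
                          phenotype = d$phenotype %||% "unknown")
    fm <- enrich(summarize_genes(ds), snapshots, catalog,
                 phenotype = ds$phenotype)
    labels <- if (identical(label_cfg$source, "explicit")) {
      lst <- label_cfg$phenotypes[[ds$phenotype]]
      if (is.null(lst)) stop("no explicit labels for phenotype ", ds$phenotype)
      label_set(as.character(lst$positives %||% character()),
                as.character(lst$negatives %||% character()),
                phenotype = ds$phenotype, provenance = "user_list")
    } else {
      if (is.null(snapshots$drugdb)) stop("drug_snapshot labels need a drugdb snapshot")
      derive_labels(ds$phenotype, snapshots$drugdb,
                    modalities = label_cfg$modalities)
    }
    projects[[ds$phenotype]] <- tr_project(fm, labels)
  }
  list(catalog = catalog, projects = projects)
}

#' Build a [tr_control()] from a config's optimization block
#' @param config A `tr_config`.
#' @export
config_control <- function(config) {
  oc <- config$optimization %||% list()
  oc$strategy <- NULL
  do.call(tr_control, oc)
}

#' Serialize fitted parameters as a project-compatible features block
#'
#' Writes the fit's per-feature enabled/weight/curve values as YAML that can
#' be dropped into a project config's `features:` key.
#' @param fit A `tr_fit` or `tr_optimization`.
#' @param path Output YAML path.
#' @export
write_params <- function(fit, path) {
  cat_all <- fit$catalog
  feats <- lapply(seq_len(nrow(cat_all)), function(i) {
    list(name = cat_all$name[i], enabled = cat_all$enabled[i],
         weight = cat_all$weight[i], curve = cat_all$curve[i])
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}
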