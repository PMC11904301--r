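#' Bundle a feature matrix with its labels as a scoring project
#'
#' @param fm A `feature_matrix` from [enrich()].
#' @param labels A [label_set()] for the same phenotype.
#' @return A `tr_project` list.
#' @export
tr_project <- function(fm, labels) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(labels, "label_set"))
  structure(list(fm = fm, labels = labels, phenotype = fm$phenotype),
            class = "tr_project")
}

#' @export
print.tr_project <- function(x, ...) {
  cat(sprintf("<tr_project> phenotype '%s': %d genes x %d features, %d/+%d labels\n",
              x$phenotype, nrow(x$fm$values), ncol(x$fm$values),
              length(x$labels$positives), length(x$labels$negatives)))
  invisible(x)
}

# The rescaled+imputed feature matrix does not depend on weights or curves,
# so optimizers compile each project once and only re-curve per evaluation.
compile_project <- function(project, catalog) {
  stopifnot(inherits(project, "tr_project"))
  feat <- catalog$name[catalog$enabled]
  feat <- feat[feat %in% colnames(project$fm$values)]
  M <- transform_features(project$fm$values[, feat, drop = FALSE],
                          catalog, stage = "imputed")
  list(M = M, genes = rownames(M), labels = project$labels)
}

# Mean MAP for weight vector w and curve vector cc over compiled projects.
# Invalid parameter vectors (all-zero weights) yield -1, below any MAP.
compiled_objective <- function(compiled, w, cc) {
  if (all(w == 0)) return(-1)
  use <- w != 0
  total <- 0
  for (cp in compiled) {
    curved <- cp$M[, use, drop = FALSE]
    e <- exp(cc[use])
    for (j in seq_along(e)) curved[, j] <- curved[, j]^e[j]
    score <- as.vector(curved %*% w[use]) / sum(abs(w[use]))
    ranking <- cp$genes[order(-score, cp$genes)]
    total <- total + average_precision(ranking, cp$labels)$map
  }
  total / length(compiled)
}

#' Optimization objective: mean MAP across projects under given parameters
#'
#' Scores every project with the catalog's weights and curves and returns the
#' unweighted mean of the per-project MAPs (the multi-cancer objective; with
#' a single project it is the phenotype-specific objective). Deterministic
#' and pure: identical inputs give bit-identical values.
#'
#' @param catalog Feature catalog carrying the parameter values.
#' @param projects List of [tr_project()] objects.
#' @return Mean MAP in [0, 1].
#' @export
objective <- function(catalog, projects) {
  if (length(projects) == 0L) stop("no projects")
  validate_catalog(catalog)
  evs <- lapply(projects, function(p) {
    rep <- score_genes(p$fm, catalog = catalog, keep_features = FALSE)
    average_precision(rep$gene, p$labels)
  })
  map_over_projects(evs)
}
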