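# Shared builders: tiny in-code projects and independent oracles.

# Minimal catalog for ad-hoc feature matrices.
toy_catalog <- function(names, weight = 1, curve = 0,
                        rescale = "minmax", impute = "zero") {
  data.frame(name = names, category = "annotation",
             direction = "higher_better",
             rescale = rescale, impute = impute,
             weight = rep_len(weight, length(names)),
             curve = rep_len(curve, length(names)),
             enabled = TRUE, source = "summary", column = names,
             stringsAsFactors = FALSE)
}

# Feature matrix straight from a genes x features numeric matrix.
toy_fm <- function(values, catalog = NULL, phenotype = "toy") {
  if (is.null(catalog)) catalog <- toy_catalog(colnames(values))
  structure(list(values = values, catalog = catalog, phenotype = phenotype,
                 provenance = stats::setNames(catalog$source, catalog$name)),
            class = "feature_matrix")
}

# Independent brute-force average precision: scan the prefix above each
# positive and count relevant genes by explicit membership tests.
ap_oracle <- function(ranking, positives, negatives = character(),
                      labeled_only = FALSE) {
  if (labeled_only) ranking <- ranking[ranking %in% c(positives, negatives)]
  precs <- c()
  for (i in seq_along(ranking)) {
    if (ranking[i] %in% positives) {
      precs <- c(precs, sum(ranking[seq_len(i)] %in% positives) / i)
    }
  }
  mean(precs)
}

# A toy multi-feature project: n genes, features as given columns, labels.
toy_project <- function(values, positives, negatives = character(),
                        catalog = NULL, phenotype = "toy") {
  fm <- toy_fm(values, catalog, phenotype)
  tr_project(fm, label_set(positives, negatives, phenotype = phenotype))
}

# Random toy project: k noise features; optionally one feature that ranks
# the positives exactly on top (a "separating" feature).
random_toy_project <- function(n_genes = 30, k = 3, n_pos = 4,
                               separating = TRUE) {
  genes <- sprintf("T%03d", seq_len(n_genes))
  pos <- sample(genes, n_pos)
  vals <- matrix(stats::runif(n_genes * k), n_genes, k,
                 dimnames = list(genes, paste0("f", seq_len(k))))
  if (separating) vals[, 1] <- ifelse(genes %in% pos, 1, 0) + vals[, 1] / 10
  toy_project(vals, pos)
}

# Exhaustive subset-search oracle at default parameters.
subset_oracle <- function(project, catalog) {
  idx <- which(catalog$enabled)
  best <- -Inf
  best_sub <- integer()
  for (m in seq_len(2^length(idx) - 1)) {
    sub <- idx[bitwAnd(m, 2^(seq_along(idx) - 1)) > 0]
    cat_m <- catalog
    cat_m$enabled <- FALSE
    cat_m$enabled[sub] <- TRUE
    val <- objective(cat_m, list(project))
    if (val > best) { best <- val; best_sub <- sub }
  }
  list(max = best, subset = catalog$name[best_sub])
}
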