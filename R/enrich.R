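#' Known-positive / known-negative label set
#'
#' @param positives Character vector of known-positive gene symbols.
#' @param negatives Character vector of known-negative gene symbols.
#' @param phenotype Phenotype the labels apply to.
#' @param provenance "user_list" or "drug_snapshot".
#' @return A `label_set` object; positives and negatives are disjoint.
#' @export
label_set <- function(positives, negatives = character(), phenotype = "unknown",
                      provenance = c("user_list", "drug_snapshot")) {
  provenance <- match.arg(provenance)
  positives <- unique(normalize_symbols(positives))
  negatives <- if (length(negatives)) unique(normalize_symbols(negatives)) else character()
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap: ",
         paste(intersect(positives, negatives), collapse = ", "))
  }
  structure(list(positives = positives, negatives = negatives,
                 phenotype = as.character(phenotype)[1],
                 provenance = provenance),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> phenotype '%s': %d positive(s), %d negative(s) [%s]\n",
              x$phenotype, length(x$positives), length(x$negatives),
              x$provenance))
  invisible(x)
}

#' Derive labels from a drug-status snapshot
#'
#' Positives are genes with at least one approved or clinical-stage record
#' matching the phenotype (and the modality filter, if given); negatives are
#' genes whose phenotype-matching records are all discontinued. A gene with
#' both active and discontinued records is positive. Phenotype matching is
#' exact after case-folding.
#'
#' @param phenotype Phenotype to match.
#' @param drug_snapshot A `feature_snapshot` with schema "drugdb".
#' @param modalities Optional modality filter (e.g. c("ADC", "CAR-T")).
#' @return A [label_set()].
#' @export
derive_labels <- function(phenotype, drug_snapshot, modalities = NULL) {
  stopifnot(inherits(drug_snapshot, "feature_snapshot"),
            drug_snapshot$source_name == "drugdb")
  tab <- drug_snapshot$table
  recs <- tab[tab$phenotype == tolower(trimws(phenotype)), , drop = FALSE]
  active <- recs$status %in% c("approved", "clinical")
  pos_ok <- active
  if (!is.null(modalities)) pos_ok <- pos_ok & recs$modality %in% modalities
  positives <- unique(recs$gene[pos_ok])
  all_disc <- vapply(split(recs$status, recs$gene),
                     function(s) all(s == "discontinued"), logical(1))
  negatives <- setdiff(names(all_disc)[all_disc], positives)
  label_set(positives, negatives, phenotype = phenotype,
            provenance = "drug_snapshot")
}

#' Join summary statistics with snapshot features into a feature matrix
#'
#' Left-joins every enabled catalog feature onto the dataset's genes: genes
#' absent from a snapshot get missing values for that snapshot's features
#' (absence of evidence is distinguishable from a measured zero; the impute
#' stage decides the fill). Derived features:
#' \itemize{
#'   \item `normal_expr_max` — max across a gtex-like snapshot's tissue columns;
#'   \item `normal_expr_pctile` — rank percentile of that max among all
#'     snapshot genes;
#'   \item `dependency_mean` / `essentiality_frac` — mean dependency and
#'     fraction of lines with dependency >= 0.5 across phenotype-matched
#'     `<phenotype>.<cell_line>` columns of a depmap-like snapshot (all
#'     columns when none match);
#'   \item `has_drug` / `has_adc` — 0/1 flags for active drug records in
#'     phenotypes other than the scored one (phenotype-matched records are
#'     reserved for label derivation, so therapeutic-availability features
#'     cannot replicate the label set).
#' }
#'
#' @param summary_table Genes-by-statistics matrix from [summarize_genes()].
#' @param snapshots Named list of `feature_snapshot` objects, names matching
#'   catalog `source` values.
#' @param catalog Feature catalog (see [default_catalog()]).
#' @param phenotype Project phenotype, used by depmap and drugdb derivations.
#' @return A `feature_matrix` object: genes x enabled features.
#' @export
enrich <- function(summary_table, snapshots = list(),
                   catalog = default_catalog(), phenotype = "unknown") {
  validate_catalog(catalog)
  genes <- rownames(summary_table)
  if (is.null(genes)) stop("summary table needs gene rownames")
  cat_on <- catalog[catalog$enabled, , drop = FALSE]
  if (nrow(cat_on) == 0L) stop("no enabled features in catalog")
  vals <- matrix(NA_real_, length(genes), nrow(cat_on),
                 dimnames = list(genes, cat_on$name))
  for (i in seq_len(nrow(cat_on))) {
    f <- cat_on[i, ]
    vals[, i] <- resolve_feature(f, genes, summary_table, snapshots, phenotype)
  }
  structure(list(values = vals,
                 catalog = cat_on,
                 phenotype = phenotype,
                 provenance = stats::setNames(cat_on$source, cat_on$name)),
            class = "feature_matrix")
}

resolve_feature <- function(f, genes, summary_table, snapshots, phenotype) {
  if (f$source == "summary") {
    if (!f$column %in% colnames(summary_table)) {
      stop("enabled feature '", f$name, "' has no resolvable summary column '",
           f$column, "'")
    }
    return(summary_table[genes, f$column])
  }
  snap <- snapshots[[f$source]]
  if (is.null(snap)) {
    stop("enabled feature '", f$name, "' needs snapshot '", f$source,
         "', which was not supplied")
  }
  derived <- startsWith(f$column, "derived:")
  if (!derived) {
    tab <- snap$table
    if (!f$column %in% colnames(tab)) {
      stop("enabled feature '", f$name, "' has no resolvable column '",
           f$column, "' in snapshot '", f$source, "'")
    }
    return(tab[match(genes, rownames(tab)), f$column])
  }
  what <- sub("^derived:", "", f$column)
  switch(what,
    normal_expr_max = {
      m <- snap$table
      mx <- apply(m, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      mx[match(genes, rownames(m))]
    },
    normal_expr_pctile = {
      m <- snap$table
      mx <- apply(m, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      rank_pctile(mx)[match(genes, rownames(m))]
    },
    dependency_mean = depmap_derive(snap, genes, phenotype, "mean"),
    essentiality_frac = depmap_derive(snap, genes, phenotype, "frac"),
    has_drug = drug_flag(snap, genes, phenotype, adc_only = FALSE),
    has_adc = drug_flag(snap, genes, phenotype, adc_only = TRUE),
    stop("unknown derived feature '", what, "' for '", f$name, "'")
  )
}

depmap_derive <- function(snap, genes, phenotype, stat = c("mean", "frac")) {
  stat <- match.arg(stat)
  m <- snap$table
  prefix <- tolower(sub("\\..*$", "", colnames(m)))
  sel <- prefix == tolower(trimws(phenotype))
  if (!any(sel)) sel <- rep(TRUE, ncol(m))
  sub <- m[, sel, drop = FALSE]
  v <- apply(sub, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    if (stat == "mean") mean(x) else mean(x >= 0.5)
  })
  v[match(genes, rownames(m))]
}

# 0/1 availability of active (approved/clinical) drug records in phenotypes
# other than the scored one; genes absent from the drug table stay missing.
drug_flag <- function(snap, genes, phenotype, adc_only = FALSE) {
  stopifnot(snap$source_name == "drugdb")
  tab <- snap$table
  other <- tab[tab$phenotype != tolower(trimws(phenotype)), , drop = FALSE]
  hit <- other$status %in% c("approved", "clinical")
  if (adc_only) hit <- hit & other$modality == "ADC"
  flagged <- unique(other$gene[hit])
  out <- as.numeric(genes %in% flagged)
  out[!genes %in% tab$gene] <- NA_real_
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d genes x %d features (phenotype '%s')\n",
              nrow(x$values), ncol(x$values), x$phenotype))
  cat("  categories:", paste(unique(x$catalog$category), collapse = ", "), "\n")
  invisible(x)
}

#' Restricted normal-tissue expression filter
#'
#' Returns, in report order, the genes whose value on the given feature is
#' strictly below the `pct`-th percentile (linear interpolation between
#' closest ranks) of that feature's non-missing distribution across all genes
#' in the matrix. Genes with a missing value are never returned. The default
#' reproduces a "restricted normal expression" cut at the 20th percentile of
#' maximal normal-tissue expression.
#'
#' @param report A score report (see [score_genes()]).
#' @param matrix The `feature_matrix` the report was scored from.
#' @param feature Feature name to filter on.
#' @param pct Percentile threshold in (0, 100].
#' @return Character vector of gene symbols, ordered as in the report.
#' @export
restricted_normal_filter <- function(report, matrix,
                                     feature = "normal_expr_max", pct = 20) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!feature %in% colnames(matrix$values)) {
    stop("feature '", feature, "' not in matrix")
  }
  if (!(pct > 0 && pct <= 100)) stop("pct must be in (0, 100]")
  v <- matrix$values[, feature]
  if (all(is.na(v))) stop("feature '", feature, "' is all-missing")
  thr <- pct_linear(v, pct)
  genes <- report$gene
  keep <- !is.na(v[genes]) & v[genes] < thr
  genes[keep]
}
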