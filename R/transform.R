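#' Rescale a feature column to [0, 1]
#'
#' `rank_percentile` maps each non-missing value to (rank - 1)/(n - 1) with
#' average ties; `minmax` maps to (x - min)/(max - min). Constant columns map
#' to 0.5 (no information, neutral placement); missing values stay missing
#' for the impute stage.
#'
#' @param values Numeric vector (one feature across genes).
#' @param method "rank_percentile" or "minmax".
#' @return Numeric vector in [0, 1] with the original missing pattern.
#' @export
rescale_feature <- function(values, method = c("rank_percentile", "minmax")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  if (!any(ok)) stop("all-missing feature column")
  x <- values[ok]
  out <- rep(NA_real_, length(values))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out[ok] <- 0.5
    return(out)
  }
  out[ok] <- if (method == "rank_percentile") {
    (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  } else {
    (x - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Fill missing values of a rescaled feature column
#'
#' Operates on the [0, 1] scale, so fill constants are scale-free:
#' `zero` fills 0 (no evidence contributes nothing), `neutral` fills 0.5,
#' `min` and `median` fill that statistic of the non-missing entries.
#'
#' @param values Rescaled numeric vector, may contain missing.
#' @param method "zero", "neutral", "min" or "median".
#' @return Complete numeric vector in [0, 1].
#' @export
impute_feature <- function(values, method = c("zero", "neutral", "min", "median")) {
  method <- match.arg(method)
  miss <- is.na(values)
  if (!any(miss)) return(values)
  if (all(miss)) stop("all-missing feature column")
  fill <- switch(method,
                 zero = 0,
                 neutral = 0.5,
                 min = min(values[!miss]),
                 median = stats::median(values[!miss]))
  values[miss] <- fill
  values
}

#' Curving transform of a rescaled feature value
#'
#' `curve_value(v, c) = v^exp(c)`: a one-parameter family of monotone maps of
#' [0, 1] onto itself fixing 0 and 1. `c = 0` is the identity; positive `c`
#' gives a convex map that accentuates differences among high feature values
#' (the top-ranking targets); negative `c` gives a concave map that
#' accentuates differences among low values, useful for features where lower
#' values are preferred. The exponent `exp(c)` is positive for every real
#' `c`, so the map is strictly increasing and therefore rank-preserving
#' within a feature.
#'
#' @param v Numeric vector in [0, 1].
#' @param c Curve parameter (finite real; default bounds [-3, 3]).
#' @return `v^exp(c)`, in [0, 1].
#' @export
curve_value <- function(v, c) {
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("curved values must lie in [0, 1]")
  if (!is.finite(c)) stop("curve parameter must be finite")
  v^exp(c)
}

#' Rescale, impute and curve a feature matrix
#'
#' Applies the fixed pipeline order rescale -> impute -> curve column-wise.
#' The rescaled+imputed intermediate does not depend on weight or curve
#' parameters, so optimizers precompute it once via `stage = "imputed"` and
#' re-curve cheaply.
#'
#' @param fm A `feature_matrix` (or a plain numeric matrix, with methods
#'   taken from `catalog`).
#' @param catalog Catalog rows supplying rescale/impute methods and curves;
#'   defaults to the matrix's own catalog.
#' @param stage "curved" (full pipeline) or "imputed" (stop before curving).
#' @return Numeric matrix in [0, 1], genes x features.
#' @export
transform_features <- function(fm, catalog = NULL,
                               stage = c("curved", "imputed")) {
  stage <- match.arg(stage)
  if (inherits(fm, "feature_matrix")) {
    vals <- fm$values
    if (is.null(catalog)) catalog <- fm$catalog
  } else {
    vals <- as.matrix(fm)
    if (is.null(catalog)) stop("catalog required for a plain matrix")
  }
  idx <- match(colnames(vals), catalog$name)
  if (anyNA(idx)) stop("catalog missing feature(s): ",
                       paste(colnames(vals)[is.na(idx)], collapse = ", "))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    k <- idx[j]
    col <- impute_feature(rescale_feature(vals[, j], catalog$rescale[k]),
                          catalog$impute[k])
    if (stage == "curved") col <- curve_value(col, catalog$curve[k])
    out[, j] <- col
  }
  out
}

#' Score genes by the normalized weighted average of transformed features
#'
#' After rescale -> impute -> curve, each gene's score is
#' `sum_i w_i * t_gi / sum_i |w_i|` over enabled features with nonzero
#' weight. Scores lie in [-1, 1] ([0, 1] when all weights are nonnegative).
#' Genes are ranked by descending score; ties break by ascending gene symbol
#' so reports (and therefore MAP) are deterministic. Percentile 100 is the
#' top-ranked gene.
#'
#' @param fm A `feature_matrix` from [enrich()].
#' @param catalog Optional catalog override carrying weights/curves; defaults
#'   to the matrix's catalog.
#' @param labels Optional [label_set()]; when present, MAP is attached to the
#'   report (see [average_precision()]).
#' @param keep_features Include per-feature raw and transformed values in the
#'   report (default TRUE).
#' @return A `tr_report` data.frame: gene, score, rank, percentile, then
#'   `raw.<feature>` and `feat.<feature>` columns.
#' @export
score_genes <- function(fm, catalog = NULL, labels = NULL,
                        keep_features = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(catalog)) catalog <- fm$catalog
  validate_catalog(catalog)
  catalog <- catalog[catalog$enabled & catalog$name %in% colnames(fm$values), ,
                     drop = FALSE]
  use <- catalog$weight != 0
  if (!any(use)) stop("all feature weights are zero")
  active <- catalog[use, , drop = FALSE]
  curved <- transform_features(fm$values[, active$name, drop = FALSE], active)
  w <- active$weight
  score <- as.vector(curved %*% w) / sum(abs(w))
  genes <- rownames(fm$values)
  ord <- order(-score, genes)
  rank <- integer(length(score))
  rank[ord] <- seq_along(ord)
  n <- length(score)
  percentile <- if (n > 1) 100 * (n - rank) / (n - 1) else rep(100, n)
  rep_df <- data.frame(gene = genes, score = score, rank = rank,
                       percentile = percentile,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (keep_features) {
    raw <- fm$values[, active$name, drop = FALSE]
    colnames(raw) <- paste0("raw.", active$name)
    tf <- curved
    colnames(tf) <- paste0("feat.", active$name)
    rep_df <- cbind(rep_df, as.data.frame(raw, row.names = NULL),
                    as.data.frame(tf, row.names = NULL))
  }
  rep_df <- rep_df[order(rep_df$rank), , drop = FALSE]
  rownames(rep_df) <- NULL
  attr(rep_df, "phenotype") <- fm$phenotype
  if (!is.null(labels)) {
    ev <- average_precision(rep_df$gene, labels)
    attr(rep_df, "map") <- ev$map
    attr(rep_df, "map_mode") <- ev$mode
  }
  class(rep_df) <- c("tr_report", "data.frame")
  rep_df
}

#' @export
print.tr_report <- function(x, n = 10L, ...) {
  cat(sprintf("<tr_report> %d genes, phenotype '%s'", nrow(x),
              attr(x, "phenotype") %||% "unknown"))
  if (!is.null(attr(x, "map"))) {
    cat(sprintf(", MAP = %.4f (%s)", attr(x, "map"), attr(x, "map_mode")))
  }
  cat("\n")
  print.data.frame(utils::head(x[, c("gene", "score", "rank", "percentile")], n),
                   digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more gene(s)\n")
  invisible(x)
}

#' Write a score report to TSV or JSON
#'
#' Numeric columns are written at full precision; a read-back with
#' [read_report()] reproduces scores and ranks to 1e-12. JSON output carries
#' the MAP attribute when labels were present at scoring time.
#'
#' @param report A `tr_report`.
#' @param path Output path.
#' @param format "tsv" or "json".
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(report)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(phenotype = attr(report, "phenotype"),
                    genes = as.data.frame(report))
    if (!is.null(attr(report, "map"))) {
      payload$map <- attr(report, "map")
      payload$map_mode <- attr(report, "map_mode")
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read back a score report written by [write_report()]
#' @param path Report path.
#' @param format "tsv" or "json".
#' @return A `tr_report`.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(payload$genes, stringsAsFactors = FALSE)
    attr(df, "map") <- payload$map
    attr(df, "map_mode") <- payload$map_mode
    attr(df, "phenotype") <- payload$phenotype
  }
  if (nrow(df) > 0) df$rank <- as.integer(df$rank)
  class(df) <- c("tr_report", "data.frame")
  df
}
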