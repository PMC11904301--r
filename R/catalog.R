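#' Default feature catalog
#'
#' The catalog declares, per feature: its category (tumor expression, normal
#' expression, localization, annotation, therapeutic availability), direction
#' (whether higher or lower values mark a better target), the rescale and
#' imputation method, the signed weight and the curve parameter, the snapshot
#' it resolves against and the column (or derived quantity) it reads.
#'
#' Directionality is folded into the default weight sign: lower-is-better
#' features (normal-tissue expression) start at weight -1, everything else at
#' +1; all weights and curves are free parameters for the optimizer.
#'
#' The shipped catalog is a representative set spanning all four annotation
#' categories plus the tumor-expression summaries; users extend it by adding
#' rows that resolve against their own snapshot columns.
#'
#' @return A data.frame with one row per feature.
#' @export
default_catalog <- function() {
  spec <- function(name, category, direction, source, column,
                   rescale = "rank_percentile", impute = "zero") {
    data.frame(name = name, category = category, direction = direction,
               rescale = rescale, impute = impute,
               weight = if (direction == "lower_better") -1 else 1,
               curve = 0, enabled = TRUE,
               source = source, column = column,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("expr_mean",         "tumor_expression", "higher_better", "summary", "mean",   impute = "min"),
    spec("expr_median",       "tumor_expression", "higher_better", "summary", "median", impute = "min"),
    spec("expr_max",          "tumor_expression", "higher_better", "summary", "max",    impute = "min"),
    spec("expr_q75",          "tumor_expression", "higher_better", "summary", "q75",    impute = "min"),
    spec("frac_expressed",    "tumor_expression", "higher_better", "summary", "frac_expressed",
         rescale = "minmax", impute = "min"),
    spec("normal_expr_max",   "normal_expression", "lower_better", "gtex_like", "derived:normal_expr_max",
         impute = "neutral"),
    spec("normal_expr_pctile","normal_expression", "lower_better", "gtex_like", "derived:normal_expr_pctile",
         impute = "neutral"),
    spec("surface_evidence",  "localization", "higher_better", "surface_evidence", "evidence_score",
         rescale = "minmax"),
    spec("compartments_score","localization", "higher_better", "surface_evidence", "compartments_score",
         rescale = "minmax"),
    spec("dependency_mean",   "annotation", "higher_better", "depmap_like", "derived:dependency_mean",
         impute = "neutral"),
    spec("essentiality_frac", "annotation", "higher_better", "depmap_like", "derived:essentiality_frac",
         rescale = "minmax", impute = "neutral"),
    spec("has_drug",          "therapeutic", "higher_better", "drugdb", "derived:has_drug",
         rescale = "minmax"),
    spec("has_adc",           "therapeutic", "higher_better", "drugdb", "derived:has_adc",
         rescale = "minmax"),
    spec("pmtl_flag",         "therapeutic", "higher_better", "pmtl_like", "pmtl_flag",
         rescale = "minmax")
  )
}

catalog_categories <- c("tumor_expression", "normal_expression",
                        "localization", "annotation", "therapeutic")
rescale_methods <- c("rank_percentile", "minmax")
impute_methods <- c("zero", "neutral", "min", "median")

#' Validate a feature catalog
#'
#' Checks uniqueness of names, known categories/methods, finite weights and
#' curves. Returns the catalog invisibly; stops on violation.
#' @param catalog A catalog data.frame (see [default_catalog()]).
#' @export
validate_catalog <- function(catalog) {
  need <- c("name", "category", "direction", "rescale", "impute",
            "weight", "curve", "enabled", "source", "column")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) stop("catalog missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$name)) stop("duplicate feature names in catalog")
  if (!all(catalog$category %in% catalog_categories)) {
    stop("unknown feature category: ",
         paste(setdiff(catalog$category, catalog_categories), collapse = ", "))
  }
  if (!all(catalog$direction %in% c("higher_better", "lower_better"))) {
    stop("direction must be higher_better or lower_better")
  }
  if (!all(catalog$rescale %in% rescale_methods)) {
    stop("unknown rescale method: ",
         paste(setdiff(catalog$rescale, rescale_methods), collapse = ", "))
  }
  if (!all(catalog$impute %in% impute_methods)) {
    stop("unknown impute method: ",
         paste(setdiff(catalog$impute, impute_methods), collapse = ", "))
  }
  if (!all(is.finite(catalog$weight)) || !all(is.finite(catalog$curve))) {
    stop("weights and curves must be finite")
  }
  invisible(catalog)
}

#' Apply per-feature overrides to a catalog
#'
#' `overrides` is a list of lists, each with a `name` plus any of
#' `enabled`, `weight`, `curve`, `rescale`, `impute`.
#' @keywords internal
apply_catalog_overrides <- function(catalog, overrides) {
  for (ov in overrides) {
    if (is.null(ov$name)) stop("feature override without a name")
    i <- match(ov$name, catalog$name)
    if (is.na(i)) stop("feature override for unknown feature: ", ov$name)
    for (f in c("enabled", "weight", "curve", "rescale", "impute")) {
      if (!is.null(ov[[f]])) catalog[[f]][i] <- ov[[f]]
    }
    extra <- setdiff(names(ov), c("name", "enabled", "weight", "curve",
                                  "rescale", "impute"))
    if (length(extra)) stop("unknown feature override key(s): ",
                            paste(extra, collapse = ", "))
  }
  validate_catalog(catalog)
  catalog
}
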