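#' Average precision of a ranking against labeled targets
#'
#' For each known positive p, precision-at-rank(p) is the number of positives
#' at or above p's rank divided by that rank; AP is the mean over positives.
#' Two negative-handling modes are provided because a drug-derived label set
#' carries discontinued-target negatives whose treatment is a modeling
#' choice:
#' \describe{
#'   \item{full}{AP over the full ranking; every unlabeled gene counts as
#'     non-relevant. Default when no negatives are present.}
#'   \item{labeled_only}{the ranking is first restricted to the labeled genes
#'     (positives and negatives) preserving order, then AP is computed; the
#'     score then measures only how positives order against the known
#'     negatives. Default when negatives are present.}
#' }
#'
#' @param ranking Character vector of genes, best first, no duplicates.
#' @param labels A [label_set()]; positives must be non-empty and contained
#'   in the ranking (genes outside the ranking are dropped with a warning).
#' @param mode "auto", "full" or "labeled_only".
#' @return A `tr_evaluation`: list(map, per_positive, mode, n_positives,
#'   n_negatives).
#' @export
average_precision <- function(ranking, labels,
                              mode = c("auto", "full", "labeled_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "label_set"))
  if (anyDuplicated(ranking)) stop("ranking contains duplicate genes")
  pos <- labels$positives
  neg <- labels$negatives
  drop <- setdiff(c(pos, neg), ranking)
  if (length(drop)) {
    warning("dropping ", length(drop),
            " labeled gene(s) outside the scoring universe: ",
            paste(utils::head(drop, 5), collapse = ", "), call. = FALSE)
    pos <- intersect(pos, ranking)
    neg <- intersect(neg, ranking)
  }
  if (length(pos) == 0L) stop("no known positives within the ranking")
  if (mode == "auto") mode <- if (length(neg)) "labeled_only" else "full"
  if (mode == "labeled_only") {
    if (length(neg) == 0L) stop("labeled_only mode requires known negatives")
    ranking <- ranking[ranking %in% c(pos, neg)]
  }
  is_pos <- ranking %in% pos
  cum_pos <- cumsum(is_pos)
  rk <- which(is_pos)
  prec <- cum_pos[rk] / rk
  per_positive <- data.frame(gene = ranking[rk], rank = rk, precision = prec,
                             stringsAsFactors = FALSE)
  structure(list(map = mean(prec),
                 per_positive = per_positive,
                 mode = mode,
                 n_positives = length(pos),
                 n_negatives = length(neg)),
            class = "tr_evaluation")
}

#' @export
print.tr_evaluation <- function(x, ...) {
  cat(sprintf("<tr_evaluation> AP = %.4f (%s; %d positive(s), %d negative(s))\n",
              x$map, x$mode, x$n_positives, x$n_negatives))
  print(x$per_positive, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Mean average precision over several phenotype projects
#'
#' The unweighted arithmetic mean of per-project MAP values; the multi-cancer
#' optimization objective.
#'
#' @param results List of `tr_evaluation` objects (or bare numeric MAPs).
#' @return Mean MAP in [0, 1].
#' @export
map_over_projects <- function(results) {
  if (length(results) == 0L) stop("no evaluation results")
  maps <- vapply(results, function(r) {
    if (inherits(r, "tr_evaluation")) r$map else as.numeric(r)
  }, numeric(1))
  mean(maps)
}
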