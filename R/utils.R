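#' Linear-interpolation percentile
#'
#' One percentile definition is used throughout the package (feature
#' rescaling oracles, the restricted normal-tissue filter, snapshot-derived
#' percentile features): linear interpolation between closest order
#' statistics, i.e. [stats::quantile()] type 7. Missing values are dropped.
#'
#' @param x Numeric vector.
#' @param pct Percentile in (0, 100].
#' @return The interpolated percentile value.
#' @keywords internal
pct_linear <- function(x, pct) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("all values missing; percentile undefined")
  unname(stats::quantile(x, probs = pct / 100, type = 7, names = FALSE))
}

#' Rank-based percentile of each element within its own vector
#'
#' Returns 100 * (rank - 1) / (n - 1) with average ties over the non-missing
#' entries; missing stays missing; a length-1 distribution maps to 50. Used
#' for snapshot-derived percentile features, matching the rank_percentile
#' rescale definition.
#' @keywords internal
rank_pctile <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  if (n == 1L) { out[ok] <- 50; return(out) }
  out[ok] <- 100 * (rank(x[ok], ties.method = "average") - 1) / (n - 1)
  out
}

#' Validate gene symbols: uppercase, non-empty
#' @keywords internal
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("empty gene symbol encountered")
  x
}

#' Collapse duplicate gene rows of a numeric matrix
#'
#' @param m Numeric matrix with (possibly duplicated) rownames.
#' @param aggregate One of "max", "mean", "error".
#' @keywords internal
collapse_duplicates <- function(m, aggregate = c("max", "mean", "error"),
                                what = "gene") {
  aggregate <- match.arg(aggregate)
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  if (aggregate == "error") {
    stop("duplicate ", what, " symbols with aggregation disabled: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  fun <- if (aggregate == "max") {
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  warning("collapsing ", sum(duplicated(ids)), " duplicate ", what,
          " row(s) by ", aggregate, call. = FALSE)
  uid <- unique(ids)
  out <- matrix(NA_real_, length(uid), ncol(m),
                dimnames = list(uid, colnames(m)))
  for (g in uid) {
    sub <- m[ids == g, , drop = FALSE]
    out[g, ] <- apply(sub, 2, fun)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
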