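#' Expression dataset container
#'
#' A validated genes-by-samples expression matrix with a cancer phenotype
#' label. Gene symbols are uppercased and must be unique; duplicate input
#' rows are collapsed by the configured aggregation policy. Missing cells are
#' allowed and propagate through summarization to the downstream imputation
#' stage (they are never silently zero-filled).
#'
#' @param values Numeric matrix, rownames = gene symbols, colnames = samples.
#' @param phenotype Free-text cancer phenotype label (e.g. "NBL").
#' @param units Either "log2" or "linear" expression intensity.
#' @param metadata Named list of free-text provenance fields.
#' @param aggregate Duplicate-gene policy: "max" (default), "mean" or "error".
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, phenotype, units = c("log2", "linear"),
                               metadata = list(),
                               aggregate = c("max", "mean", "error")) {
  units <- match.arg(units)
  aggregate <- match.arg(aggregate)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (ncol(values) == 0L) stop("expression dataset has zero samples")
  rownames(values) <- normalize_symbols(rownames(values))
  values <- collapse_duplicates(values, aggregate)
  all_miss <- rowSums(!is.na(values)) == 0L
  if (any(all_miss)) {
    warning(sum(all_miss), " gene(s) have all-missing expression values",
            call. = FALSE)
  }
  structure(
    list(values = values, phenotype = as.character(phenotype)[1],
         units = units, metadata = metadata),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples, phenotype '%s' (%s)\n",
              nrow(x$values), ncol(x$values), x$phenotype, x$units))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression dataset from TSV, CSV or GCT
#'
#' TSV/CSV: first column gene symbols, header row of sample identifiers,
#' remaining columns numeric. GCT v1.2: "#1.2" line, dimensions line, then a
#' header with Name and Description columns. Non-numeric cells become missing
#' with a warning; duplicate symbols collapse by the aggregation policy.
#'
#' @param path Path to the file.
#' @param format One of "tsv", "csv", "gct"; default guessed from extension.
#' @param units "log2" or "linear".
#' @param phenotype Phenotype label attached to the dataset.
#' @param aggregate Duplicate-gene policy, see [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct"),
                            units = c("log2", "linear"), phenotype = "unknown",
                            aggregate = c("max", "mean", "error")) {
  format <- match.arg(format)
  units <- match.arg(units)
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", gct = "gct", "tsv")
  }
  if (format == "gct") {
    tab <- read_gct(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "", colClasses = "character")
    if (ncol(df) < 2L) stop("expression file has zero sample columns")
    tab <- df_to_numeric_matrix(df, id_col = 1L)
  }
  expression_dataset(tab, phenotype = phenotype, units = units,
                     metadata = list(source = path),
                     aggregate = aggregate)
}

# Character data frame -> numeric matrix keyed by an identifier column.
# Non-numeric cells become NA with one warning.
df_to_numeric_matrix <- function(df, id_col = 1L) {
  ids <- as.character(df[[id_col]])
  num <- df[-id_col]
  m <- matrix(NA_real_, nrow(df), ncol(num),
              dimnames = list(ids, names(num)))
  bad <- 0L
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- bad + sum(is.na(v) & !is.na(num[[j]]) &
                       !(trimws(num[[j]]) %in% c("", "NA", "NaN", "na")))
    m[, j] <- v
  }
  if (bad > 0L) {
    warning(bad, " non-numeric cell(s) treated as missing", call. = FALSE)
  }
  m
}

# GCT v1.2 reader: version line, dims line, header (Name, Description, samples).
read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1], "#1.2")) {
    stop("not a GCT v1.2 file: ", path)
  }
  dims <- scan(text = lines[2], what = integer(), quiet = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "",
                          colClasses = "character")
  if (ncol(df) < 3L) stop("GCT file has zero sample columns")
  if (!is.na(dims[1]) && nrow(df) != dims[1]) {
    warning("GCT dimension line says ", dims[1], " rows, file has ", nrow(df),
            call. = FALSE)
  }
  m <- df_to_numeric_matrix(df[-2L], id_col = 1L)  # drop Description
  m
}

# Registered gene-level summary statistics; frac_expressed takes a threshold.
summary_stat_funs <- function(threshold = 0) {
  list(
    mean   = function(v) mean(v),
    median = function(v) stats::median(v),
    max    = function(v) max(v),
    min    = function(v) min(v),
    q25    = function(v) stats::quantile(v, 0.25, type = 7, names = FALSE),
    q75    = function(v) stats::quantile(v, 0.75, type = 7, names = FALSE),
    frac_expressed = function(v) mean(v > threshold)
  )
}

#' Per-gene summary statistics of an expression dataset
#'
#' Computes one row per gene over the non-missing samples. Genes with
#' all-missing values yield missing statistics. Available statistics:
#' mean, median, max, min, q25, q75 and frac_expressed (fraction of samples
#' strictly above `threshold`).
#'
#' @param ds An [expression_dataset()].
#' @param stats Character vector of statistic names.
#' @param threshold Expression threshold for `frac_expressed`.
#' @return Numeric genes-by-statistics matrix.
#' @export
summarize_genes <- function(ds,
                            stats = c("mean", "median", "max", "q75",
                                      "frac_expressed"),
                            threshold = 0) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(stats) == 0L) stop("empty statistic list")
  funs <- summary_stat_funs(threshold)
  unknown <- setdiff(stats, names(funs))
  if (length(unknown)) stop("unknown summary statistic: ",
                            paste(unknown, collapse = ", "))
  out <- matrix(NA_real_, nrow(ds$values), length(stats),
                dimnames = list(rownames(ds$values), stats))
  for (i in seq_len(nrow(ds$values))) {
    v <- ds$values[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    for (s in stats) out[i, s] <- funs[[s]](v)
  }
  out
}
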