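#' Snapshot schema registry
#'
#' Each snapshot is a TSV keyed by gene symbol standing in for a public
#' database export. Registered schemas:
#' \describe{
#'   \item{gtex_like}{gene + one numeric column per normal tissue (median
#'     expression per tissue).}
#'   \item{surface_evidence}{gene, `evidence_score` (0-5 surface-proteomics
#'     evidence), `compartments_score` (0-5 localization confidence).}
#'   \item{depmap_like}{gene + one numeric dependency column per cell line,
#'     named `<phenotype>.<cell_line>`; higher = stronger tumor dependency.}
#'   \item{pmtl_like}{gene, `pmtl_flag` (0/1 pediatric molecular target list
#'     membership).}
#'   \item{drugdb}{long table: gene, phenotype, modality (ADC, CAR-T, mAb,
#'     other), status (approved, clinical, discontinued); genes repeat.}
#' }
#' @return Named list of schema descriptors.
#' @export
snapshot_schemas <- function() {
  list(
    gtex_like = list(required = character(), key_unique = TRUE,
                     numeric = TRUE, min_value_cols = 1L),
    surface_evidence = list(required = c("evidence_score", "compartments_score"),
                            key_unique = TRUE, numeric = TRUE,
                            min_value_cols = 1L),
    depmap_like = list(required = character(), key_unique = TRUE,
                       numeric = TRUE, min_value_cols = 1L),
    pmtl_like = list(required = "pmtl_flag", key_unique = TRUE,
                     numeric = TRUE, min_value_cols = 1L),
    drugdb = list(required = c("phenotype", "modality", "status"),
                  key_unique = FALSE, numeric = FALSE, min_value_cols = 3L)
  )
}

drug_statuses <- c("approved", "clinical", "discontinued")
drug_modalities <- c("ADC", "CAR-T", "mAb", "other")

#' Load a feature snapshot TSV
#'
#' First column is the gene symbol; remaining columns per the registered
#' schema. Duplicate symbols in unique-key schemas collapse by element-wise
#' max with a warning; the drugdb schema keeps repeated genes (one row per
#' drug record).
#'
#' @param path TSV path.
#' @param schema_name One of [snapshot_schemas()] names.
#' @param version Free-text version/date tag.
#' @return A `feature_snapshot` object.
#' @export
load_snapshot <- function(path, schema_name, version = "") {
  schemas <- snapshot_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unregistered snapshot schema: ", schema_name)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", colClasses = "character")
  snapshot_from_df(df, schema_name, version = version, source = path)
}

#' Build a snapshot from an in-memory data.frame
#'
#' Same validation as [load_snapshot()]; used by the fixture generator and
#' tests.
#' @param df Data frame whose first column holds gene symbols.
#' @inheritParams load_snapshot
#' @export
snapshot_from_df <- function(df, schema_name, version = "", source = "memory") {
  schemas <- snapshot_schemas()
  schema <- schemas[[schema_name]]
  if (is.null(schema)) stop("unregistered snapshot schema: ", schema_name)
  if (nrow(df) == 0L) stop("empty snapshot table: ", source)
  names(df)[1] <- "gene"
  miss <- setdiff(schema$required, names(df))
  if (length(miss)) {
    stop("snapshot '", schema_name, "' missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$gene <- normalize_symbols(df$gene)
  if (schema$numeric) {
    if (ncol(df) - 1L < schema$min_value_cols) {
      stop("snapshot '", schema_name, "' needs at least ",
           schema$min_value_cols, " value column(s)")
    }
    m <- df_to_numeric_matrix(
      data.frame(gene = df$gene, lapply(df[-1], as.character),
                 check.names = FALSE, stringsAsFactors = FALSE),
      id_col = 1L)
    if (schema$key_unique) m <- collapse_duplicates(m, "max", what = "snapshot gene")
    table <- m
  } else {
    df$phenotype <- tolower(trimws(df$phenotype))
    df$status <- tolower(trimws(df$status))
    bad <- setdiff(unique(df$status), drug_statuses)
    if (length(bad)) stop("unknown drug status value(s): ",
                          paste(bad, collapse = ", "))
    table <- df
  }
  structure(list(source_name = schema_name, version = version,
                 source = source, table = table),
            class = "feature_snapshot")
}

#' @export
print.feature_snapshot <- function(x, ...) {
  n <- if (is.matrix(x$table)) nrow(x$table) else length(unique(x$table$gene))
  cat(sprintf("<feature_snapshot> schema '%s', %d genes, %d column(s)\n",
              x$source_name, n, ncol(x$table) - !is.matrix(x$table)))
  invisible(x)
}
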