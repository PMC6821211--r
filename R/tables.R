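#' Read a typed pipeline table from TSV
#'
#' Dispatches on `schema`:
#' \describe{
#'   \item{`viability`}{columns `cell_line_id`, `perturbagen_id`, `viability`,
#'     `metric_type`, plus optional `dose_um` and `assay_time_h`. Validated
#'     with [validateViabilityTable()].}
#'   \item{`annotation`}{columns `perturbagen_id`, `moa` (`;`-separated label
#'     set), optional `fingerprint` (bit string, e.g. `"0101..."`) and
#'     `max_tested_log10_conc`. The `moa` column is split into a list column
#'     `moa_labels`; fingerprints into an integer matrix attribute.}
#'   \item{`sensitivity`}{columns `cell_line_id`, `drug_id` and at least one
#'     of `auc`, `ln_ic50`.}
#'   \item{`baseline`}{a genes x cells numeric TSV matrix (first column
#'     `gene_id`); returned as a matrix.}
#' }
#' Unknown columns are preserved. Doses are micromolar.
#'
#' @param path TSV path.
#' @param schema one of `"viability"`, `"annotation"`, `"sensitivity"`,
#'   `"baseline"`.
#' @return A validated data.frame (or matrix for `"baseline"`).
#' @export
readPipelineTable <- function(path,
                              schema = c("viability", "annotation",
                                         "sensitivity", "baseline")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need_cols <- function(cols) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
      stop("schema '", schema, "': missing mandatory column(s): ",
           paste(miss, collapse = ", "))
  }
  switch(schema,
    viability = {
      need_cols(c("cell_line_id", "perturbagen_id", "viability",
                  "metric_type"))
      if (!"dose_um" %in% colnames(df)) df$dose_um <- NA_real_
      df$dose_um <- as.numeric(df$dose_um)
      df$viability <- as.numeric(df$viability)
      validateViabilityTable(df)
    },
    annotation = {
      need_cols(c("perturbagen_id", "moa"))
      df$moa_labels <- strsplit(as.character(df$moa), ";", fixed = TRUE)
      if (any(lengths(df$moa_labels) == 0) ||
          any(vapply(df$moa_labels, function(l) any(!nzchar(l)), logical(1))))
        stop("schema 'annotation': empty MoA label")
      if ("fingerprint" %in% colnames(df)) {
        bits <- strsplit(as.character(df$fingerprint), "")
        if (length(unique(lengths(bits))) > 1)
          stop("schema 'annotation': fingerprints differ in length")
        fp <- do.call(rbind, lapply(bits, as.integer))
        rownames(fp) <- df$perturbagen_id
        attr(df, "fingerprints") <- fp
      }
      df
    },
    sensitivity = {
      need_cols(c("cell_line_id", "drug_id"))
      if (!any(c("auc", "ln_ic50") %in% colnames(df)))
        stop("schema 'sensitivity': need an 'auc' or 'ln_ic50' column")
      df
    },
    baseline = {
      need_cols("gene_id")
      m <- as.matrix(df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
      mode(m) <- "numeric"
      rownames(m) <- df$gene_id
      m
    })
}

#' Validate a viability table
#'
#' Enforces the viability-table invariants: a single `metric_type` per table
#' (`"fraction"` or `"log_fold_change"`), non-negative fraction values, and no
#' duplicate (cell, perturbagen, dose) keys.
#'
#' @param df data.frame with viability-schema columns.
#' @return `df`, invisibly unchanged, or an error.
#' @export
validateViabilityTable <- function(df) {
  mt <- unique(df$metric_type)
  if (length(mt) != 1)
    stop("viability table: metric_type must be uniform, found: ",
         paste(mt, collapse = ", "))
  if (!mt %in% c("fraction", "log_fold_change"))
    stop("viability table: unknown metric_type ", sQuote(mt))
  if (mt == "fraction" && any(df$viability < 0))
    stop("viability table: fraction viability values must be >= 0")
  key <- paste(df$cell_line_id, df$perturbagen_id, df$dose_um, sep = "\r")
  if (anyDuplicated(key))
    stop("viability table: duplicate (cell, perturbagen, dose) keys")
  df
}

#' Write a viability, annotation or sensitivity table as TSV
#'
#' @param df data.frame (list columns such as `moa_labels` are collapsed with
#'   `;`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePipelineTable <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genes x cells baseline expression matrix as TSV
#' @param m numeric matrix with gene_id rownames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBaselineMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
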