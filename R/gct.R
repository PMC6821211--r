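#' Read a GCT 1.3 signature file
#'
#' Parses the GCT 1.3 text layout (version line `#1.3`; dimension line
#' `nrow ncol nrowmeta ncolmeta`; a header row; `ncolmeta` column-metadata
#' rows; `nrow` data rows). Rows are genes and columns are perturbation
#' instances, the layout used for landmark-gene signature matrices. Instance
#' metadata fields (`cell_line_id`, `perturbagen_id`, `perturbagen_type`,
#' `dose_um`, `time_h`) are taken from the column-metadata block when present
#' and defaulted to absent otherwise.
#'
#' @param path path to a GCT 1.3 text file.
#' @return A [SignatureSet-class].
#' @seealso [writeSignatureGCT()]
#' @export
readSignatureGCT <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed GCT (line 1): file has fewer than 3 lines")
  if (!grepl("^#1\\.3\\s*$", lines[1]))
    stop("malformed GCT (line 1): expected version line '#1.3', got ",
         sQuote(lines[1]))
  dims <- strsplit(trimws(lines[2]), "\t| +")[[1]]
  if (length(dims) != 4 || anyNA(suppressWarnings(as.integer(dims))))
    stop("malformed GCT (line 2): expected 4 integers 'nrow ncol nrmeta ncmeta'")
  dims <- as.integer(dims)
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  expected <- 3L + ncm + nr
  if (length(lines) < expected)
    stop("malformed GCT: declared ", nr, " data rows and ", ncm,
         " column-metadata rows but file ends at line ", length(lines))
  split_row <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  header <- split_row(3L)
  if (length(header) != 1L + nrm + nc)
    stop("malformed GCT (line 3): header has ", length(header),
         " fields, expected ", 1L + nrm + nc)
  rmeta_names <- if (nrm > 0) header[seq(2L, 1L + nrm)] else character()
  inst_ids <- header[(2L + nrm):(1L + nrm + nc)]
  cmeta <- list()
  for (k in seq_len(ncm)) {
    f <- split_row(3L + k)
    if (length(f) != 1L + nrm + nc)
      stop("malformed GCT (line ", 3L + k, "): column-metadata row has ",
           length(f), " fields, expected ", 1L + nrm + nc)
    cmeta[[f[1]]] <- f[(2L + nrm):(1L + nrm + nc)]
  }
  vals <- matrix(NA_real_, nr, nc)
  gene_ids <- character(nr)
  rmeta <- matrix(NA_character_, nr, nrm)
  for (k in seq_len(nr)) {
    f <- split_row(3L + ncm + k)
    if (length(f) != 1L + nrm + nc)
      stop("malformed GCT (line ", 3L + ncm + k, "): data row has ",
           length(f), " fields, expected ", 1L + nrm + nc)
    gene_ids[k] <- f[1]
    if (nrm > 0) rmeta[k, ] <- f[seq(2L, 1L + nrm)]
    v <- suppressWarnings(as.numeric(f[(2L + nrm):(1L + nrm + nc)]))
    if (anyNA(v))
      stop("malformed GCT (line ", 3L + ncm + k, "): non-numeric data value")
    vals[k, ] <- v
  }
  geneInfo <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (j in seq_along(rmeta_names)) geneInfo[[rmeta_names[j]]] <- rmeta[, j]
  if (!"gene_symbol" %in% colnames(geneInfo))
    geneInfo$gene_symbol <- geneInfo$gene_id
  grab <- function(name, default, as = identity) {
    if (name %in% names(cmeta)) {
      x <- cmeta[[name]]
      x[x %in% c("na", "NA", "-666", "")] <- NA
      as(x)
    } else rep(default, nc)
  }
  instanceInfo <- data.frame(
    instance_id = inst_ids,
    cell_line_id = grab("cell_line_id", NA_character_, as.character),
    perturbagen_id = grab("perturbagen_id", NA_character_, as.character),
    perturbagen_type = grab("perturbagen_type", "control", as.character),
    dose_um = grab("dose_um", NA_real_, as.numeric),
    time_h = grab("time_h", NA_real_, as.numeric),
    stringsAsFactors = FALSE)
  SignatureSet(t(vals), instanceInfo, geneInfo)
}

#' Write a SignatureSet as GCT 1.3 text
#'
#' The file is re-readable by [readSignatureGCT()] with equality of values
#' (at the stored precision, 17 significant digits: exact for doubles) and
#' metadata.
#'
#' @param sigset a [SignatureSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSignatureGCT <- function(sigset, path) {
  stopifnot(is(sigset, "SignatureSet"))
  validObject(sigset)
  m <- SummarizedExperiment::assay(sigset, "zscore")  # genes x instances
  gi <- geneInfo(sigset)
  ii <- instanceInfo(sigset)
  rmeta_names <- setdiff(colnames(gi), "gene_id")
  cmeta_names <- c("cell_line_id", "perturbagen_id", "perturbagen_type",
                   "dose_um", "time_h")
  nrm <- length(rmeta_names); ncm <- length(cmeta_names)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) {
    out <- as.character(x)
    if (is.numeric(x)) out <- sprintf("%.17g", x)
    out[is.na(x)] <- "na"
    out
  }
  writeLines("#1.3", con)
  writeLines(paste(nrow(m), ncol(m), nrm, ncm, sep = "\t"), con)
  writeLines(paste(c("id", rmeta_names, colnames(m)), collapse = "\t"), con)
  for (nm in cmeta_names)
    writeLines(paste(c(nm, rep("na", nrm), fmt(ii[[nm]])), collapse = "\t"),
               con)
  body <- cbind(gi$gene_id,
                if (nrm) sapply(rmeta_names, function(nm) fmt(gi[[nm]])),
                matrix(sprintf("%.17g", m), nrow(m), ncol(m)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
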