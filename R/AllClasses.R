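#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd var quantile setNames coef lm residuals p.adjust
#'   prcomp rnorm runif rbinom predict complete.cases median aggregate
#' @importFrom utils read.delim write.table head
NULL

PERTURBAGEN_TYPES <- c("compound", "shRNA", "control")

#' SignatureSet: a matrix of perturbation signatures with metadata
#'
#' Container for replicate-collapsed differential-expression z-scores over the
#' landmark gene space. Internally a [SummarizedExperiment::SummarizedExperiment]
#' with genes as rows and perturbation instances as columns (the Bioconductor
#' convention); [sigMatrix()] returns the instances-by-genes orientation used
#' by the viability models.
#'
#' Instance metadata columns: `instance_id`, `cell_line_id`, `perturbagen_id`,
#' `perturbagen_type` (one of compound/shRNA/control), `dose_um` (micromolar;
#' `NA` for shRNA and controls), `time_h`. Gene metadata: `gene_id`,
#' `gene_symbol`.
#'
#' @slot .Data inherits all SummarizedExperiment slots; the single assay is
#'   named `"zscore"`.
#' @export
setClass("SignatureSet", contains = "SummarizedExperiment")

.validSignatureSet <- function(object) {
  msg <- character()
  if (!"zscore" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'zscore' is required")
  v <- SummarizedExperiment::assay(object, "zscore")
  if (!all(is.finite(v)))
    msg <- c(msg, "signature values must all be finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("instance_id", "cell_line_id", "perturbagen_id",
            "perturbagen_type", "dose_um", "time_h")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing instance metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (anyDuplicated(cd$instance_id))
      msg <- c(msg, "instance_ids must be unique")
    bad <- !cd$perturbagen_type %in% PERTURBAGEN_TYPES
    if (any(bad))
      msg <- c(msg, "perturbagen_type must be compound, shRNA or control")
    is_cmp <- cd$perturbagen_type == "compound"
    if (any(is_cmp & is.na(cd$dose_um)))
      msg <- c(msg, "dose_um is mandatory for compound instances")
    if (any(!is_cmp & !is.na(cd$dose_um)))
      msg <- c(msg, "dose_um must be absent (NA) for non-compound instances")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene_id" %in% colnames(rd))
    msg <- c(msg, "missing gene metadata column gene_id")
  else if (anyDuplicated(rd$gene_id))
    msg <- c(msg, "gene_ids must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("SignatureSet", .validSignatureSet)

#' Construct a SignatureSet
#'
#' @param values numeric matrix, instances x genes, all finite.
#' @param instanceInfo data.frame with one row per instance; columns
#'   `instance_id`, `cell_line_id`, `perturbagen_id`, `perturbagen_type`,
#'   `dose_um`, `time_h`. `dose_um` must be present iff the instance is a
#'   compound treatment.
#' @param geneInfo data.frame with columns `gene_id` and optionally
#'   `gene_symbol`; defaults to the column names of `values`.
#' @return A [SignatureSet-class] object.
#' @examples
#' x <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' info <- data.frame(instance_id = c("i1", "i2"), cell_line_id = "A375",
#'                    perturbagen_id = "drugA", perturbagen_type = "compound",
#'                    dose_um = c(1, 10), time_h = 24)
#' ss <- SignatureSet(x, info)
#' dim(sigMatrix(ss))
#' @export
SignatureSet <- function(values, instanceInfo, geneInfo = NULL) {
  values <- as.matrix(values)
  if (is.null(geneInfo)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("g", seq_len(ncol(values)))
    geneInfo <- data.frame(gene_id = ids, gene_symbol = ids,
                           stringsAsFactors = FALSE)
  }
  if (!"gene_symbol" %in% colnames(geneInfo))
    geneInfo$gene_symbol <- geneInfo$gene_id
  instanceInfo <- as.data.frame(instanceInfo)
  if (!"dose_um" %in% colnames(instanceInfo)) instanceInfo$dose_um <- NA_real_
  instanceInfo$dose_um <- as.numeric(instanceInfo$dose_um)
  instanceInfo$time_h <- as.numeric(instanceInfo$time_h)
  m <- t(values)                         # store genes x instances
  rownames(m) <- geneInfo$gene_id
  colnames(m) <- instanceInfo$instance_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(zscore = m),
    rowData = S4Vectors::DataFrame(geneInfo, row.names = geneInfo$gene_id),
    colData = S4Vectors::DataFrame(instanceInfo,
                                   row.names = instanceInfo$instance_id))
  new("SignatureSet", se)
}

#' MatchedDataset: aligned signatures and viability outcomes
#'
#' Training unit for the viability models: a signature matrix `X` (instances x
#' genes) with a 1:1 aligned viability vector `y` in the source metric, plus
#' per-row matching provenance.
#'
#' @slot X numeric matrix, instances x genes.
#' @slot y numeric viability vector aligned to the rows of `X`.
#' @slot meta data.frame with one row per instance: `instance_id`,
#'   `cell_line_id`, `perturbagen_id`, `time_h`, `dose_signature_um`,
#'   `dose_viability_um`, `delta_log10_dose`.
#' @slot metricType `"fraction"` or `"log_fold_change"`.
#' @slot tag character label, e.g. `"compound-24h"`.
#' @export
setClass("MatchedDataset",
         representation(X = "matrix", y = "numeric", meta = "data.frame",
                        metricType = "character", tag = "character"))

setValidity("MatchedDataset", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "rows of X and entries of y must align 1:1")
  if (nrow(object@meta) != nrow(object@X))
    msg <- c(msg, "meta must have one row per instance")
  if (!object@metricType %in% c("fraction", "log_fold_change"))
    msg <- c(msg, "metricType must be 'fraction' or 'log_fold_change'")
  if (length(msg)) msg else TRUE
})

#' Construct a MatchedDataset
#' @param X instances x genes matrix.
#' @param y aligned viability vector.
#' @param meta per-instance provenance data.frame.
#' @param metricType `"fraction"` or `"log_fold_change"`.
#' @param tag dataset label.
#' @return A [MatchedDataset-class].
#' @export
MatchedDataset <- function(X, y, meta, metricType, tag = "") {
  new("MatchedDataset", X = as.matrix(X), y = as.numeric(y),
      meta = as.data.frame(meta), metricType = metricType, tag = tag)
}

#' ViabilityModel: a ridge cell-viability-signature model
#'
#' Per-gene coefficient vector (the operational cell viability signature, CVS)
#' plus unpenalized intercept from an L2-regularized linear fit of viability on
#' signature z-scores.
#'
#' @slot beta named numeric vector of per-gene coefficients; names are the
#'   gene order enforced at prediction time.
#' @slot intercept numeric(1).
#' @slot alpha ridge penalty (must be > 0).
#' @slot tag training-data label.
#' @export
setClass("ViabilityModel",
         representation(beta = "numeric", intercept = "numeric",
                        alpha = "numeric", tag = "character"))

setValidity("ViabilityModel", function(object) {
  msg <- character()
  if (is.null(names(object@beta)))
    msg <- c(msg, "beta must be named by gene_id")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: planted latents for the synthetic screens
#'
#' Ground-truth container produced by [buildWorld()]. All downstream synthetic
#' screens are deterministic functions of this object, so tests can compare
#' recovered quantities against the planted values.
#'
#' @slot config the [worldConfig()] list used to build the world.
#' @slot w unit-norm viability loading vector (length G): the planted CVS.
#' @slot moaVectors K x G matrix of unit-norm MoA signature components, each
#'   orthogonal to `w`.
#' @slot cellEffects C x G matrix of cell-line offset vectors.
#' @slot potency D x C matrix of pIC50 values (log10 micromolar).
#' @slot essentiality S x C matrix of shRNA essentialities (>= 0).
#' @slot moaOf integer vector length D: MoA class of each compound.
#' @slot pathwayOf integer vector length K: coarse pathway of each MoA class.
#' @slot shrnaTarget integer vector length S: target gene index of each shRNA.
#' @slot shrnaEfficiency numeric vector length S: per-shRNA knockdown
#'   efficiency in (0, 1]; scales both the essentiality phenotype and the
#'   knockdown depth at the target gene.
#' @slot shrnaOfftarget S x G matrix of unit-norm per-shRNA off-target
#'   (seed-sequence) signature components, orthogonal to `w`; reproducible
#'   across cells and times for a given shRNA.
#' @slot fingerprintPrototypes K x n_bits 0/1 matrix of per-class prototypes.
#' @slot rho per-cell CVS propensity (length C).
#' @slot tissue,msi per-cell tissue labels and MSI flags.
#' @slot glds per-cell general-level-of-drug-sensitivity offsets (correlated
#'   with `rho`).
#' @slot pathwayState C x K matrix: cell-specific MoA-class interaction state.
#' @slot regulons named list of weighted gene sets (includes the planted `w`
#'   itself and random decoys).
#' @export
setClass("SyntheticWorld",
         representation(config = "list", w = "numeric", moaVectors = "matrix",
                        cellEffects = "matrix", potency = "matrix",
                        essentiality = "matrix", moaOf = "integer",
                        pathwayOf = "integer", shrnaTarget = "integer",
                        shrnaEfficiency = "numeric",
                        shrnaOfftarget = "matrix",
                        fingerprintPrototypes = "matrix", rho = "numeric",
                        tissue = "character", msi = "logical",
                        glds = "numeric", pathwayState = "matrix",
                        regulons = "list"))

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@w^2)) - 1) > 1e-8)
    msg <- c(msg, "planted w must have unit norm")
  dots <- drop(object@moaVectors %*% object@w)
  if (any(abs(dots) > 1e-8))
    msg <- c(msg, "MoA vectors must be orthogonal to w")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("SignatureSet:", ncol(object), "instances x", nrow(object), "genes\n")
  cat("  perturbagen types:",
      paste(names(table(cd$perturbagen_type)), table(cd$perturbagen_type),
            sep = "=", collapse = ", "), "\n")
  cat("  times (h):", paste(sort(unique(cd$time_h)), collapse = ", "), "\n")
})

setMethod("show", "MatchedDataset", function(object) {
  cat("MatchedDataset", sQuote(object@tag), ":", nrow(object@X),
      "instances x", ncol(object@X), "genes; metric:", object@metricType, "\n")
})

setMethod("show", "ViabilityModel", function(object) {
  cat("ViabilityModel", sQuote(object@tag), ":", length(object@beta),
      "genes; alpha =", object@alpha,
      "; intercept =", signif(object@intercept, 4), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cfg <- object@config
  cat("SyntheticWorld:", cfg$n_genes, "genes,", cfg$n_cells, "cells,",
      cfg$n_compounds, "compounds,", cfg$n_shrnas, "shRNAs,",
      cfg$n_moa_classes, "MoA classes (seed", cfg$seed, ")\n")
})
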