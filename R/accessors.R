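#' @name SignatureSet-accessors
#' @title Accessors for SignatureSet, MatchedDataset and ViabilityModel
#' @description `sigMatrix()` returns the instances-by-genes z-score matrix;
#'   `instanceInfo()` and `geneInfo()` return the metadata as plain data
#'   frames; `instanceIds()`/`geneIds()` the corresponding identifiers.
#'   For a `MatchedDataset`, `sigMatrix()` is the aligned `X` and
#'   `viability()` the aligned `y`; `datasetTag()` returns the provenance tag.
#'   `modelCoef()` returns the named coefficient vector of a `ViabilityModel`.
#' @param x a SignatureSet, MatchedDataset or ViabilityModel.
NULL

#' @rdname SignatureSet-accessors
#' @export
setGeneric("sigMatrix", function(x) standardGeneric("sigMatrix"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("viability", function(x) standardGeneric("viability"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("modelCoef", function(x) standardGeneric("modelCoef"))

#' @rdname SignatureSet-accessors
setMethod("sigMatrix", "SignatureSet", function(x)
  t(SummarizedExperiment::assay(x, "zscore")))
#' @rdname SignatureSet-accessors
setMethod("instanceInfo", "SignatureSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname SignatureSet-accessors
setMethod("geneInfo", "SignatureSet", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))
#' @rdname SignatureSet-accessors
setMethod("instanceIds", "SignatureSet", function(x) colnames(x))
#' @rdname SignatureSet-accessors
setMethod("geneIds", "SignatureSet", function(x) rownames(x))

#' @rdname SignatureSet-accessors
setMethod("sigMatrix", "MatchedDataset", function(x) x@X)
#' @rdname SignatureSet-accessors
setMethod("instanceInfo", "MatchedDataset", function(x) x@meta)
#' @rdname SignatureSet-accessors
setMethod("geneIds", "MatchedDataset", function(x) colnames(x@X))
#' @rdname SignatureSet-accessors
setMethod("viability", "MatchedDataset", function(x) x@y)
#' @rdname SignatureSet-accessors
setMethod("datasetTag", "MatchedDataset", function(x) x@tag)

#' @rdname SignatureSet-accessors
setMethod("modelCoef", "ViabilityModel", function(x) x@beta)
#' @rdname SignatureSet-accessors
setMethod("datasetTag", "ViabilityModel", function(x) x@tag)

#' Subset a SignatureSet by instances and/or genes
#'
#' @param x a SignatureSet.
#' @param instances,genes logical, integer or character index into instances
#'   (columns of the underlying experiment) and genes (rows).
#' @return A SignatureSet.
#' @export
subsetSignatures <- function(x, instances = NULL, genes = NULL) {
  stopifnot(is(x, "SignatureSet"))
  if (!is.null(genes)) x <- x[genes, ]
  if (!is.null(instances)) x <- x[, instances]
  x
}
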