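#' Moderated z-score (MODZ) consensus of a signature group
#'
#' For `n >= 2` member signatures, a pairwise Spearman correlation matrix is
#' computed (average-rank ties); its diagonal is set to 0, then negative
#' entries are clamped to 0.01. Each signature's weight is its row sum,
#' normalized to sum 1, and the consensus is the weighted average of the
#' member signatures. A single signature is returned unchanged with weight 1.
#'
#' A constant member row leaves the Spearman correlation undefined; such
#' correlations are treated as 0 and then clamped like any other
#' non-positive entry, with a warning.
#'
#' @param signatures numeric matrix, members x genes (G >= 2).
#' @return A list of class `"ConsensusResult"`: `consensus` (length-G
#'   vector), `weights` (length-n, sums to 1), `member_ids` (rownames of the
#'   input, if any).
#' @export
modz <- function(signatures) {
  signatures <- as.matrix(signatures)
  n <- nrow(signatures)
  if (n < 1 || ncol(signatures) < 2)
    stop("modz: need at least 1 signature over at least 2 genes")
  ids <- rownames(signatures)
  if (n == 1) {
    res <- list(consensus = drop(signatures[1, ]), weights = 1,
                member_ids = ids)
    class(res) <- "ConsensusResult"
    return(res)
  }
  if (any(apply(signatures, 1, function(r) length(unique(r)) == 1)))
    warning("modz: constant signature row; its correlations treated as 0")
  rho <- suppressWarnings(cor(t(signatures), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  rho[rho < 0] <- 0.01
  wts <- rowSums(rho)
  # degenerate case: every off-diagonal correlation exactly 0 (zeros are not
  # negative, so nothing is clamped) -> fall back to equal weights
  if (sum(wts) == 0) wts <- rep(1, n)
  wts <- wts / sum(wts)
  res <- list(consensus = drop(wts %*% signatures), weights = wts,
              member_ids = ids)
  class(res) <- "ConsensusResult"
  res
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult:", length(x$weights), "members,",
      length(x$consensus), "genes\n")
  invisible(x)
}

#' MODZ consensus per metadata group
#'
#' Groups the instances of a [SignatureSet-class] by one or more instance
#' metadata keys (e.g. `perturbagen_id`, or
#' `c("perturbagen_id", "cell_line_id")`) and computes the [modz()] consensus
#' of each group. Size-1 groups pass through with weight 1.
#'
#' @param sigset a [SignatureSet-class].
#' @param groupBy character vector of instance metadata column names.
#' @return A named list of `ConsensusResult`, one per group (names are the
#'   `.`-joined group keys).
#' @export
groupConsensus <- function(sigset, groupBy) {
  stopifnot(is(sigset, "SignatureSet"))
  ii <- instanceInfo(sigset)
  miss <- setdiff(groupBy, colnames(ii))
  if (length(miss))
    stop("groupConsensus: unknown metadata key(s): ",
         paste(miss, collapse = ", "))
  X <- sigMatrix(sigset)
  key <- do.call(paste, c(ii[groupBy], sep = "."))
  idx <- split(seq_len(nrow(X)), key)
  lapply(idx, function(i) modz(X[i, , drop = FALSE]))
}

#' Consensus signature matrix for a grouping
#'
#' Convenience wrapper around [groupConsensus()] returning the consensus
#' vectors stacked into a groups x genes matrix.
#' @inheritParams groupConsensus
#' @return Numeric matrix with one row per group.
#' @export
consensusMatrix <- function(sigset, groupBy = "perturbagen_id") {
  res <- groupConsensus(sigset, groupBy)
  out <- do.call(rbind, lapply(res, `[[`, "consensus"))
  rownames(out) <- names(res)
  colnames(out) <- geneIds(sigset)
  out
}
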