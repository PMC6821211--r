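#' @importFrom mclust Mclust mclustBIC
NULL

#' Pairwise Spearman similarity of signatures
#'
#' Spearman correlation (average-rank ties) between all row pairs of an
#' instances x genes matrix.
#'
#' @param signatures matrix (n x G, G >= 3) or a [SignatureSet-class].
#' @param methodTag tag stored on the result.
#' @return A symmetric n x n matrix of class `"SimilarityMatrix"` with a
#'   `method` attribute; the diagonal is 1 but is excluded from all
#'   downstream statistics.
#' @export
pairwiseSpearman <- function(signatures, methodTag = "spearman_signature") {
  X <- if (is(signatures, "SignatureSet")) sigMatrix(signatures)
       else as.matrix(signatures)
  if (ncol(X) < 3) stop("pairwiseSpearman: need at least 3 genes")
  rk <- apply(X, 1, rank)            # genes x instances, ranked per row
  S <- cor(rk)
  dimnames(S) <- list(rownames(X), rownames(X))
  attr(S, "method") <- methodTag
  class(S) <- c("SimilarityMatrix", class(S))
  S
}

.asSimilarity <- function(S, methodTag) {
  attr(S, "method") <- methodTag
  class(S) <- c("SimilarityMatrix", class(S))
  S
}

#' Data-driven toxicity threshold from a 2-component Gaussian mixture
#'
#' Fits a two-component unequal-variance Gaussian mixture to the viability
#' values; the nontoxic component is the one with the larger mean and the
#' threshold is its `mean - 2 * SD` (for a nontoxic mode near 1.0 with SD
#' near 0.1 this lands at the conventional 0.8). If the mixture collapses
#' (component means closer than half the larger component SD, or the fit
#' fails), the fixed fallback 0.8 is returned with a warning.
#'
#' @param viabilities numeric vector (n >= 50), fraction metric.
#' @param seed RNG seed for the mixture initialization.
#' @return Numeric threshold, with attribute `"fallback"` = TRUE/FALSE.
#' @export
toxicityThresholdGmm <- function(viabilities, seed = 1) {
  if (length(viabilities) < 50)
    stop("toxicityThresholdGmm: need at least 50 values")
  fallback <- function() {
    warning("toxicityThresholdGmm: mixture collapse; using fixed 0.8")
    structure(0.8, fallback = TRUE)
  }
  # (near-)constant input: the mixture is degenerate before fitting
  if (sd(viabilities) < 1e-8) return(fallback())
  set.seed(seed)
  fit <- tryCatch(
    suppressWarnings(Mclust(viabilities, G = 2, modelNames = "V",
                            verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  hi <- which.max(mu)
  if (abs(diff(mu)) < 0.5 * sg[hi]) return(fallback())
  structure(unname(mu[hi] - 2 * sg[hi]), fallback = FALSE)
}

#' Similarity distributions of toxicity/MoA-defined pair groups
#'
#' Splits all unordered signature pairs into three disjoint groups:
#' `nontoxic_shared_moa` (both members with viability above the threshold and
#' at least one shared MoA label), `toxic_different_moa` (both below the
#' threshold, no shared label), and `random` (everything else). Pairs of the
#' same perturbagen are excluded throughout. Both scopes are reported:
#' `any_cell` (all pairs) and `same_cell` (pairs from one cell line).
#'
#' @param simmat a `SimilarityMatrix` over instances.
#' @param meta data.frame aligned with the matrix: `cell_line_id`,
#'   `perturbagen_id`.
#' @param moaLabels named list: perturbagen_id -> character vector of MoA
#'   labels.
#' @param viab viability vector aligned with the instances.
#' @param threshold toxicity threshold (e.g. from [toxicityThresholdGmm()]).
#' @return A list of class `"PairGroupReport"`: per scope, the similarity
#'   distributions and medians per group, plus the threshold used.
#' @export
pairSimilarityGroups <- function(simmat, meta, moaLabels, viab, threshold) {
  n <- nrow(simmat)
  stopifnot(nrow(meta) == n, length(viab) == n)
  pairs <- which(upper.tri(simmat), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- meta$perturbagen_id[i] != meta$perturbagen_id[j]
  i <- i[keep]; j <- j[keep]
  s <- simmat[cbind(i, j)]
  # shared-MoA lookup at the perturbagen level (instances reuse it)
  perts <- unique(meta$perturbagen_id)
  labs <- sort(unique(unlist(moaLabels[perts])))
  membership <- vapply(moaLabels[perts],
                       function(l) labs %in% l, logical(length(labs)))
  membership <- matrix(membership, nrow = length(labs))
  sharedMat <- crossprod(membership * 1L) > 0
  pi_ <- match(meta$perturbagen_id[i], perts)
  pj_ <- match(meta$perturbagen_id[j], perts)
  shared <- sharedMat[cbind(pi_, pj_)]
  both_non <- viab[i] > threshold & viab[j] > threshold
  both_tox <- viab[i] < threshold & viab[j] < threshold
  grp <- ifelse(both_non & shared, "nontoxic_shared_moa",
                ifelse(both_tox & !shared, "toxic_different_moa", "random"))
  same_cell <- meta$cell_line_id[i] == meta$cell_line_id[j]
  scope <- function(mask) {
    sp <- split(s[mask], grp[mask])
    list(distributions = sp, medians = vapply(sp, median, numeric(1)))
  }
  structure(list(any_cell = scope(rep(TRUE, length(s))),
                 same_cell = scope(same_cell),
                 threshold = threshold),
            class = "PairGroupReport")
}

#' Remove the genes most correlated with viability
#'
#' Drops the `n` genes with the largest `|r|` in the supplied gene-level
#' viability statistics (ties broken by gene_id), or `n` random genes in the
#' `"random"` mode control. To avoid leakage the statistics should come from
#' a different screen than the signatures (e.g. shRNA-screen statistics used
#' to reduce compound signatures).
#'
#' @param sigset a [SignatureSet-class].
#' @param stats a `GeneViabilityStats` data.frame covering the set's genes.
#' @param n number of genes to remove (`0 <= n < G`).
#' @param mode `"top"` (largest `|r|`) or `"random"`.
#' @param seed seed for `mode = "random"`.
#' @return A [SignatureSet-class] with `G - n` genes.
#' @export
reduceByViabilityGenes <- function(sigset, stats, n, mode = c("top", "random"),
                                   seed = 1) {
  stopifnot(is(sigset, "SignatureSet"))
  mode <- match.arg(mode)
  genes <- geneIds(sigset)
  if (!all(genes %in% stats$gene_id))
    stop("reduceByViabilityGenes: stats do not cover the signature genes")
  if (n < 0 || n >= length(genes))
    stop("reduceByViabilityGenes: n must satisfy 0 <= n < G")
  if (n == 0) return(sigset)
  if (mode == "top") {
    r <- setNames(stats$r, stats$gene_id)[genes]
    drop_genes <- genes[order(-abs(r), genes)][seq_len(n)]
  } else {
    set.seed(seed)
    drop_genes <- sample(genes, n)
  }
  subsetSignatures(sigset, genes = setdiff(genes, drop_genes))
}

#' Regress viability out of every gene
#'
#' Per gene, fits the simple regression of signature values on viability and
#' replaces the values by the residuals, removing the viability-correlated
#' component while keeping all genes.
#'
#' @param ds a [MatchedDataset-class] with n >= 3.
#' @return A [SignatureSet-class] of residual signatures (metadata carried
#'   from the dataset).
#' @export
residualizeOnViability <- function(ds) {
  stopifnot(is(ds, "MatchedDataset"))
  if (nrow(ds@X) < 3) stop("residualizeOnViability: need at least 3 instances")
  y <- ds@y
  yc <- y - mean(y)
  denom <- sum(yc^2)
  Xc <- sweep(ds@X, 2, colMeans(ds@X))
  b <- if (denom == 0) rep(0, ncol(ds@X)) else drop(crossprod(Xc, yc)) / denom
  R <- Xc - yc %o% b
  colnames(R) <- colnames(ds@X)
  meta <- ds@meta
  info <- data.frame(instance_id = meta$instance_id,
                     cell_line_id = meta$cell_line_id,
                     perturbagen_id = meta$perturbagen_id,
                     perturbagen_type = if (ds@metricType == "fraction")
                       "compound" else "shRNA",
                     dose_um = if (ds@metricType == "fraction")
                       meta$dose_signature_um else NA_real_,
                     time_h = meta$time_h, stringsAsFactors = FALSE)
  SignatureSet(R, info)
}

#' Tanimoto similarity of fingerprint bit vectors
#'
#' `|A & B| / |A | B|` for every pair of rows; two empty fingerprints get
#' similarity 0 (flagged via the `"empty_pairs"` attribute).
#'
#' @param fingerprints drugs x bits 0/1 matrix with rownames.
#' @return A `SimilarityMatrix` (method `"tanimoto"`).
#' @export
tanimotoSimilarity <- function(fingerprints) {
  fp <- as.matrix(fingerprints) > 0
  inter <- tcrossprod(fp * 1)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, `+`) - inter
  S <- ifelse(uni == 0, 0, inter / uni)
  diag(S) <- ifelse(ones == 0, 0, 1)
  dimnames(S) <- list(rownames(fp), rownames(fp))
  attr(S, "empty_pairs") <- any(uni == 0)
  .asSimilarity(S, "tanimoto")
}

#' Sensitivity-profile similarity of drugs
#'
#' Pearson correlation of per-drug sensitivity profiles (e.g. dose-response
#' AUC) across the shared cell panel; pairs with fewer than 3 shared cells
#' are set to `NA`.
#'
#' @param sensitivity long data.frame: `cell_line_id`, `drug_id`, and the
#'   response named by `metric`.
#' @param metric response column (default `"auc"`).
#' @return A `SimilarityMatrix` (method `"sensitivity_profile"`).
#' @export
sensitivityProfileSimilarity <- function(sensitivity, metric = "auc") {
  wide <- tapply(sensitivity[[metric]],
                 list(sensitivity$cell_line_id, sensitivity$drug_id), mean)
  S <- suppressWarnings(cor(wide, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(wide))
  S[counts < 3] <- NA
  diag(S) <- 1
  .asSimilarity(S, "sensitivity_profile")
}

#' Fuse similarity matrices by normalized summation
#'
#' Each matrix's off-diagonal entries are z-normalized and the matrices are
#' summed elementwise, giving each source equal weight.
#'
#' @param mats list of `SimilarityMatrix` over the same entities (matched by
#'   rownames when present).
#' @return A `SimilarityMatrix` (method `"fused"`).
#' @export
fuseSimilarities <- function(mats) {
  stopifnot(length(mats) >= 1)
  ids <- rownames(mats[[1]])
  norm1 <- function(S) {
    if (!is.null(ids) && !is.null(rownames(S))) S <- S[ids, ids]
    off <- S[upper.tri(S)]     # each unordered pair counted once
    mu <- mean(off, na.rm = TRUE); sg <- sd(off, na.rm = TRUE)
    Z <- (S - mu) / if (sg == 0) 1 else sg
    diag(Z) <- 0
    Z
  }
  out <- Reduce(`+`, lapply(mats, norm1))
  dimnames(out) <- dimnames(mats[[1]])
  .asSimilarity(out, "fused")
}

#' ROC and Precision-Recall evaluation of a score against binary truth
#'
#' Threshold-sweep curves with tied scores grouped (so the ROC AUC equals the
#' Mann-Whitney U-statistic with 0.5 credit for ties) and trapezoidal AUCs.
#'
#' @param scores numeric vector; larger = more positive-like.
#' @param truth binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return A list: `roc` (data.frame fpr/tpr), `roc_auc`, `pr` (data.frame
#'   recall/precision), `pr_auc`.
#' @export
binaryScoreEval <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  ok <- is.finite(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  P <- sum(truth == 1); N <- sum(truth == 0)
  if (P == 0 || N == 0) stop("binaryScoreEval: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  grp <- cumsum(!duplicated(s))            # ties grouped
  tp <- cumsum(t); fp <- cumsum(1 - t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  rec <- tp[last] / P
  prec <- tp[last] / (tp[last] + fp[last])
  # PR curve anchored at the first operating point's precision
  rec2 <- c(0, rec); prec2 <- c(prec[1], prec)
  pr_auc <- sum(diff(rec2) * (head(prec2, -1) + prec2[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), roc_auc = roc_auc,
       pr = data.frame(recall = rec, precision = prec), pr_auc = pr_auc)
}

#' Shared-MoA truth and similarity scores for compound pairs
#'
#' Helper that turns a drug-level similarity matrix and an MoA label list
#' into the per-pair score/truth vectors consumed by [binaryScoreEval()].
#'
#' @param simmat drug x drug `SimilarityMatrix` with rownames.
#' @param moaLabels named list: drug id -> label vector.
#' @return A data.frame: `drug_a`, `drug_b`, `score`, `shared_moa`.
#' @export
moaPairTable <- function(simmat, moaLabels) {
  ids <- rownames(simmat)
  pairs <- which(upper.tri(simmat), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  shared <- mapply(function(a, b) length(intersect(a, b)) > 0,
                   moaLabels[ids[i]], moaLabels[ids[j]])
  data.frame(drug_a = ids[i], drug_b = ids[j], score = simmat[cbind(i, j)],
             shared_moa = as.logical(shared), stringsAsFactors = FALSE)
}
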