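#' Per-gene Pearson correlation with viability
#'
#' The gene-level viability statistic: for each gene (column of `X`), the
#' Pearson correlation of its signature values with the matched viability
#' vector. Zero-variance genes get `r = 0` and are flagged.
#'
#' @param ds a [MatchedDataset-class] with at least 3 instances.
#' @return A data.frame of class `"GeneViabilityStats"`: `gene_id`, `r`,
#'   `n`, `flagged` (zero variance), and a `tag` attribute.
#' @export
geneViabilityCorrelations <- function(ds) {
  stopifnot(is(ds, "MatchedDataset"))
  n <- nrow(ds@X)
  if (n < 3) stop("geneViabilityCorrelations: need at least 3 instances")
  sds <- apply(ds@X, 2, sd)
  flagged <- sds == 0
  r <- rep(0, ncol(ds@X))
  if (sd(ds@y) > 0 && any(!flagged))
    r[!flagged] <- drop(cor(ds@X[, !flagged, drop = FALSE], ds@y))
  out <- data.frame(gene_id = colnames(ds@X), r = r, n = n,
                    flagged = flagged, stringsAsFactors = FALSE)
  attr(out, "tag") <- ds@tag
  class(out) <- c("GeneViabilityStats", "data.frame")
  out
}

#' Write a ranked gene-statistic TSV (consumable by GSEA-family tools)
#' @param stats a `GeneViabilityStats` data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRankedStats <- function(stats, path) {
  o <- order(stats$r, decreasing = TRUE)
  write.table(stats[o, c("gene_id", "r")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Permutation z-score of a weighted gene set
#'
#' Score of the set is the weighted sum of the gene statistics over the
#' intersection of set genes and the statistic's gene space. The z-score
#' compares it to `nPerm` permutations of the GENE LABELS of the statistic
#' vector (set membership held fixed): `z = (score - mean(null)) / sd(null)`.
#'
#' @param stats a `GeneViabilityStats` data.frame (or any data.frame with
#'   `gene_id` and `r`).
#' @param geneSet named numeric vector: gene_id -> signed weight (use 1 for
#'   unweighted sets).
#' @param nPerm number of gene-label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return A list: `score`, `z` (`NA` when the null sd is 0, flagged),
#'   `n_genes_used`, `flagged`.
#' @export
weightedSetZscore <- function(stats, geneSet, nPerm = 1000, seed = 1) {
  common <- intersect(names(geneSet), stats$gene_id)
  if (length(common) < 2)
    stop("weightedSetZscore: need at least 2 set genes in the statistic space")
  r <- setNames(stats$r, stats$gene_id)
  wts <- geneSet[common]
  score <- sum(wts * r[common])
  set.seed(seed)
  nullv <- vapply(seq_len(nPerm), function(i)
    sum(wts * sample(r, length(common))), numeric(1))
  s <- sd(nullv)
  flagged <- s == 0 || all(wts == 0)
  list(score = score,
       z = if (flagged) NA_real_ else (score - mean(nullv)) / s,
       n_genes_used = length(common), flagged = flagged)
}

#' Correlate set activities with average essentialities
#'
#' Pearson correlation over the shared names of two named vectors — e.g.
#' transcription-factor activity z-scores against average gene essentiality
#' of the TF-coding genes.
#'
#' @param activities named numeric vector (set/TF -> activity).
#' @param essentiality named numeric vector (set/TF -> mean essentiality).
#' @return A list: `r`, `n` (shared names used).
#' @export
activityVsEssentiality <- function(activities, essentiality) {
  common <- intersect(names(activities), names(essentiality))
  if (length(common) < 3)
    stop("activityVsEssentiality: need at least 3 shared names")
  list(r = cor(activities[common], essentiality[common]), n = length(common))
}

#' Average silhouette of a labelling in a 2-D embedding
#'
#' Per point, `(b - a) / max(a, b)` with `a` the mean distance to the other
#' members of its own cluster and `b` the smallest mean distance to any other
#' cluster (Euclidean). Points in singleton clusters score 0. Negative
#' averages indicate the labels do not cluster the points.
#'
#' @param embedding n x d numeric matrix (typically the first two principal
#'   components).
#' @param labels factor-like vector of length n with at least 2 levels.
#' @return The average silhouette coefficient.
#' @export
silhouetteByFactor <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  n <- nrow(embedding)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2)
    stop("silhouetteByFactor: need at least 2 label levels")
  dm <- as.matrix(dist(embedding))
  lev <- unique(labels)
  # mean distance from every point to every cluster
  cl_means <- vapply(lev, function(l) rowSums(dm[, labels == l, drop = FALSE]),
                     numeric(n))
  sizes <- as.numeric(table(factor(labels, levels = lev)))
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- match(labels[i], lev)
    if (sizes[li] == 1L) { s[i] <- 0; next }
    a <- cl_means[i, li] / (sizes[li] - 1L)   # exclude self
    b <- min(cl_means[i, -li] / sizes[-li])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' @importFrom stats dist
NULL

#' PC1-viability association of a signature set
#'
#' Runs PCA on the centered signatures, orients PC1 so that its loading has a
#' non-negative dot product with the mean signature of the lowest-viability
#' decile (so "more death-like" scores are positive), and reports the
#' Spearman correlation between PC1 scores and viability.
#'
#' @param sigset a [SignatureSet-class] or an instances x genes matrix.
#' @param viab viability vector aligned with the instances.
#' @return A list: `pc1` (scores), `spearman_r`, `var_explained` (fraction of
#'   variance on PC1).
#' @export
pcViabilityAssociation <- function(sigset, viab) {
  X <- if (is(sigset, "SignatureSet")) sigMatrix(sigset) else as.matrix(sigset)
  stopifnot(nrow(X) == length(viab))
  pca <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  pc1 <- pca$x[, 1]
  low <- viab <= quantile(viab, 0.1)
  ref <- colMeans(X[low, , drop = FALSE]) - colMeans(X)
  if (sum(ref * pca$rotation[, 1]) < 0) pc1 <- -pc1
  list(pc1 = pc1,
       spearman_r = cor(pc1, viab, method = "spearman"),
       var_explained = pca$sdev[1]^2 / sum(pca$sdev^2))
}
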