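# Independent reference implementations used only as test oracles.
# Deliberately written with plain loops and textbook formulas, sharing no
# code path with the package.

# Spearman correlation of two vectors: rank (average ties), then the Pearson
# product-moment formula written out
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) NA_real_ else num / den
}

# direct MODZ: explicit pairwise loop, diagonal -> 0, negatives -> 0.01,
# row-sum weights normalized to 1, weighted average
oracleModz <- function(sigs) {
  n <- nrow(sigs)
  if (n == 1) return(list(weights = 1, consensus = sigs[1, ]))
  R <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) {
        r <- oracleSpearman(sigs[i, ], sigs[j, ])
        if (is.na(r)) r <- 0
        R[i, j] <- if (r < 0) 0.01 else r
      }
  wts <- rowSums(R)
  if (sum(wts) == 0) wts <- rep(1, n)   # all-zero degenerate group
  wts <- wts / sum(wts)
  cons <- rep(0, ncol(sigs))
  for (i in seq_len(n)) cons <- cons + wts[i] * sigs[i, ]
  list(weights = wts, consensus = cons)
}

# brute-force average silhouette: per-point loops over all other points
oracleSilhouette <- function(emb, labels) {
  n <- nrow(emb)
  d <- function(i, j) sqrt(sum((emb[i, ] - emb[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    bs <- vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), function(j) d(i, j), numeric(1)))
    }, numeric(1))
    b <- min(bs)
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ROC AUC as the U-statistic: exhaustive concordant-pair counting with 0.5
# credit for ties
oracleRocAuc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# centered closed-form ridge with unpenalized intercept, by direct solve
oracleRidge <- function(X, y, alpha) {
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  beta <- solve(crossprod(Xc) + diag(alpha, ncol(X)),
                crossprod(Xc, y - ybar))
  list(beta = drop(beta), intercept = ybar - sum(xbar * drop(beta)))
}
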