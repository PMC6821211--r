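test_that("pairwise Spearman hits its anchors and the rank-then-Pearson oracle", {
  set.seed(2)
  x <- rnorm(6)
  M <- rbind(a = x, b = x, c = -x)
  S <- pairwiseSpearman(M)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  expect_lt(max(abs(S - t(S))), 1e-12)

  Fx <- rbind(c(3, 1, 4, 1), c(5, 9, 2, 6), c(5, 3, 5, 8))
  S2 <- pairwiseSpearman(Fx)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(S2[i, j], oracleSpearman(Fx[i, ], Fx[j, ]),
                 tolerance = 1e-12)
})

test_that("GMM threshold lands at mean - 2 SD of the nontoxic component", {
  set.seed(15)
  v <- c(rnorm(1500, 1.0, 0.1), rnorm(700, 0.3, 0.2))
  th <- toxicityThresholdGmm(v, seed = 1)
  expect_equal(as.numeric(th), 0.8, tolerance = 0.03)
  expect_false(attr(th, "fallback"))
  # degenerate input falls back to the fixed 0.8
  expect_warning(th0 <- toxicityThresholdGmm(rep(0.7, 60), seed = 1), "0.8")
  expect_equal(as.numeric(th0), 0.8)
  expect_true(attr(th0, "fallback"))
  expect_error(toxicityThresholdGmm(runif(10)), "at least 50")
  # synthetic compound screen: threshold in a plausible band
  b <- worldBundle(1)
  ths <- toxicityThresholdGmm(b$compound$viability$viability, seed = 1)
  expect_gt(as.numeric(ths), 0.6)
  expect_lt(as.numeric(ths), 0.95)
})

test_that("pair groups are disjoint, exclude same-perturbagen pairs, and degrade safely", {
  set.seed(16)
  n <- 10
  meta <- data.frame(cell_line_id = rep(c("A", "B"), 5),
                     perturbagen_id = paste0("p", rep(1:5, each = 2)))
  moa <- list(p1 = "m1", p2 = "m1", p3 = "m2", p4 = "m3", p5 = "m2")
  viab <- c(0.95, 0.9, 0.98, 0.92, 0.1, 0.2, 0.15, 0.1, 0.96, 0.3)
  S <- pairwiseSpearman(matrix(rnorm(n * 8), n, 8))
  rep1 <- pairSimilarityGroups(S, meta, moa, viab, threshold = 0.8)
  counts <- lengths(rep1$any_cell$distributions)
  # all cross-perturbagen pairs, none double-counted
  expect_equal(sum(counts), choose(10, 2) - 5L)
  expect_true(all(c("nontoxic_shared_moa", "toxic_different_moa") %in%
                    names(counts)))
  # threshold -Inf empties the toxic group without error
  rep2 <- pairSimilarityGroups(S, meta, moa, viab, threshold = -Inf)
  expect_false("toxic_different_moa" %in%
                 names(rep2$any_cell$distributions))
})

test_that("toxic different-MoA pairs look alike; removing viability genes fixes it", {
  b <- worldBundle(1)
  w <- b$world
  sig24 <- subsetSignatures(collapseConditions(b$compound$signatures))
  sig24 <- subsetSignatures(sig24,
                            instances = instanceInfo(sig24)$time_h == 24)
  ii <- instanceInfo(sig24)
  viab <- b$compound$viability
  vkey <- paste(viab$cell_line_id, viab$perturbagen_id, viab$dose_um)
  skey <- paste(ii$cell_line_id, ii$perturbagen_id, ii$dose_um)
  v <- viab$viability[match(skey, vkey)]
  moa <- split(paste0("MoA", w@moaOf), rownames(w@potency))
  thr <- toxicityThresholdGmm(viab$viability, seed = 1)
  stats <- geneViabilityCorrelations(b$dsS[["96"]])  # leakage control
  grpRep <- function(nrem) {
    red <- reduceByViabilityGenes(sig24, stats, nrem)
    pairSimilarityGroups(pairwiseSpearman(sigMatrix(red)), ii, moa, v, thr)
  }
  rep0 <- grpRep(0)
  m0 <- rep0$any_cell$medians
  m90 <- grpRep(90)$any_cell$medians
  # with all genes, toxicity-driven similarity beats MoA-driven similarity,
  # in the all-pairs scope and within single cell lines alike
  expect_gt(m0["toxic_different_moa"], m0["random"])
  expect_gt(m0["nontoxic_shared_moa"], m0["random"])
  sc0 <- rep0$same_cell$medians
  expect_gt(sc0["toxic_different_moa"], sc0["random"])
  # removing the top 30% viability genes (shRNA-derived stats) collapses the
  # toxic group far more than the shared-MoA group
  drop_tox <- m0["toxic_different_moa"] - m90["toxic_different_moa"]
  drop_moa <- m0["nontoxic_shared_moa"] - m90["nontoxic_shared_moa"]
  expect_gt(drop_tox, drop_moa)
  expect_gt(drop_tox, 0)
})

test_that("gene removal follows the |r| ranking with its edge cases", {
  ss <- tinySigset(n = 3, G = 10)
  stats <- data.frame(gene_id = paste0("g", 1:10),
                      r = c(0.9, -0.8, 0.1, 0, 0.5, -0.05, 0.3, 0.2, -0.6,
                            0.02))
  red <- reduceByViabilityGenes(ss, stats, 3)
  removed <- setdiff(paste0("g", 1:10), geneIds(red))
  expect_identical(sort(removed), sort(c("g1", "g2", "g9")))
  expect_identical(geneIds(reduceByViabilityGenes(ss, stats, 0)),
                   geneIds(ss))
  expect_error(reduceByViabilityGenes(ss, stats, 10), "0 <= n < G")
  # random mode removes the requested count reproducibly
  r1 <- reduceByViabilityGenes(ss, stats, 4, mode = "random", seed = 2)
  r2 <- reduceByViabilityGenes(ss, stats, 4, mode = "random", seed = 2)
  expect_identical(geneIds(r1), geneIds(r2))
  expect_length(geneIds(r1), 6L)
})

test_that("removing 700 of 978 landmark-scale genes leaves 278", {
  set.seed(44)
  X <- matrix(rnorm(2 * 978), 2, 978,
              dimnames = list(NULL, sprintf("g%04d", 1:978)))
  ss <- SignatureSet(X, data.frame(
    instance_id = c("a", "b"), cell_line_id = "A", perturbagen_id = "p",
    perturbagen_type = "compound", dose_um = 1, time_h = 24))
  stats <- data.frame(gene_id = colnames(X), r = rnorm(978))
  expect_length(geneIds(reduceByViabilityGenes(ss, stats, 700)), 278L)
})

test_that("residualizing on viability leaves residuals orthogonal to it", {
  set.seed(18)
  n <- 20
  y <- rnorm(n)
  X <- cbind(g1 = 2 * y + 3,            # exactly linear in viability
             g2 = rnorm(n),             # independent
             g3 = y + rnorm(n),
             g4 = rnorm(n),
             g5 = -y + rnorm(n))
  meta <- data.frame(instance_id = paste0("i", 1:n), cell_line_id = "A",
                     perturbagen_id = "p", time_h = 24,
                     dose_signature_um = 1, dose_viability_um = 1,
                     delta_log10_dose = 0)
  ds <- MatchedDataset(X, y, meta, "fraction", "resid")
  res <- residualizeOnViability(ds)
  R <- sigMatrix(res)
  for (j in seq_len(ncol(R)))
    expect_lt(abs(sum(R[, j] * (y - mean(y)))), 1e-10)
  expect_true(all(abs(R[, "g1"]) < 1e-12))
  expect_equal(unname(R[, "g2"]),
               X[, "g2"] - mean(X[, "g2"]) -
                 (y - mean(y)) * cov(X[, "g2"], y) / var(y),
               tolerance = 1e-12)
})

test_that("auxiliary similarities: Tanimoto arithmetic and profile class structure", {
  fp <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), d = c(0, 0, 0, 0))
  S <- tanimotoSimilarity(fp)
  expect_equal(S["a", "b"], 0.5)      # 2 shared of 4 in the union
  expect_equal(S["a", "a"], 1)
  expect_equal(S["a", "d"], 0)
  expect_equal(S["d", "d"], 0)        # empty/empty flagged as 0
  expect_true(attr(S, "empty_pairs"))

  b <- worldBundle(1)
  bp <- simulateBaselinePanel(b$world)
  P <- sensitivityProfileSimilarity(bp$sensitivity)
  moa <- setNames(b$world@moaOf, rownames(b$world@potency))[rownames(P)]
  same <- outer(moa, moa, "==")[upper.tri(P)]
  off <- P[upper.tri(P)]
  expect_gt(mean(off[same]), mean(off[!same]))
})

test_that("fusion z-normalizes and preserves the signal ranking", {
  set.seed(21)
  n <- 15
  A <- matrix(rnorm(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 1
  rownames(A) <- colnames(A) <- paste0("e", 1:n)
  f1 <- fuseSimilarities(list(A))
  off <- A[upper.tri(A)]
  expect_equal(f1[upper.tri(f1)], (off - mean(off)) / sd(off),
               tolerance = 1e-12)
  # fusing with itself is a monotone transform: identical pair ranking
  f2 <- fuseSimilarities(list(A, A))
  expect_equal(cor(f2[upper.tri(f2)], A[upper.tri(A)], method = "spearman"),
               1)
  # signal + pure noise keeps most of the signal's ranking
  N <- matrix(rnorm(n * n), n); N <- (N + t(N)) / 2; diag(N) <- 1
  dimnames(N) <- dimnames(A)
  f3 <- fuseSimilarities(list(A, N))
  expect_gt(cor(f3[upper.tri(f3)], A[upper.tri(A)], method = "spearman"),
            0.6)
})

test_that("ROC/PR evaluation matches hand counting, the U-statistic and pROC", {
  ev <- binaryScoreEval(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(ev$roc_auc, 0.75)   # 3 of 4 concordant pairs
  perfect <- binaryScoreEval(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$pr_auc, 1)
  expect_error(binaryScoreEval(1:3, c(1, 1, 1)), "both classes")

  set.seed(22)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)   # forces ties
    tr <- rbinom(n, 1, 0.5)
    if (length(unique(tr)) < 2) next
    expect_equal(binaryScoreEval(sc, tr)$roc_auc, oracleRocAuc(sc, tr),
                 tolerance = 1e-12)
  }
  # independent cross-check against pROC on one continuous instance
  set.seed(23)
  sc <- rnorm(200); tr <- rbinom(200, 1, 0.4)
  auc_proc <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                             direction = "<")))
  expect_equal(binaryScoreEval(sc, tr)$roc_auc, auc_proc, tolerance = 1e-10)
  # random scores sit near 0.5
  set.seed(24)
  ev_null <- binaryScoreEval(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(ev_null$roc_auc - 0.5), 0.02)
})
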