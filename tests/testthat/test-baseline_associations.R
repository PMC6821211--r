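mkModel <- function(beta, tag = "m") {
  new("ViabilityModel", beta = beta, intercept = 0, alpha = 1, tag = tag)
}

test_that("CVS scoring normalizes per gene and respects the overlap contract", {
  beta <- c(g1 = 1, g2 = -2, g3 = 0.5)
  base <- rbind(g1 = c(1, 2, 3, 4), g2 = c(0, 0, 1, 1), g3 = rep(5, 4))
  colnames(base) <- paste0("c", 1:4)
  sc <- cvsScore(mkModel(beta), base)
  Z <- t(scale(t(base[1:2, ])))
  # g3 is constant across cells and contributes 0 after z-normalization
  expect_equal(unname(sc$score), unname(drop(crossprod(Z, beta[1:2]))))
  # identical cell columns score identically
  base2 <- base[, c(1, 1, 3, 4)]
  colnames(base2) <- paste0("c", 1:4)
  sc2 <- cvsScore(mkModel(beta), base2)
  expect_equal(sc2$score[1], sc2$score[2])
  # appending genes absent from the model changes nothing
  base3 <- rbind(base, g99 = rnorm(4))
  expect_equal(cvsScore(mkModel(beta), base3)$score, sc$score)
  # < 50% overlap errors
  expect_error(cvsScore(mkModel(c(beta, g7 = 1, g8 = 1, g9 = 1, g10 = 1)),
                        base), "50%")
})

test_that("CVS scores recover the planted cell propensity from baseline expression", {
  b <- worldBundle(1)
  m96 <- fitRidge(b$dsS[["96"]])
  bp <- simulateBaselinePanel(b$world)
  sc <- cvsScore(m96, bp$expression)
  expect_gt(cor(sc$score, b$world@rho, method = "spearman"), 0.8)
})

test_that("per-drug associations recover an exact planted effect", {
  set.seed(14)
  cells <- paste0("c", 1:12)
  tissue <- setNames(rep(c("t1", "t2", "t3"), each = 4), cells)
  msi <- setNames(rep(c(TRUE, FALSE), 6), cells)
  cvs <- setNames(rnorm(12), cells)
  tis_eff <- c(t1 = 0, t2 = 3, t3 = -1)
  sens <- expand.grid(cell_line_id = cells, drug_id = paste0("d", 1:4),
                      stringsAsFactors = FALSE)
  sens$auc <- -2 * cvs[sens$cell_line_id] + tis_eff[tissue[sens$cell_line_id]] +
    rnorm(nrow(sens), 0, 1e-6)
  scores <- data.frame(cell_line_id = cells, score = cvs)
  res <- drugSensitivityAssociations(scores, sens, tissue, msi)
  expect_equal(nrow(res), 4L)
  expect_equal(res$effect, rep(-2, 4), tolerance = 1e-4)
  expect_true(all(res$fdr < 1e-6))
  # FDR is monotone in the raw p ranking
  expect_true(all(diff(res$fdr[order(res$p)]) >= -1e-15))
  # single tissue level reduces the model without error
  res1 <- drugSensitivityAssociations(scores, sens,
                                      setNames(rep("t1", 12), cells), msi)
  expect_equal(nrow(res1), 4L)
})

test_that("null associations stay near the nominal FDR level", {
  set.seed(77)
  cells <- paste0("c", 1:20)
  tissue <- setNames(rep(c("t1", "t2"), 10), cells)
  msi <- setNames(rep(FALSE, 20), cells)
  scores <- data.frame(cell_line_id = cells, score = rnorm(20))
  sens <- expand.grid(cell_line_id = cells, drug_id = paste0("d", 1:100),
                      stringsAsFactors = FALSE)
  sens$auc <- rnorm(nrow(sens))
  res <- drugSensitivityAssociations(scores, sens, tissue, msi)
  expect_lte(sum(res$fdr < 0.05), 5)
})

test_that("GLDS is exact on balanced tables and translation-invariant", {
  cells <- paste0("c", 1:5); drugs <- paste0("d", 1:7)
  ce <- c(2, -1, 0.5, 0, -1.5); de <- rnorm(7, sd = 2)
  tab <- expand.grid(cell_line_id = cells, drug_id = drugs,
                     stringsAsFactors = FALSE)
  tab$auc <- 10 + ce[match(tab$cell_line_id, cells)] +
    de[match(tab$drug_id, drugs)]
  est <- glds(tab)
  expect_equal(unname(est[cells]), ce - mean(ce), tolerance = 1e-8)
  tab2 <- tab; tab2$auc <- tab2$auc + 100
  expect_equal(glds(tab2), est, tolerance = 1e-8)
})

test_that("GLDS on unbalanced tables matches a generic least-squares oracle", {
  set.seed(31)
  cells <- paste0("c", 1:6); drugs <- paste0("d", 1:8)
  tab <- expand.grid(cell_line_id = cells, drug_id = drugs,
                     stringsAsFactors = FALSE)
  tab <- tab[-sample(nrow(tab), 10), ]          # drop cells x drugs at random
  stopifnot(all(table(tab$cell_line_id) >= 2), all(table(tab$drug_id) >= 2))
  tab$auc <- rnorm(nrow(tab))
  est <- glds(tab)
  # oracle: solve the normal equations of the sum-to-zero dummy design
  Cn <- length(cells); Dn <- length(drugs)
  Xd <- matrix(0, nrow(tab), 1 + (Cn - 1) + (Dn - 1))
  Xd[, 1] <- 1
  ic <- match(tab$cell_line_id, cells); idg <- match(tab$drug_id, drugs)
  for (k in seq_len(Cn - 1)) Xd[, 1 + k] <-
      (ic == k) - (ic == Cn)
  for (k in seq_len(Dn - 1)) Xd[, Cn + k] <-
      (idg == k) - (idg == Dn)
  bhat <- solve(crossprod(Xd), crossprod(Xd, tab$auc))
  ce <- c(bhat[2:Cn], -sum(bhat[2:Cn]))
  expect_equal(unname(est[cells]), unname(ce), tolerance = 1e-8)
})

test_that("partial correlation matches the hand-worked two-level example", {
  # 6 points, two tissue levels; residualize on group means by hand
  x <- c(1, 2, 3, 10, 11, 15)
  y <- c(2, 1, 4, 20, 19, 27)
  f <- c("a", "a", "a", "b", "b", "b")
  rx <- c(x[1:3] - 2, x[4:6] - 12)
  ry <- c(y[1:3] - 7 / 3, y[4:6] - 22)
  hand <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  res <- partialCorrelationFactor(x, y, f)
  expect_equal(res$r, hand, tolerance = 1e-12)
  # constant factor reduces to the plain Pearson correlation
  expect_equal(partialCorrelationFactor(x, y, rep("z", 6))$r, cor(x, y))
  # no within-level variance is flagged as undefined
  res0 <- partialCorrelationFactor(c(1, 1, 5, 5), c(2, 2, 7, 7),
                                   c("a", "a", "b", "b"))
  expect_true(res0$flagged)
  expect_true(is.na(res0$r))
})

test_that("null-signature comparison behaves at its anchors and detects the planted link", {
  b <- worldBundle(1)
  s96 <- b$dsS[["96"]]
  bp <- simulateBaselinePanel(b$world)
  statFun <- function(scores) abs(cor(scores$score,
                                      b$world@glds[scores$cell_line_id]))
  # an unreachable reference has exceedance 0 by construction
  ns <- nullSignatureComparison(s96, bp$expression, statFun, Inf,
                                "permute_genes", nReps = 3, seed = 1)
  expect_equal(ns$exceedance, 0)
  expect_length(ns$null_stats, 3L)
})

test_that("the planted CVS-sensitivity link beats permuted models on a powered panel", {
  # association power needs more cell lines than the default screen carries
  w <- buildWorld(worldConfig(seed = 1, n_cells = 40))
  sh <- simulateShrnaScreen(w)
  s96 <- composeDatasets(sh$signatures, sh$viability, tag = "shrna")[["96"]]
  bp <- simulateBaselinePanel(w)
  g <- glds(bp$sensitivity)
  tis <- setNames(bp$cells$tissue, bp$cells$cell_line_id)
  statFun <- function(scores)
    abs(partialCorrelationFactor(scores$score, g[scores$cell_line_id],
                                 tis[scores$cell_line_id])$r)
  ref <- statFun(cvsScore(fitRidge(s96), bp$expression))
  ns <- nullSignatureComparison(s96, bp$expression, statFun, ref,
                                "permute_samples", nReps = 30, seed = 5)
  expect_lt(ns$exceedance, 0.1)
  sg <- nullSignatureComparison(s96, bp$expression, statFun, ref,
                                "single_gene", nReps = 30, seed = 5)
  expect_lt(sg$exceedance, 0.2)
})
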