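test_that("a fixed (config, seed) reproduces the world bitwise", {
  cfg <- worldConfig(seed = 11, n_genes = 40, n_cells = 3, n_compounds = 6,
                     n_shrnas = 8, n_moa_classes = 3)
  w1 <- buildWorld(cfg)
  w2 <- buildWorld(cfg)
  expect_identical(w1@w, w2@w)
  expect_identical(w1@potency, w2@potency)
  expect_identical(sigMatrix(simulateCompoundScreen(w1)$signatures),
                   sigMatrix(simulateCompoundScreen(w2)$signatures))
  expect_identical(simulateShrnaScreen(w1)$viability,
                   simulateShrnaScreen(w2)$viability)
})

test_that("planted latents satisfy their construction invariants", {
  w <- worldBundle(1)$world
  expect_equal(sqrt(sum(w@w^2)), 1, tolerance = 1e-12)
  expect_true(all(abs(w@moaVectors %*% w@w) < 1e-10))
  expect_true(all(abs(w@shrnaOfftarget %*% w@w) < 1e-10))
  # tissue labels are balanced
  expect_true(max(table(w@tissue)) - min(table(w@tissue)) <= 1)
  # minimal world builds
  expect_s4_class(buildWorld(worldConfig(seed = 1, n_genes = 10, n_cells = 2,
                                         n_moa_classes = 2, n_compounds = 2,
                                         n_shrnas = 2)), "SyntheticWorld")
  expect_error(worldConfig(seed = 1, n_cells = 1), ">= 2")
  expect_error(worldConfig(n_cells = 4), "seed")
})

test_that("noise-free compound screen matches the generative formula", {
  cfg <- worldConfig(seed = 3, n_genes = 50, n_cells = 2, n_compounds = 4,
                     n_moa_classes = 2, n_shrnas = 4, sigma_x = 1e-12,
                     sigma_v = 1e-12, moa_amplitude = 0, cell_sd = 1e-12,
                     doses_um = c(0.1, 1e9))   # saturating top dose
  w <- buildWorld(cfg)
  scr <- simulateCompoundScreen(w)
  ii <- instanceInfo(scr$signatures)
  X <- sigMatrix(scr$signatures)
  hit <- which(ii$dose_um == 1e9 & ii$time_h == 24)[1]
  u <- viabilityBurden(w, ii$perturbagen_id[hit], ii$cell_line_id[hit], 1e9)
  expect_equal(u, cfg$kappa, tolerance = 1e-3)   # saturated burden
  expect_equal(unname(X[hit, ]), -cfg$kappa * w@w, tolerance = 1e-2)
  vrow <- scr$viability[scr$viability$dose_um == 1e9, ]
  expect_true(all(vrow$viability < 1e-2))
  # viability non-increasing in dose for every (compound, cell)
  byKey <- split(scr$viability, paste(scr$viability$cell_line_id,
                                      scr$viability$perturbagen_id))
  for (d in byKey) {
    d <- d[order(d$dose_um), ]
    expect_true(all(diff(d$viability) <= 1e-9))
  }
})

test_that("24h signature projection on w tracks compound viability", {
  b <- worldBundle(1)
  c24 <- b$dsC[["24"]]
  r <- cor(drop(sigMatrix(c24) %*% b$world@w), viability(c24),
           method = "spearman")
  # toxicity lowers both the w-projection and viability, so the planted
  # association is positive
  expect_gt(r, 0.4)
})

test_that("noise-free shRNA screen obeys its construction", {
  cfg <- worldConfig(seed = 5, n_genes = 40, n_cells = 2, n_compounds = 2,
                     n_moa_classes = 2, n_shrnas = 6, sigma_x = 1e-12,
                     sigma_lfc = 1e-12, essential_frac = 0, cell_sd = 1e-12,
                     offtarget_amplitude = 0)
  w <- buildWorld(cfg)
  scr <- simulateShrnaScreen(w)
  # essentiality 0 -> LFC 0 and zero viability component off the target gene
  expect_true(all(abs(scr$viability$viability) < 1e-9))
  X <- sigMatrix(scr$signatures)
  ii <- instanceInfo(scr$signatures)
  tgt <- w@shrnaTarget[match(ii$perturbagen_id, rownames(w@essentiality))]
  for (i in seq_len(nrow(X))) {
    expect_lt(X[i, tgt[i]], -0.1)   # knockdown pushes the target gene down
    expect_lt(max(abs(X[i, -tgt[i]])), 1e-6)
  }
})

test_that("per-gene expression-LFC correlations concentrate on the support of w", {
  b <- worldBundle(1)
  st <- geneViabilityCorrelations(b$dsS[["96"]])
  top20 <- st$gene_id[order(-abs(st$r))][1:20]
  support <- paste0("g", which(b$world@w != 0))
  expect_true(all(top20 %in% support))
})

test_that("noise-free baseline panel encodes rho in doubling time and GLDS in AUC", {
  cfg <- worldConfig(seed = 9, n_genes = 40, n_cells = 9, n_compounds = 8,
                     n_moa_classes = 4, n_shrnas = 4, sigma_doubling = 1e-12,
                     sigma_auc = 1e-12, auc_moa_scale = 0)
  w <- buildWorld(cfg)
  bp <- simulateBaselinePanel(w)
  # partial correlation of rho with doubling time given tissue is exactly -1
  pc <- partialCorrelationFactor(w@rho, bp$cells$doubling_time_h,
                                 bp$cells$tissue)
  expect_equal(pc$r, -1, tolerance = 1e-8)
  # planted GLDS offsets recovered up to an additive constant
  est <- glds(bp$sensitivity)
  planted <- w@glds[names(est)] * cfg$auc_glds_scale
  expect_equal(unname(est - mean(est)), unname(planted - mean(planted)),
               tolerance = 1e-8)
})

test_that("fingerprints inherit MoA-class structure controlled by flip_prob", {
  w <- worldBundle(1)$world
  same <- outer(w@moaOf, w@moaOf, "==")
  offd <- upper.tri(same)
  ann0 <- simulateFingerprints(w, flip_prob = 0)
  T0 <- tanimotoSimilarity(attr(ann0, "fingerprints"))
  expect_true(all(T0[offd][same[offd]] == 1))
  ann <- simulateFingerprints(w, flip_prob = 0.05)
  Tm <- tanimotoSimilarity(attr(ann, "fingerprints"))
  expect_gt(mean(Tm[offd][same[offd]]), mean(Tm[offd][!same[offd]]))
  annU <- simulateFingerprints(w, flip_prob = 0.5)
  Tu <- tanimotoSimilarity(attr(annU, "fingerprints"))
  expect_lt(abs(mean(Tu[offd][same[offd]]) - mean(Tu[offd][!same[offd]])),
            0.05)
})

test_that("generated artifacts are valid io types and round-trip", {
  b <- worldBundle(1)
  expect_true(validObject(b$compound$signatures))
  expect_s3_class(validateViabilityTable(b$compound$viability), "data.frame")
  expect_s3_class(validateViabilityTable(b$shrna$viability), "data.frame")
  path <- withr::local_tempfile(fileext = ".gct")
  small <- subsetSignatures(b$compound$signatures, instances = 1:5)
  writeSignatureGCT(small, path)
  expect_equal(sigMatrix(readSignatureGCT(path)), sigMatrix(small))
})
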