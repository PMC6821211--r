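#' Configuration for a synthetic perturbation-screen world
#'
#' Returns the parameter list consumed by [buildWorld()]. Defaults encode a
#' desk-scale world with the statistical structure the pipeline assumes: a
#' single viability-driven expression axis shared by compound and shRNA
#' screens, MoA-specific signature components orthogonal to that axis,
#' cell-line offsets, logistic dose-response viability with per-MoA potency
#' classes (some toxic, some inert), and time-dependent maturation of the
#' viability component (weak at 3/6 h, full at 24 h; full at all shRNA
#' times).
#'
#' @param n_genes,n_cells,n_moa_classes,n_compounds,n_shrnas world sizes
#'   (all >= 2).
#' @param doses_um compound dose grid, micromolar.
#' @param compound_times_h,shrna_times_h signature measurement times.
#' @param w_sparsity fraction of genes with nonzero viability loading.
#' @param sigma_x per-gene signature noise SD (z-score units).
#' @param sigma_v viability noise SD (fraction scale).
#' @param sigma_lfc shRNA log-fold-change noise SD.
#' @param g_tau named vector of maturation factors in (0, 1] for the compound
#'   times; shRNA times all use 1.
#' @param kappa viability signature amplitude (z-score units per full kill).
#' @param kappa_shrna scale of the shared viability axis in shRNA signatures
#'   (z-score units per LFC unit).
#' @param hill_slope logistic slope per log10 concentration unit.
#' @param moa_amplitude amplitude of the MoA component in compound signatures.
#' @param knockdown_depth z-score drop at an shRNA's target gene.
#' @param offtarget_amplitude amplitude of the reproducible per-shRNA
#'   off-target (seed-sequence) signature component.
#' @param cell_sd SD of per-gene cell-line offsets.
#' @param potency_class_mean,potency_class_sd,potency_drug_sd,potency_cell_sd
#'   pIC50 hierarchy (log10 micromolar): class means are
#'   N(potency_class_mean, potency_class_sd^2); drugs and (drug, cell) pairs
#'   deviate with the stated SDs.
#' @param essential_frac fraction of shRNAs with nonzero essentiality.
#' @param essential_mean,essential_sd essentiality of essential shRNAs
#'   (LFC units, folded to >= 0); per-cell deviation SD 0.3.
#' @param glds_rho_cor planted correlation between per-cell GLDS offsets and
#'   the CVS propensity rho.
#' @param auc_base,auc_glds_scale,auc_tox_scale,auc_moa_scale,sigma_auc
#'   coefficients of the synthetic dose-response AUC model (see
#'   [simulateBaselinePanel()]).
#' @param doubling_t0_h,doubling_lambda,doubling_tissue_sd,sigma_doubling
#'   doubling-time model parameters (hours).
#' @param n_decoy_regulons number of random decoy gene sets stored next to the
#'   planted viability axis.
#' @param seed integer seed; mandatory, fixes the entire world.
#' @return A list of class `"worldConfig"`.
#' @export
worldConfig <- function(n_genes = 300L, n_cells = 12L, n_moa_classes = 10L,
                        n_compounds = 60L, n_shrnas = 150L,
                        doses_um = c(0.37, 1.1, 3.3, 10),
                        compound_times_h = c(3, 6, 24),
                        shrna_times_h = c(96, 120, 144),
                        w_sparsity = 0.3, sigma_x = 1.0, sigma_v = 0.05,
                        sigma_lfc = 0.3,
                        g_tau = c(`3` = 0.2, `6` = 0.5, `24` = 1.0),
                        kappa = 3.0, kappa_shrna = 1.0, hill_slope = 3.0,
                        moa_amplitude = 1.5, knockdown_depth = 2.0,
                        offtarget_amplitude = 1.5,
                        cell_sd = 0.15,
                        potency_class_mean = 1.0, potency_class_sd = 1.5,
                        potency_drug_sd = 1.0, potency_cell_sd = 0.3,
                        essential_frac = 0.4, essential_mean = 2.5,
                        essential_sd = 1.0,
                        glds_rho_cor = 0.5,
                        auc_base = 0.5, auc_glds_scale = 0.1,
                        auc_tox_scale = 0.3, auc_moa_scale = 0.1,
                        sigma_auc = 0.05,
                        doubling_t0_h = 40, doubling_lambda = 5,
                        doubling_tissue_sd = 3, sigma_doubling = 2,
                        n_decoy_regulons = 10L,
                        seed) {
  if (missing(seed)) stop("worldConfig: a seed is mandatory")
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_moa_classes = as.integer(n_moa_classes),
              n_compounds = as.integer(n_compounds),
              n_shrnas = as.integer(n_shrnas),
              doses_um = doses_um, compound_times_h = compound_times_h,
              shrna_times_h = shrna_times_h,
              w_sparsity = w_sparsity, sigma_x = sigma_x, sigma_v = sigma_v,
              sigma_lfc = sigma_lfc, g_tau = g_tau, kappa = kappa,
              kappa_shrna = kappa_shrna, hill_slope = hill_slope,
              moa_amplitude = moa_amplitude,
              knockdown_depth = knockdown_depth,
              offtarget_amplitude = offtarget_amplitude, cell_sd = cell_sd,
              potency_class_mean = potency_class_mean,
              potency_class_sd = potency_class_sd,
              potency_drug_sd = potency_drug_sd,
              potency_cell_sd = potency_cell_sd,
              essential_frac = essential_frac,
              essential_mean = essential_mean, essential_sd = essential_sd,
              glds_rho_cor = glds_rho_cor,
              auc_base = auc_base, auc_glds_scale = auc_glds_scale,
              auc_tox_scale = auc_tox_scale, auc_moa_scale = auc_moa_scale,
              sigma_auc = sigma_auc,
              doubling_t0_h = doubling_t0_h,
              doubling_lambda = doubling_lambda,
              doubling_tissue_sd = doubling_tissue_sd,
              sigma_doubling = sigma_doubling,
              n_decoy_regulons = as.integer(n_decoy_regulons),
              seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_cells, cfg$n_moa_classes, cfg$n_compounds,
              cfg$n_shrnas)
  if (any(counts < 2)) stop("worldConfig: all counts must be >= 2")
  if (any(cfg$g_tau <= 0 | cfg$g_tau > 1))
    stop("worldConfig: maturation factors g_tau must lie in (0, 1]")
  if (length(cfg$g_tau) != length(cfg$compound_times_h))
    stop("worldConfig: one g_tau per compound time required")
  class(cfg) <- "worldConfig"
  cfg
}

.logistic <- function(x) 1 / (1 + exp(-x))

#' Build a synthetic world with planted ground truth
#'
#' Draws every latent of the world from a single seeded stream in a fixed
#' order, so a fixed `(config, seed)` reproduces the world bitwise. The
#' planted viability loading `w` is a sparse standard-normal vector normalized
#' to unit length; MoA vectors are standard normal, orthogonalized against `w`
#' and normalized; potencies follow the class/drug/cell hierarchy of the
#' config so that some MoA classes are toxic in the tested dose range and
#' others inert.
#'
#' @param config a [worldConfig()].
#' @return A [SyntheticWorld-class].
#' @export
buildWorld <- function(config) {
  stopifnot(inherits(config, "worldConfig"))
  cfg <- config
  G <- cfg$n_genes; C <- cfg$n_cells; K <- cfg$n_moa_classes
  D <- cfg$n_compounds; S <- cfg$n_shrnas
  set.seed(cfg$seed)

  n_active <- max(2L, round(cfg$w_sparsity * G))
  support <- sort(sample.int(G, n_active))
  w <- numeric(G)
  w[support] <- rnorm(n_active)
  w <- w / sqrt(sum(w^2))

  moa <- matrix(rnorm(K * G), K, G)
  moa <- moa - outer(drop(moa %*% w), w)      # orthogonalize against w
  moa <- moa / sqrt(rowSums(moa^2))

  cells <- matrix(rnorm(C * G, sd = cfg$cell_sd), C, G)

  class_mean <- rnorm(K, cfg$potency_class_mean, cfg$potency_class_sd)
  moaOf <- as.integer(rep_len(seq_len(K), D))
  drug_dev <- rnorm(D, 0, cfg$potency_drug_sd)
  potency <- outer(class_mean[moaOf] + drug_dev, rep(0, C), `+`) +
    matrix(rnorm(D * C, 0, cfg$potency_cell_sd), D, C)
  dimnames(potency) <- list(paste0("drug", seq_len(D)),
                            paste0("cell", seq_len(C)))

  essential <- runif(S) < cfg$essential_frac
  base_e <- ifelse(essential,
                   abs(rnorm(S, cfg$essential_mean, cfg$essential_sd)), 0)
  efficiency <- runif(S, 0.4, 1)   # heterogeneous knockdown efficiency
  essentiality <- pmax(efficiency * (outer(base_e, rep(0, C), `+`) +
                         matrix(rnorm(S * C, 0, 0.3), S, C) *
                         rep(as.numeric(essential), C)), 0)
  dimnames(essentiality) <- list(paste0("shRNA", seq_len(S)),
                                 paste0("cell", seq_len(C)))
  shrnaTarget <- sample.int(G, S, replace = TRUE)
  offt <- matrix(rnorm(S * G), S, G)
  offt <- offt - outer(drop(offt %*% w), w)
  offt <- offt / sqrt(rowSums(offt^2))

  proto <- matrix(rbinom(K * 256L, 1L, 0.3), K, 256L)

  rho <- rnorm(C)
  r <- cfg$glds_rho_cor
  glds <- r * rho + sqrt(1 - r^2) * rnorm(C)
  names(glds) <- colnames(potency)
  tissues <- sort(rep_len(paste0("tissue", 1:3), C))   # balanced ceiling(C/3)
  msi <- runif(C) < 0.2
  pathwayOf <- as.integer(rep_len(seq_len(max(2L, ceiling(K / 3))), K))
  pathwayState <- matrix(rnorm(C * K), C, K)

  regulons <- list(viability_axis = setNames(w[support],
                                             paste0("g", support)))
  decoy_size <- min(30L, G)
  for (d in seq_len(cfg$n_decoy_regulons)) {
    idx <- sample.int(G, decoy_size)
    regulons[[paste0("decoy", d)]] <- setNames(rnorm(decoy_size),
                                               paste0("g", idx))
  }

  new("SyntheticWorld", config = unclass(cfg), w = w, moaVectors = moa,
      cellEffects = cells, potency = potency, essentiality = essentiality,
      moaOf = moaOf, pathwayOf = pathwayOf,
      shrnaTarget = as.integer(shrnaTarget), shrnaEfficiency = efficiency,
      shrnaOfftarget = offt,
      fingerprintPrototypes = proto, rho = rho, tissue = tissues,
      msi = as.logical(msi), glds = glds, pathwayState = pathwayState,
      regulons = regulons)
}

.geneIdsOf <- function(world) paste0("g", seq_len(world@config$n_genes))
.cellIdsOf <- function(world) colnames(world@potency)
.drugIdsOf <- function(world) rownames(world@potency)
.shrnaIdsOf <- function(world) rownames(world@essentiality)

#' Viability burden of a compound at a dose
#'
#' `kappa * logistic(slope * (log10(dose) - pIC50))`, the planted link between
#' dose and kill. Exported because screens and benchmark truth tables both
#' derive from it.
#' @param world a [SyntheticWorld-class].
#' @param drug,cell indices or ids.
#' @param dose_um dose in micromolar.
#' @return Burden in (0, kappa).
#' @export
viabilityBurden <- function(world, drug, cell, dose_um) {
  cfg <- world@config
  p <- world@potency[drug, cell]
  cfg$kappa * .logistic(cfg$hill_slope * (log10(dose_um) - p))
}

#' Simulate the compound screen (signatures + viability)
#'
#' One signature instance per (compound, cell, dose, time) and one fraction
#' viability record per (compound, cell, dose) at a single assay time (72 h),
#' emulating a compound sensitivity screen profiled in parallel with a
#' multi-time transcriptomics screen. Signature model:
#' `X = -g(tau) * u * w + b * m_moa + c_cell + noise` with burden
#' `u = kappa * logistic(slope * (log10 d - pIC50))`; viability
#' `v = max(0, 1 - u / kappa + noise)`.
#'
#' @param world a [SyntheticWorld-class].
#' @return A list with elements `signatures` ([SignatureSet-class]) and
#'   `viability` (a fraction-metric viability table).
#' @export
simulateCompoundScreen <- function(world) {
  cfg <- world@config
  set.seed(cfg$seed + 101L)
  G <- cfg$n_genes
  drugs <- .drugIdsOf(world); cellsv <- .cellIdsOf(world)
  grid <- expand.grid(dose = cfg$doses_um, cell = seq_along(cellsv),
                      drug = seq_along(drugs), KEEP.OUT.ATTRS = FALSE)
  u <- cfg$kappa * .logistic(cfg$hill_slope *
         (log10(grid$dose) - world@potency[cbind(grid$drug, grid$cell)]))
  viab <- data.frame(cell_line_id = cellsv[grid$cell],
                     perturbagen_id = drugs[grid$drug],
                     dose_um = grid$dose,
                     viability = pmax(0, 1 - u / cfg$kappa +
                                        rnorm(nrow(grid), 0, cfg$sigma_v)),
                     metric_type = "fraction", assay_time_h = 72,
                     stringsAsFactors = FALSE)

  times <- cfg$compound_times_h
  n_inst <- nrow(grid) * length(times)
  X <- matrix(0, n_inst, G)
  info <- vector("list", length(times))
  for (ti in seq_along(times)) {
    g <- cfg$g_tau[[ti]]
    rows <- (ti - 1L) * nrow(grid) + seq_len(nrow(grid))
    X[rows, ] <- -g * u %o% world@w +
      cfg$moa_amplitude * world@moaVectors[world@moaOf[grid$drug], ,
                                           drop = FALSE] +
      world@cellEffects[grid$cell, , drop = FALSE]
    info[[ti]] <- data.frame(
      instance_id = sprintf("cmp_%s_%s_d%g_t%g", drugs[grid$drug],
                            cellsv[grid$cell], grid$dose, times[ti]),
      cell_line_id = cellsv[grid$cell], perturbagen_id = drugs[grid$drug],
      perturbagen_type = "compound", dose_um = grid$dose,
      time_h = times[ti], stringsAsFactors = FALSE)
  }
  X <- X + matrix(rnorm(n_inst * G, 0, cfg$sigma_x), n_inst, G)
  colnames(X) <- .geneIdsOf(world)
  list(signatures = SignatureSet(X, do.call(rbind, info)),
       viability = validateViabilityTable(viab))
}

#' Simulate the shRNA screen (signatures + viability)
#'
#' One signature instance per (shRNA, cell, time) and one log-fold-change
#' viability record per (shRNA, cell); `LFC = -essentiality + noise`.
#' Signatures share the planted viability axis with the compound screen:
#' `X = g(tau) * LFC_true * kappa_shrna * w + knockdown(target gene) +
#' c_cell + noise`, with `g(tau) = 1` at all shRNA times.
#'
#' @param world a [SyntheticWorld-class].
#' @return A list with `signatures` and `viability` (log_fold_change metric).
#' @export
simulateShrnaScreen <- function(world) {
  cfg <- world@config
  set.seed(cfg$seed + 202L)
  G <- cfg$n_genes
  sh <- .shrnaIdsOf(world); cellsv <- .cellIdsOf(world)
  grid <- expand.grid(cell = seq_along(cellsv), sh = seq_along(sh),
                      KEEP.OUT.ATTRS = FALSE)
  lfc_true <- -world@essentiality[cbind(grid$sh, grid$cell)]
  viab <- data.frame(cell_line_id = cellsv[grid$cell],
                     perturbagen_id = sh[grid$sh],
                     dose_um = NA_real_,
                     viability = lfc_true + rnorm(nrow(grid), 0,
                                                  cfg$sigma_lfc),
                     metric_type = "log_fold_change", assay_time_h = 960,
                     stringsAsFactors = FALSE)

  times <- cfg$shrna_times_h
  n_inst <- nrow(grid) * length(times)
  X <- matrix(0, n_inst, G)
  info <- vector("list", length(times))
  for (ti in seq_along(times)) {
    rows <- (ti - 1L) * nrow(grid) + seq_len(nrow(grid))
    M <- (lfc_true * cfg$kappa_shrna) %o% world@w +
      cfg$offtarget_amplitude * world@shrnaOfftarget[grid$sh, , drop = FALSE] +
      world@cellEffects[grid$cell, , drop = FALSE]
    M[cbind(seq_len(nrow(grid)), world@shrnaTarget[grid$sh])] <-
      M[cbind(seq_len(nrow(grid)), world@shrnaTarget[grid$sh])] -
      cfg$knockdown_depth * world@shrnaEfficiency[grid$sh]
    X[rows, ] <- M
    info[[ti]] <- data.frame(
      instance_id = sprintf("sh_%s_%s_t%g", sh[grid$sh], cellsv[grid$cell],
                            times[ti]),
      cell_line_id = cellsv[grid$cell], perturbagen_id = sh[grid$sh],
      perturbagen_type = "shRNA", dose_um = NA_real_, time_h = times[ti],
      stringsAsFactors = FALSE)
  }
  X <- X + matrix(rnorm(n_inst * G, 0, cfg$sigma_x), n_inst, G)
  colnames(X) <- .geneIdsOf(world)
  list(signatures = SignatureSet(X, do.call(rbind, info)),
       viability = validateViabilityTable(viab))
}

#' Simulate the baseline panel: expression, annotations, sensitivity
#'
#' Baseline expression of cell `c` is `mu0 + c_cell + rho_c * w`, so the
#' per-cell CVS propensity `rho` is readable with a CVS model. Doubling time
#' is `T0 - lambda * rho + tissue effect + noise`. The dose-response AUC of
#' drug `p` in cell `c` is
#' `auc_base + auc_glds_scale * GLDS_c - auc_tox_scale * toxicity(p) +
#' auc_moa_scale * state[c, moa(p)] + noise`,
#' where `toxicity(p)` is the drug's mean viability burden (scaled to (0, 1))
#' over cells at the highest tested dose — the drug-level main effect carried
#' by the planted viability axis, which is what makes signature-derived drug
#' features informative for held-out target classes.
#'
#' @param world a [SyntheticWorld-class].
#' @return A list: `expression` (genes x cells matrix), `cells` (data.frame
#'   with `cell_line_id`, `tissue`, `msi`, `doubling_time_h`), `sensitivity`
#'   (cell x drug long table with `auc`), and `drug_toxicity` (the planted
#'   per-drug toxicity used in the AUC model).
#' @export
simulateBaselinePanel <- function(world) {
  cfg <- world@config
  set.seed(cfg$seed + 303L)
  G <- cfg$n_genes; C <- cfg$n_cells
  cellsv <- .cellIdsOf(world); drugs <- .drugIdsOf(world)
  mu0 <- rnorm(G)
  expr <- t(outer(rep(1, C), mu0) + world@cellEffects +
              world@rho %o% world@w)               # genes x cells
  dimnames(expr) <- list(.geneIdsOf(world), cellsv)

  tis_eff <- rnorm(3, 0, cfg$doubling_tissue_sd)
  names(tis_eff) <- paste0("tissue", 1:3)
  doubling <- cfg$doubling_t0_h - cfg$doubling_lambda * world@rho +
    tis_eff[world@tissue] + rnorm(C, 0, cfg$sigma_doubling)
  cells <- data.frame(cell_line_id = cellsv, tissue = world@tissue,
                      msi = world@msi, doubling_time_h = as.numeric(doubling),
                      stringsAsFactors = FALSE)

  max_dose <- max(cfg$doses_um)
  burden <- cfg$kappa * .logistic(cfg$hill_slope *
                                    (log10(max_dose) - world@potency))
  drug_tox <- rowMeans(burden) / cfg$kappa       # in (0, 1)
  grid <- expand.grid(cell = seq_len(C), drug = seq_along(drugs),
                      KEEP.OUT.ATTRS = FALSE)
  auc <- cfg$auc_base + cfg$auc_glds_scale * world@glds[grid$cell] -
    cfg$auc_tox_scale * drug_tox[grid$drug] +
    cfg$auc_moa_scale * world@pathwayState[cbind(grid$cell,
                                                 world@moaOf[grid$drug])] +
    rnorm(nrow(grid), 0, cfg$sigma_auc)
  sens <- data.frame(cell_line_id = cellsv[grid$cell],
                     drug_id = drugs[grid$drug], auc = as.numeric(auc),
                     stringsAsFactors = FALSE)
  list(expression = expr, cells = cells, sensitivity = sens,
       drug_toxicity = setNames(drug_tox, drugs))
}

#' Simulate ECFP-like fingerprints for the world's compounds
#'
#' Each MoA class has a prototype bit vector; each drug copies its class
#' prototype with independent per-bit flips.
#'
#' @param world a [SyntheticWorld-class].
#' @param n_bits number of bits (<= 256, the stored prototype width).
#' @param flip_prob per-bit flip probability.
#' @return An annotation data.frame with `perturbagen_id`, `moa` (class
#'   label), `moa_labels` (list column), `max_tested_log10_conc`, and a
#'   `fingerprints` attribute (drugs x bits 0/1 matrix).
#' @export
simulateFingerprints <- function(world, n_bits = 256L, flip_prob = 0.05) {
  cfg <- world@config
  if (n_bits > ncol(world@fingerprintPrototypes))
    stop("n_bits exceeds stored prototype width")
  set.seed(cfg$seed + 404L)
  drugs <- .drugIdsOf(world)
  proto <- world@fingerprintPrototypes[world@moaOf, seq_len(n_bits),
                                       drop = FALSE]
  flips <- matrix(runif(length(proto)) < flip_prob, nrow(proto))
  fp <- abs(proto - flips * 1L)
  rownames(fp) <- drugs
  ann <- data.frame(perturbagen_id = drugs,
                    moa = paste0("MoA", world@moaOf),
                    max_tested_log10_conc = log10(max(cfg$doses_um)),
                    stringsAsFactors = FALSE)
  ann$moa_labels <- as.list(ann$moa)
  attr(ann, "fingerprints") <- fp
  ann
}
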