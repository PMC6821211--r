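#' Score baseline expression with a CVS model
#'
#' Baseline expression is z-normalized per gene across cell lines
#' (`Z_gc = (E_gc - mu_g) / sigma_g`; zero-variance genes contribute 0) and
#' each cell line is scored as `sum_g beta_g * Z_gc` over the genes shared
#' with the model. Model genes absent from the panel are dropped with their
#' count logged; less than 50% overlap is an error.
#'
#' @param model a [ViabilityModel-class].
#' @param baseline genes x cells numeric matrix with gene_id rownames.
#' @param normalize `"genewise_z"` (default) or `"none"`.
#' @return A data.frame of class `"CvsScoreTable"`: `cell_line_id`, `score`;
#'   attributes `model_tag`, `normalization`, `n_genes_used`,
#'   `n_genes_dropped`.
#' @export
cvsScore <- function(model, baseline,
                     normalize = c("genewise_z", "none")) {
  stopifnot(is(model, "ViabilityModel"))
  normalize <- match.arg(normalize)
  genes <- names(model@beta)
  common <- intersect(genes, rownames(baseline))
  if (length(common) < 0.5 * length(genes))
    stop("cvsScore: gene overlap with model below 50% (",
         length(common), "/", length(genes), ")")
  E <- baseline[common, , drop = FALSE]
  if (normalize == "genewise_z") {
    mu <- rowMeans(E)
    sg <- apply(E, 1, sd)
    Z <- (E - mu) / ifelse(sg == 0, Inf, sg)   # constant gene -> 0
  } else Z <- E
  sc <- drop(crossprod(Z, model@beta[common]))
  out <- data.frame(cell_line_id = colnames(baseline), score = sc,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "model_tag") <- model@tag
  attr(out, "normalization") <- normalize
  attr(out, "n_genes_used") <- length(common)
  attr(out, "n_genes_dropped") <- length(genes) - length(common)
  class(out) <- c("CvsScoreTable", "data.frame")
  out
}

#' Per-drug sensitivity associations with the CVS score
#'
#' For every drug with at least `minCells` measured cell lines, fits
#' `sensitivity ~ CVS + tissue + MSI` by least squares and records the CVS
#' coefficient (effect size), its p-value and the Benjamini-Hochberg FDR
#' across drugs. Covariate levels that make the design rank deficient
#' (e.g. a single-level tissue factor) are dropped with a warning from `lm`
#' handled silently; the CVS coefficient is always estimable as long as the
#' scores vary.
#'
#' @param scores a `CvsScoreTable` (from [cvsScore()]).
#' @param sensitivity long data.frame: `cell_line_id`, `drug_id`, and the
#'   response named by `metric` (default `"auc"`; `"ln_ic50"` accepted).
#' @param tissue,msi named vectors (by cell_line_id) of tissue labels and MSI
#'   flags.
#' @param metric response column name.
#' @param minCells minimum cells per drug (default 8).
#' @return A data.frame of class `"DrugAssociationResult"`: `drug_id`,
#'   `effect`, `p`, `fdr`, `n_cells`.
#' @export
drugSensitivityAssociations <- function(scores, sensitivity, tissue, msi,
                                        metric = "auc", minCells = 8) {
  stopifnot(metric %in% colnames(sensitivity))
  sc <- setNames(scores$score, scores$cell_line_id)
  res <- lapply(split(sensitivity, sensitivity$drug_id), function(df) {
    df <- df[df$cell_line_id %in% names(sc), , drop = FALSE]
    if (nrow(df) < minCells) return(NULL)
    dat <- data.frame(y = df[[metric]], cvs = sc[df$cell_line_id],
                      tissue = factor(tissue[df$cell_line_id]),
                      msi = as.numeric(msi[df$cell_line_id]))
    # drop degenerate covariates rather than fitting a rank-deficient design
    form <- y ~ cvs
    if (nlevels(droplevels(dat$tissue)) > 1) form <- update(form, . ~ . + tissue)
    if (length(unique(dat$msi)) > 1) form <- update(form, . ~ . + msi)
    fit <- lm(form, data = dat)
    cf <- summary(fit)$coefficients
    if (!"cvs" %in% rownames(cf)) return(NULL)
    data.frame(drug_id = df$drug_id[1], effect = cf["cvs", 1],
               p = cf["cvs", 4], n_cells = nrow(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(drug_id = character(0), effect = numeric(0),
                      p = numeric(0), n_cells = integer(0))
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("DrugAssociationResult", "data.frame")
  out
}

#' @importFrom stats update
NULL

#' General level of drug sensitivity (GLDS) per cell line
#'
#' Fits the two-way additive model `sensitivity ~ cell + drug` to the whole
#' long sensitivity table with sum-to-zero constraints and returns the cell
#' effects. The overall constant is absorbed by the intercept, so the cell
#' effects are identified up to (and reported with) a zero mean; adding a
#' constant to all sensitivities leaves them unchanged.
#'
#' @param sensitivity long data.frame: `cell_line_id`, `drug_id`, response in
#'   the column named by `metric`.
#' @param metric response column (default `"auc"`).
#' @return Named numeric vector of per-cell GLDS effects (sum-to-zero).
#' @export
glds <- function(sensitivity, metric = "auc") {
  stopifnot(metric %in% colnames(sensitivity))
  cellf <- factor(sensitivity$cell_line_id)
  drugf <- factor(sensitivity$drug_id)
  if (any(table(cellf) < 2) || any(table(drugf) < 2))
    stop("glds: every cell and drug must appear at least twice")
  dat <- data.frame(y = sensitivity[[metric]], cell = cellf, drug = drugf)
  fit <- lm(y ~ cell + drug, data = dat,
            contrasts = list(cell = "contr.sum", drug = "contr.sum"))
  cf <- coef(fit)
  k <- nlevels(cellf)
  ce <- cf[paste0("cell", seq_len(k - 1))]
  eff <- c(ce, -sum(ce))
  names(eff) <- levels(cellf)
  eff
}

#' Partial correlation given a factor covariate
#'
#' Residualizes `x` and `y` on the factor's group means (the linear models
#' `x ~ factor` and `y ~ factor`) and returns the Pearson correlation of the
#' residuals. When the factor is constant this is the plain Pearson
#' correlation. If either residual vector has zero variance the correlation
#' is undefined and returned as `NA` with `flagged = TRUE`.
#'
#' @param x,y numeric vectors (length >= 3).
#' @param factor factor-like covariate of the same length.
#' @return A list: `r`, `n`, `flagged`.
#' @export
partialCorrelationFactor <- function(x, y, factor) {
  stopifnot(length(x) == length(y), length(x) == length(factor))
  if (length(x) < 3) stop("partialCorrelationFactor: need at least 3 points")
  f <- as.character(factor)
  rx <- x - ave(x, f)
  ry <- y - ave(y, f)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(r = NA_real_, n = length(x), flagged = TRUE))
  list(r = cor(rx, ry), n = length(x), flagged = FALSE)
}

#' @importFrom stats ave
NULL

#' Null-signature comparison of a downstream association statistic
#'
#' Re-derives the CVS model under a null scheme and asks how often the
#' downstream statistic of interest is at least as large as the reference
#' value computed with the real model. Null schemes: `permute_genes`
#' (shuffle the gene labels of the training signatures before fitting),
#' `permute_samples` (shuffle the viability vector), `single_gene` (skip the
#' model; use each sampled gene's baseline expression as the score vector).
#'
#' @param ds the training [MatchedDataset-class].
#' @param baseline genes x cells baseline expression matrix.
#' @param statFun function(scores: CvsScoreTable-like data.frame) -> numeric
#'   scalar; the same function must have produced `referenceStat`.
#' @param referenceStat numeric scalar computed with the real model.
#' @param mode one of `"permute_genes"`, `"permute_samples"`,
#'   `"single_gene"`.
#' @param nReps number of null replicates.
#' @param alpha ridge penalty for the refits.
#' @param seed RNG seed.
#' @return A list: `exceedance` (fraction of null stats >= reference),
#'   `null_stats`, `mode`, `n_reps`.
#' @export
nullSignatureComparison <- function(ds, baseline, statFun, referenceStat,
                                    mode = c("permute_genes",
                                             "permute_samples",
                                             "single_gene"),
                                    nReps = 100, alpha = 1.0, seed = 1) {
  stopifnot(is(ds, "MatchedDataset"))
  mode <- match.arg(mode)
  set.seed(seed)
  nulls <- numeric(nReps)
  for (i in seq_len(nReps)) {
    if (mode == "single_gene") {
      g <- sample(rownames(baseline), 1)
      scores <- data.frame(cell_line_id = colnames(baseline),
                           score = as.numeric(scale(baseline[g, ])),
                           stringsAsFactors = FALSE)
      scores$score[is.na(scores$score)] <- 0
    } else {
      Xp <- ds@X
      yp <- ds@y
      if (mode == "permute_genes") colnames(Xp) <- sample(colnames(Xp))
      else yp <- sample(yp)
      model <- fitRidge(list(X = Xp, y = yp), alpha)
      scores <- cvsScore(model, baseline)
    }
    nulls[i] <- statFun(scores)
  }
  list(exceedance = mean(nulls >= referenceStat), null_stats = nulls,
       mode = mode, n_reps = nReps)
}
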