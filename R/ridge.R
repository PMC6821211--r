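.ridgeSolve <- function(X, y, alpha) {
  # unpenalized intercept via centering; coefficient path solved through the
  # SVD of the centered design (stable for any n/G ratio)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  shrink <- sv$d[keep] / (sv$d[keep]^2 + alpha)
  beta <- sv$v[, keep, drop = FALSE] %*%
    (shrink * drop(crossprod(sv$u[, keep, drop = FALSE], y - ybar)))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  list(beta = beta, intercept = ybar - sum(xbar * beta))
}

#' Fit a ridge cell-viability-signature model
#'
#' Solves `min ||y - X beta - b||^2 + alpha ||beta||^2` with an unpenalized
#' intercept `b` and no feature standardization (landmark z-scores already
#' share a scale). The coefficient vector is the operational cell viability
#' signature.
#'
#' @param ds a [MatchedDataset-class] (or a plain list with `X` and `y`).
#' @param alpha ridge penalty (> 0), default 1.
#' @return A [ViabilityModel-class].
#' @export
fitRidge <- function(ds, alpha = 1.0) {
  if (is(ds, "MatchedDataset")) {
    X <- ds@X; y <- ds@y; tag <- ds@tag
  } else {
    X <- as.matrix(ds$X); y <- as.numeric(ds$y); tag <- ""
  }
  if (nrow(X) < 2) stop("fitRidge: need at least 2 observations")
  if (anyNA(X) || anyNA(y)) stop("fitRidge: missing values not allowed")
  if (alpha <= 0) stop("fitRidge: alpha must be > 0")
  fit <- .ridgeSolve(X, y, alpha)
  new("ViabilityModel", beta = fit$beta, intercept = fit$intercept,
      alpha = alpha, tag = tag)
}

#' One-hot / dose design matrix for the ID-based "standard" model
#' @keywords internal
.standardDesign <- function(meta, cells, perts, withDose) {
  n <- nrow(meta)
  Xc <- matrix(0, n, length(cells),
               dimnames = list(NULL, paste0("cell:", cells)))
  hit <- match(meta$cell_line_id, cells)
  ok <- !is.na(hit)
  Xc[cbind(which(ok), hit[ok])] <- 1
  Xp <- matrix(0, n, length(perts),
               dimnames = list(NULL, paste0("pert:", perts)))
  hit <- match(meta$perturbagen_id, perts)
  ok <- !is.na(hit)
  Xp[cbind(which(ok), hit[ok])] <- 1
  X <- cbind(Xc, Xp)
  if (withDose)
    X <- cbind(X, log10_dose = log10(meta$dose_signature_um))
  X
}

#' Fit the ID-based "standard" baseline model
#'
#' Ridge regression (same penalty as the signature model) over one-hot cell
#' line IDs, one-hot perturbagen IDs, and — for compound data — the log10
#' dose. Unseen IDs at prediction time map to all-zero encodings, so the
#' prediction degrades to the intercept plus the dose term.
#'
#' @param ds a [MatchedDataset-class].
#' @param alpha ridge penalty (> 0).
#' @return A list of class `"StandardModel"` with the fitted coefficients and
#'   the ID vocabularies.
#' @export
fitStandard <- function(ds, alpha = 1.0) {
  stopifnot(is(ds, "MatchedDataset"))
  meta <- ds@meta
  cells <- sort(unique(meta$cell_line_id))
  perts <- sort(unique(meta$perturbagen_id))
  withDose <- ds@metricType == "fraction" &&
    all(is.finite(meta$dose_signature_um))
  X <- .standardDesign(meta, cells, perts, withDose)
  fit <- .ridgeSolve(X, ds@y, alpha)
  structure(list(beta = fit$beta, intercept = fit$intercept, alpha = alpha,
                 cells = cells, perts = perts, withDose = withDose,
                 tag = ds@tag),
            class = "StandardModel")
}

#' @export
print.StandardModel <- function(x, ...) {
  cat("StandardModel:", length(x$cells), "cells,", length(x$perts),
      "perturbagens", if (x$withDose) "+ log10 dose", "\n")
  invisible(x)
}

#' Predict viability from signatures
#'
#' Columns of `newdata` are aligned to the model's gene order by name (a
#' permutation is accepted; missing model genes are an error).
#'
#' @param model a [ViabilityModel-class] or `StandardModel`.
#' @param newdata instances x genes matrix, a [SignatureSet-class], or — for
#'   the standard model — a [MatchedDataset-class]/meta data.frame.
#' @return Numeric vector of predictions.
#' @export
predictViability <- function(model, newdata) {
  if (is(model, "ViabilityModel")) {
    X <- if (is(newdata, "SignatureSet")) sigMatrix(newdata)
         else if (is(newdata, "MatchedDataset")) newdata@X
         else as.matrix(newdata)
    genes <- names(model@beta)
    if (!is.null(colnames(X))) {
      miss <- setdiff(genes, colnames(X))
      if (length(miss))
        stop("predictViability: ", length(miss),
             " model gene(s) missing from newdata, e.g. ", miss[1])
      X <- X[, genes, drop = FALSE]
    } else if (ncol(X) != length(genes))
      stop("predictViability: unnamed columns and width mismatch")
    drop(X %*% model@beta) + model@intercept
  } else if (inherits(model, "StandardModel")) {
    meta <- if (is(newdata, "MatchedDataset")) newdata@meta
            else as.data.frame(newdata)
    X <- .standardDesign(meta, model$cells, model$perts, model$withDose)
    drop(X %*% model$beta) + model$intercept
  } else stop("predictViability: unknown model type")
}

#' Random sub-sampling validation of viability models
#'
#' Within mode (`testDs = NULL`): in each of `nIter` iterations a random half
#' of the dataset trains the model and the other half is scored; the Pearson
#' correlation between predicted and observed viability is recorded. Across
#' mode: the model is trained on a random half of `trainDs` and evaluated on
#' ALL of `testDs`. `modelType = "standard"` runs the ID-based baseline
#' (within mode only is meaningful across screens). Iteration `i` uses seed
#' `seed + i`.
#'
#' @param trainDs a [MatchedDataset-class].
#' @param testDs optional [MatchedDataset-class] for across-dataset
#'   evaluation.
#' @param nIter number of random sub-samples (default 20).
#' @param frac training fraction per iteration (default 0.5).
#' @param alpha ridge penalty.
#' @param modelType `"signature"` or `"standard"`.
#' @param seed integer; base seed for the iteration splits.
#' @return A list of class `"ValidationReport"`: `r` (per-iteration Pearson,
#'   `NA` when the test response is degenerate, with a warning), `mode`,
#'   `n_iter`, `train_tag`, `test_tag`.
#' @export
validateModel <- function(trainDs, testDs = NULL, nIter = 20, frac = 0.5,
                          alpha = 1.0, modelType = c("signature", "standard"),
                          seed = 1) {
  stopifnot(is(trainDs, "MatchedDataset"))
  modelType <- match.arg(modelType)
  n <- nrow(trainDs@X)
  rs <- numeric(nIter)
  for (i in seq_len(nIter)) {
    set.seed(seed + i)
    tr <- sample.int(n, floor(frac * n))
    sub <- MatchedDataset(trainDs@X[tr, , drop = FALSE], trainDs@y[tr],
                          trainDs@meta[tr, , drop = FALSE],
                          trainDs@metricType, trainDs@tag)
    model <- if (modelType == "signature") fitRidge(sub, alpha)
             else fitStandard(sub, alpha)
    if (is.null(testDs)) {
      te <- setdiff(seq_len(n), tr)
      pred <- predictViability(model,
                if (modelType == "signature") trainDs@X[te, , drop = FALSE]
                else trainDs@meta[te, , drop = FALSE])
      obs <- trainDs@y[te]
    } else {
      pred <- predictViability(model,
                if (modelType == "signature") testDs@X else testDs@meta)
      obs <- testDs@y
    }
    if (sd(obs) == 0 || sd(pred) == 0) {
      warning("validateModel: degenerate test response in iteration ", i)
      rs[i] <- NA_real_
    } else rs[i] <- cor(pred, obs)
  }
  structure(list(r = rs,
                 mode = if (modelType == "standard") "standard"
                        else if (is.null(testDs)) "within" else "across",
                 n_iter = nIter, train_tag = trainDs@tag,
                 test_tag = if (is.null(testDs)) trainDs@tag else testDs@tag),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport [", x$mode, "] ", x$train_tag, " -> ", x$test_tag,
      ": mean r = ", signif(mean(x$r, na.rm = TRUE), 3),
      " (", x$n_iter, " iterations)\n", sep = "")
  invisible(x)
}
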