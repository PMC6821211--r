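#' Cell-line features from baseline expression
#'
#' Standardizes baseline expression per gene across cell lines
#' (`Z_gc = (E_gc - mu_g) / sigma_g`; zero-variance genes contribute 0),
#' scores every weighted gene set (TF regulons and pathway sets) per cell as
#' `sum_g weight_g * Z_gc`, and appends a tissue one-hot block.
#'
#' @param baseline genes x cells matrix (>= 2 cells).
#' @param tissue named (by cell) or aligned tissue label vector.
#' @param tfSets,pathwaySets named lists of weighted gene sets (named numeric
#'   vectors gene_id -> weight).
#' @return Cells x features numeric matrix (rownames = cell ids).
#' @export
buildCellFeatures <- function(baseline, tissue, tfSets = list(),
                              pathwaySets = list()) {
  if (ncol(baseline) < 2) stop("buildCellFeatures: need at least 2 cells")
  mu <- rowMeans(baseline)
  sg <- apply(baseline, 1, sd)
  Z <- (baseline - mu) / ifelse(sg == 0, Inf, sg)
  sets <- c(tfSets, pathwaySets)
  score1 <- function(set) {
    common <- intersect(names(set), rownames(Z))
    if (!length(common)) return(rep(0, ncol(Z)))
    drop(crossprod(Z[common, , drop = FALSE], set[common]))
  }
  feat <- if (length(sets))
    vapply(sets, score1, numeric(ncol(baseline))) else
    matrix(0, ncol(baseline), 0)
  tis <- if (!is.null(names(tissue))) tissue[colnames(baseline)]
         else setNames(tissue, colnames(baseline))
  lev <- sort(unique(tis))
  onehot <- vapply(lev, function(l) as.numeric(tis == l),
                   numeric(ncol(baseline)))
  colnames(onehot) <- paste0("tissue:", lev)
  out <- cbind(feat, onehot)
  rownames(out) <- colnames(baseline)
  out
}

#' Drug-level features for sensitivity models
#'
#' One feature variant per model run:
#' \describe{
#'   \item{`target` / `pathway`}{one-hot encodings of an annotation map
#'     (drug -> label set); unseen labels at prediction time are all-zero.}
#'   \item{`fingerprint`}{ECFP-like bit matrix passed through.}
#'   \item{`consensus`}{principal-component scores of MODZ consensus
#'     signatures — see [fitSignaturePca()]; the PCA must be fit on
#'     training-fold drugs only and applied to the rest, which is why the
#'     projection is a separate step inside [fitEvalRf()].}
#' }
#'
#' @param variant one of `"target"`, `"pathway"`, `"fingerprint"`.
#' @param annotation named list drug -> label vector (for one-hot variants)
#'   or drugs x bits matrix (for `"fingerprint"`).
#' @return Drugs x features numeric matrix.
#' @export
buildDrugFeatures <- function(variant = c("target", "pathway", "fingerprint"),
                              annotation) {
  variant <- match.arg(variant)
  if (variant == "fingerprint") {
    fp <- as.matrix(annotation)
    colnames(fp) <- paste0("bit", seq_len(ncol(fp)))
    return(fp)
  }
  labels <- sort(unique(unlist(annotation)))
  out <- vapply(labels, function(l)
    vapply(annotation, function(a) as.numeric(l %in% a), numeric(1)),
    numeric(length(annotation)))
  rownames(out) <- names(annotation)
  colnames(out) <- paste0(variant, ":", labels)
  out
}

#' PCA reduction of consensus signature features
#'
#' Fits a centered PCA on the (training) consensus signature matrix,
#' retaining components up to 95% explained variance, capped at `maxComp`
#' (default 40). Returns a projector usable on unseen drugs.
#'
#' @param consensus drugs x genes consensus signature matrix (>= 2 drugs).
#' @param varTarget cumulative explained-variance target.
#' @param maxComp component cap.
#' @return A list of class `"SignaturePca"`: `center`, `rotation`,
#'   `n_comp`, `var_explained`; use [projectSignaturePca()] to transform.
#' @export
fitSignaturePca <- function(consensus, varTarget = 0.95, maxComp = 40) {
  if (nrow(consensus) < 2)
    stop("fitSignaturePca: need at least 2 drugs")
  pca <- prcomp(consensus, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- min(which(cum >= varTarget)[1], maxComp, length(pca$sdev))
  if (is.na(k)) k <- min(maxComp, length(pca$sdev))
  structure(list(center = pca$center,
                 rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 n_comp = k, var_explained = cum[k]),
            class = "SignaturePca")
}

#' @rdname fitSignaturePca
#' @param pca a `SignaturePca`.
#' @param newdata drugs x genes matrix.
#' @export
projectSignaturePca <- function(pca, newdata) {
  sweep(as.matrix(newdata), 2, pca$center) %*% pca$rotation
}

#' Split drugs into train/test folds by target scheme
#'
#' \describe{
#'   \item{`random`}{50/50 split of the drugs.}
#'   \item{`shared_target`}{each target class with >= 2 drugs contributes at
#'     least one drug to the training fold, so every test drug has a train
#'     drug sharing a target; singleton classes are assigned to train with a
#'     warning.}
#'   \item{`different_target`}{drugs are grouped into connected components of
#'     the target-sharing graph and whole components are assigned to folds
#'     (greedy size balancing), so no target spans both folds.}
#' }
#'
#' @param drugs character vector of drug ids.
#' @param targets named list drug -> target label vector.
#' @param scheme `"random"`, `"shared_target"` or `"different_target"`.
#' @param seed RNG seed.
#' @return A list of class `"SplitScheme"`: `train`, `test`, `scheme`,
#'   `seed`.
#' @export
makeSplit <- function(drugs, targets,
                      scheme = c("random", "shared_target",
                                 "different_target"),
                      seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  n <- length(drugs)
  if (scheme == "random") {
    tr <- sample(drugs, floor(n / 2))
    te <- setdiff(drugs, tr)
  } else if (scheme == "shared_target") {
    # primary class = first target label
    cls <- vapply(targets[drugs], `[[`, character(1), 1)
    tr <- character(0); te <- character(0)
    for (cl in sample(unique(cls))) {
      members <- sample(drugs[cls == cl])
      if (length(members) == 1L) {
        warning("makeSplit: singleton target class ", sQuote(cl),
                " assigned to train")
        tr <- c(tr, members)
      } else {
        k <- ceiling(length(members) / 2)
        tr <- c(tr, members[seq_len(k)])
        te <- c(te, members[-seq_len(k)])
      }
    }
  } else {
    comp <- .targetComponents(drugs, targets)
    sizes <- vapply(comp, length, integer(1))
    tr <- character(0); te <- character(0)
    for (ci in sample(seq_along(comp))) {
      if (length(tr) <= length(te)) tr <- c(tr, comp[[ci]])
      else te <- c(te, comp[[ci]])
    }
    if (!length(te)) { te <- tr[seq_len(1)]; tr <- tr[-1] }  # degenerate guard
  }
  structure(list(train = sort(tr), test = sort(te), scheme = scheme,
                 seed = seed), class = "SplitScheme")
}

# connected components of the drug graph linking drugs that share a target
.targetComponents <- function(drugs, targets) {
  lab2drugs <- list()
  for (d in drugs)
    for (l in targets[[d]])
      lab2drugs[[l]] <- c(lab2drugs[[l]], d)
  parent <- setNames(seq_along(drugs), drugs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ds in lab2drugs)
    for (d in ds[-1]) {
      a <- find(match(ds[1], drugs)); b <- find(match(d, drugs))
      if (a != b) parent[b] <- a
    }
  roots <- vapply(seq_along(drugs), find, numeric(1))
  unname(split(drugs, roots))
}

#' Structural check of a split against its scheme
#' @param split a `SplitScheme`.
#' @param targets named list drug -> target label vector.
#' @return TRUE, or an error describing the violated invariant.
#' @export
checkSplit <- function(split, targets) {
  if (length(intersect(split$train, split$test)))
    stop("checkSplit: folds overlap")
  if (split$scheme == "shared_target") {
    for (d in split$test) {
      hit <- any(vapply(targets[split$train], function(t)
        length(intersect(t, targets[[d]])) > 0, logical(1)))
      if (!hit) stop("checkSplit: test drug ", d, " has no shared-target ",
                     "partner in train")
    }
  }
  if (split$scheme == "different_target") {
    t_tr <- unique(unlist(targets[split$train]))
    t_te <- unique(unlist(targets[split$test]))
    if (length(intersect(t_tr, t_te)))
      stop("checkSplit: a target spans both folds")
  }
  TRUE
}

#' Random-forest drug sensitivity models under drug-level splits
#'
#' For each of `nRuns` runs: resample the split (seed + run), build the drug
#' feature block (for `drugFeatures = "consensus"` the PCA is fit on
#' training-fold consensus signatures only and applied to the test fold),
#' concatenate cell and drug features per (cell, drug) row of the
#' sensitivity table, fit a random forest regression (`nTrees` trees) on the
#' training-drug rows, predict the test-drug rows, compute the per-cell
#' Pearson correlation between predicted and observed sensitivity (cells
#' with fewer than 3 test drugs are excluded; constant predictions count as
#' r = 0), and average over cells.
#'
#' @param cellFeats cells x features matrix (rownames = cell ids).
#' @param drugFeats drugs x features matrix (one-hot/fingerprint variants)
#'   or, when `consensus` is supplied, ignored.
#' @param consensus optional drugs x genes consensus signature matrix;
#'   enables the consensus-PCA feature variant.
#' @param sensitivity long data.frame: `cell_line_id`, `drug_id`, response
#'   in `metric`.
#' @param targets named list drug -> target labels (drives the splits).
#' @param scheme split scheme, see [makeSplit()].
#' @param metric response column (default `"auc"`).
#' @param nTrees random forest size (default 50).
#' @param nRuns number of random sub-sampling runs (default 20).
#' @param seed base seed; run i uses `seed + i`.
#' @return A list of class `"RfReport"`: `mean_r` (per-run averages),
#'   `per_cell_r` (list of named vectors), `scheme`, `n_runs`, `n_trees`.
#' @export
fitEvalRf <- function(cellFeats, drugFeats = NULL, consensus = NULL,
                      sensitivity, targets,
                      scheme = c("random", "shared_target",
                                 "different_target"),
                      metric = "auc", nTrees = 50, nRuns = 20, seed = 1) {
  scheme <- match.arg(scheme)
  drugs <- sort(unique(sensitivity$drug_id))
  mean_r <- numeric(nRuns)
  per_cell <- vector("list", nRuns)
  for (run in seq_len(nRuns)) {
    sp <- makeSplit(drugs, targets, scheme, seed = seed + run)
    checkSplit(sp, targets)                       # leakage guard, every run
    if (!is.null(consensus)) {
      pca <- fitSignaturePca(consensus[sp$train, , drop = FALSE])
      df_tr <- projectSignaturePca(pca, consensus[sp$train, , drop = FALSE])
      df_te <- projectSignaturePca(pca, consensus[sp$test, , drop = FALSE])
      dfeat <- rbind(df_tr, df_te)
      colnames(dfeat) <- paste0("pc", seq_len(ncol(dfeat)))
    } else {
      dfeat <- drugFeats
    }
    rows_tr <- sensitivity$drug_id %in% sp$train
    rows_te <- sensitivity$drug_id %in% sp$test
    featRows <- function(rows) {
      cbind(cellFeats[sensitivity$cell_line_id[rows], , drop = FALSE],
            dfeat[sensitivity$drug_id[rows], , drop = FALSE])
    }
    Xtr <- featRows(rows_tr); Xte <- featRows(rows_te)
    ytr <- sensitivity[[metric]][rows_tr]
    yte <- sensitivity[[metric]][rows_te]
    fit <- ranger::ranger(x = as.data.frame(Xtr), y = ytr,
                          num.trees = nTrees, seed = seed + run,
                          num.threads = 1)
    pred <- predict(fit, data = as.data.frame(Xte),
                    num.threads = 1)$predictions
    cells_te <- sensitivity$cell_line_id[rows_te]
    rs <- vapply(split(seq_along(pred), cells_te), function(idx) {
      if (length(idx) < 3) return(NA_real_)
      if (sd(pred[idx]) == 0 || sd(yte[idx]) == 0) return(0)
      cor(pred[idx], yte[idx])
    }, numeric(1))
    per_cell[[run]] <- rs[!is.na(rs)]
    mean_r[run] <- mean(rs, na.rm = TRUE)
  }
  structure(list(mean_r = mean_r, per_cell_r = per_cell, scheme = scheme,
                 n_runs = nRuns, n_trees = nTrees),
            class = "RfReport")
}

#' @export
print.RfReport <- function(x, ...) {
  cat("RfReport [", x$scheme, "]: mean per-cell r = ",
      signif(mean(x$mean_r), 3), " over ", x$n_runs, " runs (",
      x$n_trees, " trees)\n", sep = "")
  invisible(x)
}
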