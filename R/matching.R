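#' Collapse duplicate signature conditions with MODZ
#'
#' Signatures sharing the same condition key — (perturbagen, cell, time,
#' dose) for compounds, (perturbagen, cell, time) otherwise — are replaced by
#' their [modz()] consensus; single-row groups pass through unchanged. Row
#' order follows the first occurrence of each key.
#'
#' @param sigset a [SignatureSet-class].
#' @return A [SignatureSet-class] with one row per condition.
#' @export
collapseConditions <- function(sigset) {
  stopifnot(is(sigset, "SignatureSet"))
  ii <- instanceInfo(sigset)
  X <- sigMatrix(sigset)
  key <- ifelse(ii$perturbagen_type == "compound",
                paste(ii$perturbagen_id, ii$cell_line_id, ii$time_h,
                      ii$dose_um, sep = "\r"),
                paste(ii$perturbagen_id, ii$cell_line_id, ii$time_h,
                      sep = "\r"))
  first <- !duplicated(key)
  if (all(first)) return(sigset)
  ord_keys <- key[first]
  idx <- split(seq_len(nrow(X)), factor(key, levels = ord_keys))
  Xn <- t(vapply(idx, function(i)
    if (length(i) == 1L) X[i, ] else modz(X[i, , drop = FALSE])$consensus,
    numeric(ncol(X))))
  meta <- ii[first, , drop = FALSE]
  meta$instance_id <- vapply(idx, function(i) ii$instance_id[i[1L]],
                             character(1))
  SignatureSet(Xn, meta, geneInfo(sigset))
}

#' Match signature instances to viability records
#'
#' For every viability record, candidate signature instances share the cell
#' line and perturbagen. For compounds, the instance minimizing the absolute
#' log10 dose difference is paired iff that minimum is strictly below
#' `toleranceLog10` (ties broken by lower signature dose, then instance id);
#' for shRNA, dose is ignored and the key match is exact. Unmatched viability
#' records are dropped. One signature may serve several time points: matching
#' is done within each signature time separately when `perTime = TRUE`
#' (default), so the same viability value is reused across times, and each
#' viability record pairs with at most one instance per time point.
#'
#' @param sigset a condition-collapsed [SignatureSet-class].
#' @param viab a validated viability table (see [readPipelineTable()]).
#' @param toleranceLog10 strict upper bound on `|log10(dose_sig / dose_viab)|`
#'   (default 0.2, about a 1.5-fold concentration difference).
#' @param tag provenance tag for the result.
#' @param perTime match within each signature time point separately.
#' @return A [MatchedDataset-class]; empty (0 rows, with a warning) when the
#'   screens share no cells or perturbagens.
#' @export
matchRecords <- function(sigset, viab, toleranceLog10 = 0.2, tag = "matched",
                         perTime = TRUE) {
  stopifnot(is(sigset, "SignatureSet"))
  viab <- validateViabilityTable(viab)
  ii <- instanceInfo(sigset)
  X <- sigMatrix(sigset)
  empty <- function() {
    warning("matchRecords: no viability record matched a signature ",
            "instance; empty dataset")
    MatchedDataset(X[0, , drop = FALSE], numeric(0),
                   data.frame(instance_id = character(0),
                              cell_line_id = character(0),
                              perturbagen_id = character(0),
                              time_h = numeric(0),
                              dose_signature_um = numeric(0),
                              dose_viability_um = numeric(0),
                              delta_log10_dose = numeric(0)),
                   metricType = unique(viab$metric_type), tag = tag)
  }
  sig_key <- paste(ii$cell_line_id, ii$perturbagen_id, sep = "\r")
  v_key <- paste(viab$cell_line_id, viab$perturbagen_id, sep = "\r")
  if (!any(v_key %in% sig_key)) return(empty())
  times <- if (perTime) sort(unique(ii$time_h)) else NA
  picked_sig <- integer(0); picked_v <- integer(0)
  for (tm in times) {
    in_t <- if (perTime) ii$time_h == tm else rep(TRUE, nrow(ii))
    cand <- split(which(in_t), sig_key[in_t])
    for (vi in seq_len(nrow(viab))) {
      rows <- cand[[v_key[vi]]]
      if (is.null(rows)) next
      if (viab$metric_type[vi] == "fraction" || !is.na(viab$dose_um[vi])) {
        dlog <- abs(log10(ii$dose_um[rows]) - log10(viab$dose_um[vi]))
        ok <- which(is.finite(dlog) & dlog < toleranceLog10)
        if (!length(ok)) next
        # smallest |delta|, ties by lower signature dose, then instance_id
        o <- order(dlog[ok], ii$dose_um[rows][ok],
                   ii$instance_id[rows][ok])[1L]
        pick <- rows[ok][o]
      } else {
        pick <- rows[order(ii$instance_id[rows])][1L]
      }
      picked_sig <- c(picked_sig, pick)
      picked_v <- c(picked_v, vi)
    }
  }
  if (!length(picked_v)) return(empty())
  meta <- data.frame(
    instance_id = ii$instance_id[picked_sig],
    cell_line_id = ii$cell_line_id[picked_sig],
    perturbagen_id = ii$perturbagen_id[picked_sig],
    time_h = ii$time_h[picked_sig],
    dose_signature_um = ii$dose_um[picked_sig],
    dose_viability_um = viab$dose_um[picked_v],
    delta_log10_dose = abs(log10(ii$dose_um[picked_sig]) -
                             log10(viab$dose_um[picked_v])),
    stringsAsFactors = FALSE)
  ord <- order(meta$time_h, meta$instance_id)
  MatchedDataset(X[picked_sig[ord], , drop = FALSE],
                 viab$viability[picked_v[ord]],
                 meta[ord, , drop = FALSE],
                 metricType = unique(viab$metric_type), tag = tag)
}

#' Split a matched dataset by signature time point
#'
#' @param ds a [MatchedDataset-class].
#' @return A named list of [MatchedDataset-class], one per `time_h`, tags
#'   suffixed `"-{t}h"`; the union of the splits is the input.
#' @export
splitByTime <- function(ds) {
  stopifnot(is(ds, "MatchedDataset"))
  times <- sort(unique(ds@meta$time_h))
  out <- lapply(times, function(tm) {
    i <- ds@meta$time_h == tm
    MatchedDataset(ds@X[i, , drop = FALSE], ds@y[i],
                   ds@meta[i, , drop = FALSE], ds@metricType,
                   tag = paste0(ds@tag, "-", tm, "h"))
  })
  names(out) <- as.character(times)
  out
}

#' One-call construction of the matched, time-split training datasets
#'
#' Collapses duplicate conditions, matches against the viability table, and
#' splits by time.
#' @inheritParams matchRecords
#' @return Named list of per-time [MatchedDataset-class] objects.
#' @export
composeDatasets <- function(sigset, viab, toleranceLog10 = 0.2,
                            tag = "matched") {
  splitByTime(matchRecords(collapseConditions(sigset), viab,
                           toleranceLog10, tag = tag))
}
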