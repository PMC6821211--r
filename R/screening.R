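#' Predict viability for a whole signature screen
#'
#' Applies a CVS model to every instance of a signature set, carrying the
#' full instance metadata through.
#'
#' @param model a [ViabilityModel-class].
#' @param sigset a [SignatureSet-class].
#' @return The instance metadata data.frame with an added `predicted`
#'   column.
#' @export
predictScreen <- function(model, sigset) {
  stopifnot(is(sigset, "SignatureSet"))
  out <- instanceInfo(sigset)
  out$predicted <- predictViability(model, sigset)
  out
}

#' Per-compound extremes of predicted viability
#'
#' For each compound, restricts to instances at that compound's own maximum
#' tested dose (when `restrictToHighestDose`) and records the minimum (most
#' toxic) and maximum (least toxic / most proliferative) prediction across
#' cells and times, with the cell lines attaining them. Compounds with no
#' instance left after the dose filter are excluded with a warning.
#'
#' @param predictions data.frame from [predictScreen()] (compound rows).
#' @param restrictToHighestDose logical, default TRUE.
#' @return A data.frame of class `"CompoundScreenResult"`: `perturbagen_id`,
#'   `min_pred`, `max_pred`, `argmin_cell`, `argmax_cell`, `n_instances`.
#' @export
compoundExtremes <- function(predictions, restrictToHighestDose = TRUE) {
  df <- predictions[predictions$perturbagen_type == "compound", , drop = FALSE]
  res <- lapply(split(df, df$perturbagen_id), function(d) {
    if (restrictToHighestDose) {
      keep <- !is.na(d$dose_um) & d$dose_um == max(d$dose_um, na.rm = TRUE)
      d <- d[keep, , drop = FALSE]
    }
    if (!nrow(d)) return(NULL)
    data.frame(perturbagen_id = d$perturbagen_id[1],
               min_pred = min(d$predicted), max_pred = max(d$predicted),
               argmin_cell = d$cell_line_id[which.min(d$predicted)],
               argmax_cell = d$cell_line_id[which.max(d$predicted)],
               n_instances = nrow(d), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped) warning("compoundExtremes: ", dropped,
                       " compound(s) had no instance at their maximum dose")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("CompoundScreenResult", "data.frame")
  out
}

#' Classify compounds by predicted toxicity and selectivity
#'
#' A compound is toxic when its minimum prediction falls below `toxicThr`:
#' `general_toxic` if the maximum is also below it (toxic in every screened
#' cell), else `selective_toxic`. Non-toxic compounds with a maximum above
#' `prolifThr` are `proliferative`; the rest are `neutral`. With
#' `percentileFrom` supplied, the thresholds are instead the 5th and 95th
#' percentiles of that viability vector (the general path for fraction-scale
#' predictions); the fixed defaults -3 / 1.5 are on the shRNA
#' log-fold-change scale and should only be applied to predictions from
#' LFC-trained models.
#'
#' @param extremes a `CompoundScreenResult` from [compoundExtremes()].
#' @param toxicThr,prolifThr fixed thresholds (`toxicThr < prolifThr`).
#' @param percentileFrom optional viability vector; when given, thresholds
#'   are its 5% and 95% quantiles (type-7).
#' @return The input with added `class` column and a `thresholds` attribute.
#' @export
classifyCompounds <- function(extremes, toxicThr = -3, prolifThr = 1.5,
                              percentileFrom = NULL) {
  if (!is.null(percentileFrom)) {
    qs <- quantile(percentileFrom, c(0.05, 0.95), names = FALSE)
    toxicThr <- qs[1]; prolifThr <- qs[2]
  }
  if (!toxicThr < prolifThr)
    stop("classifyCompounds: toxicThr must be below prolifThr")
  cls <- ifelse(extremes$min_pred < toxicThr,
                ifelse(extremes$max_pred < toxicThr, "general_toxic",
                       "selective_toxic"),
                ifelse(extremes$max_pred > prolifThr, "proliferative",
                       "neutral"))
  extremes$class <- cls
  attr(extremes, "thresholds") <- c(toxic = toxicThr, proliferative = prolifThr)
  extremes
}

#' Delta-concentration sensitivity metric
#'
#' Difference between a log10 sensitivity metric (e.g. GI50) and the maximal
#' tested log10 concentration. Screens assign the maximal tested
#' concentration when the effect level is not reached, so `delta < 0`
#' (strictly) marks a drug effective within the tested range.
#'
#' @param metricLog10Conc numeric vector of log10 metric concentrations.
#' @param maxTestedLog10Conc aligned vector of maximal tested log10
#'   concentrations.
#' @return A data.frame: `delta`, `effective` (logical, `delta < 0`).
#' @export
deltaConcentration <- function(metricLog10Conc, maxTestedLog10Conc) {
  stopifnot(length(metricLog10Conc) == length(maxTestedLog10Conc))
  d <- metricLog10Conc - maxTestedLog10Conc
  data.frame(delta = d, effective = d < 0)
}

#' External-benchmark ROC/PR evaluation of screen predictions
#'
#' Scores each (cell, compound) pair with its LOWEST predicted viability
#' across available signatures, negated so that higher scores mean more
#' likely effective, and evaluates against a binary effectiveness truth with
#' [binaryScoreEval()]. Supplying `comparatorScore` (e.g. a second screen's
#' AUC, lower = more sensitive) instead evaluates that external metric on the
#' same pairs — the "ground truth" comparator path.
#'
#' @param predictions data.frame from [predictScreen()].
#' @param truthTable data.frame: `cell_line_id`, `perturbagen_id`,
#'   `effective` (logical/0-1).
#' @param comparatorScore optional named-by-pair numeric vector or a column
#'   name in `truthTable` to use as score (negated, lower = more effective).
#' @return A list: the [binaryScoreEval()] report plus `n_pairs`.
#' @export
externalBenchmarkEval <- function(predictions, truthTable,
                                  comparatorScore = NULL) {
  key <- function(c, p) paste(c, p, sep = "\r")
  if (is.null(comparatorScore)) {
    mins <- tapply(predictions$predicted,
                   key(predictions$cell_line_id, predictions$perturbagen_id),
                   min)
    sc <- -as.numeric(mins[key(truthTable$cell_line_id,
                               truthTable$perturbagen_id)])
  } else if (is.character(comparatorScore) && length(comparatorScore) == 1) {
    sc <- -truthTable[[comparatorScore]]
  } else {
    sc <- -as.numeric(comparatorScore)
  }
  ok <- !is.na(sc)
  ev <- binaryScoreEval(sc[ok], truthTable$effective[ok])
  ev$n_pairs <- sum(ok)
  ev
}
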