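#' Calibrate percentile thresholds on an uncertainty distribution
#'
#' Computes mean-entropy cut-offs at the requested percentiles of the
#' development cohort's score distribution. The cutoff at percentile q is the
#' inverse-ECDF empirical quantile (`type = 1`): the `ceiling(n*q/100)`-th
#' order statistic. With the tie rule of [assignGroups()] (certain iff
#' score <= cutoff) this guarantees that re-classifying the calibration scores
#' retains at least `percentile`% of them as certain, for every n — a
#' guarantee interpolating quantile definitions do not provide.
#'
#' @param x numeric vector of mean-entropy scores, or a scored
#'   [NoduleCohort-class].
#' @param percentiles percentiles in (0, 100); default `c(90, 95)`.
#' @param source_cohort provenance tag stored in the result (taken from the
#'   cohort tag when `x` is a cohort).
#' @return A [ThresholdSet-class].
#' @examples
#' ts <- calibrateThresholds(runif(100))
#' ts
#' @export
calibrateThresholds <- function(x, percentiles = c(90, 95),
                                source_cohort = "development") {
  if (is(x, "NoduleCohort")) {
    source_cohort <- cohortTag(x)[1]
    x <- uncertaintyScores(x)
  }
  if (length(x) == 0L) stop("no scores supplied for calibration")
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly inside (0, 100)")
  if (length(x) < 20L)
    warning("fewer than 20 scores: percentile cutoffs will be unstable")
  o <- order(percentiles)
  cut <- unname(stats::quantile(x, probs = percentiles[o] / 100, type = 1))
  new("ThresholdSet",
      percentiles = percentiles[o],
      cutoffs = cut,
      sourceCohort = source_cohort,
      nSource = length(x))
}

#' ThresholdSet accessors
#'
#' @param x a [ThresholdSet-class].
#' @param percentile one of the calibrated percentiles.
#' @return `thresholdPercentiles()` / `thresholdCutoffs()`: numeric vectors;
#'   `cutoffFor()`: the single cutoff calibrated at `percentile`.
#' @name ThresholdSet-accessors
NULL

#' @rdname ThresholdSet-accessors
#' @export
setMethod("thresholdPercentiles", "ThresholdSet", function(x) x@percentiles)

#' @rdname ThresholdSet-accessors
#' @export
setMethod("thresholdCutoffs", "ThresholdSet", function(x) x@cutoffs)

#' @rdname ThresholdSet-accessors
#' @export
setMethod("cutoffFor", "ThresholdSet", function(x, percentile) {
  i <- match(percentile, x@percentiles)
  if (is.na(i))
    stop("no cutoff calibrated at percentile ", percentile,
         " (available: ", paste(x@percentiles, collapse = ", "), ")")
  x@cutoffs[i]
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet calibrated on '%s' (n = %d)\n",
              object@sourceCohort, object@nSource))
  for (i in seq_along(object@percentiles))
    cat(sprintf("  p%-4g -> mean entropy <= %.4f bits is certain\n",
                object@percentiles[i], object@cutoffs[i]))
  invisible(NULL)
})

#' Assign nodules to certain / uncertain groups
#'
#' Applies a calibrated cut-off to a cohort's uncertainty scores: a nodule is
#' uncertain iff its mean entropy strictly exceeds the cutoff; scores exactly
#' at the cutoff are certain. Thresholds calibrated on a development cohort
#' may flag any fraction of a different cohort as uncertain.
#'
#' @param x numeric vector of mean-entropy scores (named by nodule id), or a
#'   scored [NoduleCohort-class].
#' @param thresholds a [ThresholdSet-class].
#' @param percentile which calibrated percentile to apply.
#' @return A data frame with columns `nodule_id`, `threshold_percentile` and
#'   `group` (factor, levels `certain`, `uncertain`).
#' @examples
#' nc <- scoreUncertainty(generateCohort(cohortPreset("screening", seed = 1)))
#' ts <- calibrateThresholds(nc)
#' table(assignGroups(nc, ts, 90)$group)
#' @export
assignGroups <- function(x, thresholds, percentile = 90) {
  stopifnot(is(thresholds, "ThresholdSet"))
  if (is(x, "NoduleCohort")) x <- uncertaintyScores(x)
  cut <- cutoffFor(thresholds, percentile)
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("nod%05d", seq_along(x))
  data.frame(
    nodule_id = ids,
    threshold_percentile = percentile,
    group = factor(ifelse(x > cut, "uncertain", "certain"),
                   levels = c("certain", "uncertain")),
    row.names = NULL)
}
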