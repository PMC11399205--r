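#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.NODULE_TYPES <- c("solid", "part-solid", "non-solid")
.COHORT_TAGS <- c("development", "external")

#' NoduleCohort: a cohort of nodules with ensemble member predictions
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one row per
#' nodule. The single assay, `"members"`, is a nodules x members matrix of
#' per-member malignancy probabilities in \[0, 1\]. Row metadata carries the
#' ground-truth label (0 = benign, 1 = malignant), the nodule diameter in mm,
#' the nodule type (solid, part-solid or non-solid) and a cohort tag
#' (development or external). After [scoreUncertainty()] the row data
#' additionally holds `mean_entropy` (bits) and `ensemble_risk`.
#'
#' @export
setClass("NoduleCohort", contains = "SummarizedExperiment")

setValidity("NoduleCohort", function(object) {
  msg <- character()
  if (!"members" %in% SummarizedExperiment::assayNames(object))
    return("assay 'members' is required")
  m <- SummarizedExperiment::assay(object, "members")
  if (ncol(m) < 1L)
    msg <- c(msg, "at least one ensemble member is required")
  if (anyNA(m) || any(m < 0) || any(m > 1))
    msg <- c(msg, "member probabilities must lie in [0, 1] with no NA")
  rd <- rowData(object)
  need <- c("cohort", "label", "diameter_mm", "nodule_type")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste0("missing rowData column(s): ", paste(miss, collapse = ", ")))
  if (!all(rd$label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0 (benign) or 1 (malignant)")
  if (anyNA(rd$diameter_mm) || any(rd$diameter_mm <= 0))
    msg <- c(msg, "diameter_mm must be positive")
  if (!all(as.character(rd$nodule_type) %in% .NODULE_TYPES))
    msg <- c(msg, paste0("nodule_type must be one of: ",
                         paste(.NODULE_TYPES, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "nodule ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Cohort simulation configuration
#'
#' Parameters of the synthetic nodule-cohort generator. See [cohortConfig()]
#' for construction with validated defaults and [cohortPreset()] for the
#' screening-like and clinical-like presets the package ships with.
#'
#' @slot nNodules number of nodules to simulate.
#' @slot malignantFraction expected fraction of malignant nodules.
#' @slot nMembers ensemble size (number of member probabilities per nodule).
#' @slot typeMix 2 x 3 matrix of type proportions; rows `benign`, `malignant`,
#'   columns `solid`, `part-solid`, `non-solid`; each row sums to 1.
#' @slot sizeDistribution list with elements `benign` and `malignant`, each a
#'   list `list(median_mm=, sdlog=)` of truncated log-normal size parameters,
#'   plus `trunc_mm`, the lower truncation bound.
#' @slot difficultyModel named list of latent-difficulty parameters; see
#'   [difficultyModel()].
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nNodules = "integer",
    malignantFraction = "numeric",
    nMembers = "integer",
    typeMix = "matrix",
    sizeDistribution = "list",
    difficultyModel = "list",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nNodules < 1L) msg <- c(msg, "nNodules must be a positive integer")
  if (is.na(object@malignantFraction) || object@malignantFraction < 0 ||
      object@malignantFraction > 1)
    msg <- c(msg, "malignantFraction must lie in [0, 1]")
  if (object@nMembers < 2L) msg <- c(msg, "nMembers must be at least 2")
  tm <- object@typeMix
  if (!identical(dim(tm), c(2L, 3L)))
    msg <- c(msg, "typeMix must be a 2 x 3 matrix (benign/malignant x type)")
  else {
    if (any(tm < 0)) msg <- c(msg, "typeMix proportions must be non-negative")
    if (any(abs(rowSums(tm) - 1) > 1e-9))
      msg <- c(msg, "typeMix rows must each sum to 1 (tolerance 1e-9)")
  }
  sd <- object@sizeDistribution
  for (lbl in c("benign", "malignant")) {
    p <- sd[[lbl]]
    if (is.null(p) || is.null(p$median_mm) || is.null(p$sdlog))
      msg <- c(msg, sprintf("sizeDistribution$%s needs median_mm and sdlog", lbl))
    else if (p$median_mm <= 0 || p$sdlog <= 0)
      msg <- c(msg, sprintf("sizeDistribution$%s scale parameters must be > 0", lbl))
  }
  if (is.null(sd$trunc_mm) || sd$trunc_mm <= 0)
    msg <- c(msg, "sizeDistribution$trunc_mm must be > 0")
  dm <- object@difficultyModel
  for (nm in c("sigma", "separation", "noise")) {
    if (!is.null(dm[[nm]]) && dm[[nm]] < 0)
      msg <- c(msg, sprintf("difficultyModel$%s must be non-negative", nm))
  }
  for (nm in c("kappa_certain", "kappa_uncertain")) {
    if (is.null(dm[[nm]]) || dm[[nm]] <= 0)
      msg <- c(msg, sprintf("difficultyModel$%s must be > 0", nm))
  }
  if (!is.null(dm$fixed) && !is.na(dm$fixed) && (dm$fixed < 0 || dm$fixed > 1))
    msg <- c(msg, "difficultyModel$fixed must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Calibrated percentile thresholds on the uncertainty distribution
#'
#' Cut-off values of the mean-entropy score at given percentiles of a
#' development cohort's score distribution, with provenance. Nodules whose
#' score is at or below a cut-off are triaged as certain; strictly above as
#' uncertain.
#'
#' @slot percentiles percentiles in (0, 100), non-decreasing.
#' @slot cutoffs matching mean-entropy cut-off values (bits).
#' @slot sourceCohort tag of the cohort the thresholds were calibrated on.
#' @slot nSource number of scores used in calibration.
#' @export
setClass("ThresholdSet",
  representation(
    percentiles = "numeric",
    cutoffs = "numeric",
    sourceCohort = "character",
    nSource = "integer"
  )
)

setValidity("ThresholdSet", function(object) {
  msg <- character()
  if (length(object@percentiles) != length(object@cutoffs))
    msg <- c(msg, "percentiles and cutoffs must have equal length")
  if (any(object@percentiles <= 0) || any(object@percentiles >= 100))
    msg <- c(msg, "percentiles must lie strictly inside (0, 100)")
  if (is.unsorted(object@percentiles))
    msg <- c(msg, "percentiles must be non-decreasing")
  if (length(object@cutoffs) > 1 && is.unsorted(object@cutoffs))
    msg <- c(msg, "cutoffs must be non-decreasing in percentile")
  if (any(object@cutoffs < 0 | object@cutoffs > 1))
    msg <- c(msg, "mean-entropy cutoffs must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of a DeLong comparison of two AUCs
#'
#' @slot groupA,groupB group tags.
#' @slot aucA,aucB the two AUC estimates.
#' @slot varA,varB their DeLong variances.
#' @slot zStatistic normal test statistic (aucA - aucB) / sqrt(varA + varB).
#' @slot pValue two-sided normal p-value.
#' @slot paired always `FALSE`: the covariance between groups is not estimated.
#' @slot overlapping `TRUE` when the groups share nodules (e.g. full vs
#'   certain), in which case the unpaired z is a documented approximation that
#'   ignores the (positive) covariance term.
#' @export
setClass("AucComparison",
  representation(
    groupA = "character", groupB = "character",
    aucA = "numeric", aucB = "numeric",
    varA = "numeric", varB = "numeric",
    zStatistic = "numeric", pValue = "numeric",
    paired = "logical", overlapping = "logical"
  )
)

setValidity("AucComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]" else TRUE
})
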