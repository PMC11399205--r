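#' @rdname NoduleCohort-accessors
#' @export
setGeneric("memberProbs", function(x) standardGeneric("memberProbs"))

#' @rdname NoduleCohort-accessors
#' @export
setGeneric("noduleLabels", function(x) standardGeneric("noduleLabels"))

#' @rdname NoduleCohort-accessors
#' @export
setGeneric("noduleDiameters", function(x) standardGeneric("noduleDiameters"))

#' @rdname NoduleCohort-accessors
#' @export
setGeneric("noduleTypes", function(x) standardGeneric("noduleTypes"))

#' @rdname NoduleCohort-accessors
#' @export
setGeneric("cohortTag", function(x) standardGeneric("cohortTag"))

#' @rdname NoduleCohort-accessors
#' @export
setGeneric("noduleIds", function(x) standardGeneric("noduleIds"))

#' @rdname scoreUncertainty
#' @export
setGeneric("scoreUncertainty", function(x, ...) standardGeneric("scoreUncertainty"))

#' @rdname ThresholdSet-accessors
#' @export
setGeneric("thresholdPercentiles", function(x) standardGeneric("thresholdPercentiles"))

#' @rdname ThresholdSet-accessors
#' @export
setGeneric("thresholdCutoffs", function(x) standardGeneric("thresholdCutoffs"))

#' @rdname ThresholdSet-accessors
#' @export
setGeneric("cutoffFor", function(x, percentile) standardGeneric("cutoffFor"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort", function(config, ...) standardGeneric("generateCohort"))
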