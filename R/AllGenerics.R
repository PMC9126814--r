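#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("csType", function(x) standardGeneric("csType"))
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("fcTensor", function(x) standardGeneric("fcTensor"))
#' @rdname accessors
#' @export
setGeneric("fcMethod", function(x) standardGeneric("fcMethod"))
#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("edgeVector", function(x) standardGeneric("edgeVector"))
#' @rdname accessors
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("componentStats", function(x) standardGeneric("componentStats"))
#' @rdname accessors
#' @export
setGeneric("pFwe", function(x) standardGeneric("pFwe"))
#' @rdname accessors
#' @export
setGeneric("edgeStats", function(x) standardGeneric("edgeStats"))
#' @rdname accessors
#' @export
setGeneric("canonicalR", function(x) standardGeneric("canonicalR"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname jackknifeTrialFC
#' @export
setGeneric("jackknifeTrialFC", function(beta, method = c("jackknife_zflip", "jackknife_pseudovalue"),
                                        fisherTransform = TRUE, zCap = 6,
                                        pool = c("all", "per_cs")) standardGeneric("jackknifeTrialFC"))

#' @rdname blockAverage
#' @export
setGeneric("blockAverage", function(tfc, nBlocks = 4L,
                                    remainder = c("error", "truncate_late")) standardGeneric("blockAverage"))

#' @rdname deltaFC
#' @export
setGeneric("deltaFC", function(bfc) standardGeneric("deltaFC"))

#' @rdname componentMeanSeries
#' @export
setGeneric("componentMeanSeries", function(bfc, edges) standardGeneric("componentMeanSeries"))

#' @rdname staticFC
#' @export
setGeneric("staticFC", function(beta, csType = "CSplus", zCap = 6) standardGeneric("staticFC"))
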