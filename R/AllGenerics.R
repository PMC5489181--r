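#' @rdname SurveyDesign-accessors
#' @export
setGeneric("designYears", function(x) standardGeneric("designYears"))

#' @rdname SurveyDesign-accessors
#' @export
setGeneric("secondaryCounts", function(x) standardGeneric("secondaryCounts"))

#' @rdname SurveyDesign-accessors
#' @export
setGeneric("cameraEra", function(x) standardGeneric("cameraEra"))

#' @rdname SurveyDesign-accessors
#' @export
setGeneric("primaryStarts", function(x) standardGeneric("primaryStarts"))

#' @rdname SurveyDesign-accessors
#' @export
setGeneric("intervalYears", function(x) standardGeneric("intervalYears"))

#' @rdname CaptureHistory-accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname CaptureHistory-accessors
#' @export
setGeneric("secondaryMatrix", function(x) standardGeneric("secondaryMatrix"))

#' @rdname CaptureHistory-accessors
#' @export
setGeneric("detectionCounts", function(x) standardGeneric("detectionCounts"))

#' @rdname CaptureHistory-accessors
#' @export
setGeneric("firstPrimary", function(x) standardGeneric("firstPrimary"))

#' @rdname CaptureHistory-accessors
#' @export
setGeneric("buildReport", function(x) standardGeneric("buildReport"))

#' @rdname RobustFit-accessors
#' @export
setGeneric("aicc", function(x) standardGeneric("aicc"))

#' @rdname RobustFit-accessors
#' @export
setGeneric("realEstimates", function(x) standardGeneric("realEstimates"))

#' @rdname RobustFit-accessors
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname ModelAverage-class
#' @export
setGeneric("akaikeWeights", function(x) standardGeneric("akaikeWeights"))

#' @rdname ModelAverage-class
#' @export
setGeneric("averagedEstimates", function(x) standardGeneric("averagedEstimates"))

#' @rdname ModelAverage-class
#' @export
setGeneric("abundanceTable", function(x) standardGeneric("abundanceTable"))
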