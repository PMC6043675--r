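#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `seriesTimes()`/`seriesValues()` for [HalfHourlySeries-class],
#' `profileParams()` for [GaussianProfileFit-class] (named vector `A`, `mu`,
#' `sigma`), `loopMetrics()` for [HysteresisLoop-class], `anovaTable()`,
#' `varianceComponents()` and `r2Nakagawa()` for [MixedModelResult-class],
#' and `studyTrees()`/`studyClimate()`/`studySensors()`/`studyTruth()` for
#' [SyntheticStudy-class].
#'
#' @param x an object of the documented class.
#' @return the extracted component (see details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("profileParams", function(x) standardGeneric("profileParams"))
#' @rdname accessors
#' @export
setGeneric("loopMetrics", function(x) standardGeneric("loopMetrics"))
#' @rdname accessors
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))
#' @rdname accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setGeneric("r2Nakagawa", function(x) standardGeneric("r2Nakagawa"))
#' @rdname accessors
#' @export
setGeneric("studyTrees", function(x) standardGeneric("studyTrees"))
#' @rdname accessors
#' @export
setGeneric("studyClimate", function(x) standardGeneric("studyClimate"))
#' @rdname accessors
#' @export
setGeneric("studySensors", function(x) standardGeneric("studySensors"))
#' @rdname accessors
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))

#' @rdname accessors
setMethod("seriesTimes", "HalfHourlySeries", function(x) x@time)
#' @rdname accessors
setMethod("seriesValues", "HalfHourlySeries", function(x) x@values)
#' @rdname accessors
setMethod("profileParams", "GaussianProfileFit", function(x)
  c(A = x@A, mu = x@mu, sigma = x@sigma))
#' @rdname accessors
setMethod("loopMetrics", "HysteresisLoop", function(x)
  data.frame(
    date = x@date, group = x@group, signedArea = x@signedArea,
    absArea = abs(x@signedArea), rotation = x@rotation,
    jsPeak = x@jsPeak, vpdPeak = x@vpdPeak,
    selfIntersecting = x@selfIntersecting
  ))
#' @rdname accessors
setMethod("anovaTable", "MixedModelResult", function(x) x@anova)
#' @rdname accessors
setMethod("varianceComponents", "MixedModelResult", function(x) x@varcomp)
#' @rdname accessors
setMethod("r2Nakagawa", "MixedModelResult", function(x)
  c(marginal = x@r2m, conditional = x@r2c))
#' @rdname accessors
setMethod("studyTrees", "SyntheticStudy", function(x) x@trees)
#' @rdname accessors
setMethod("studyClimate", "SyntheticStudy", function(x) x@climate)
#' @rdname accessors
setMethod("studySensors", "SyntheticStudy", function(x) x@sensors)
#' @rdname accessors
setMethod("studyTruth", "SyntheticStudy", function(x) x@truth)
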