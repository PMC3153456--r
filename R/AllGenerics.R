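#' @rdname DoseProfile-class
#' @param object,x a model object.
#' @export
setGeneric("totalSteps", function(x) standardGeneric("totalSteps"))

#' @rdname DoseProfile-class
#' @export
setGeneric("doseVector", function(x) standardGeneric("doseVector"))

#' @rdname DoseProfile-class
#' @param t time-scale index (1-based step number).
#' @export
setGeneric("doseAt", function(x, t) standardGeneric("doseAt"))

#' @rdname SimulationResult-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname SimulationResult-class
#' @export
setGeneric("dsbDraws", function(x) standardGeneric("dsbDraws"))

#' @rdname CellState-class
#' @export
setGeneric("dsbTotal", function(x) standardGeneric("dsbTotal"))

#' @rdname IndicatorReport-class
#' @export
setGeneric("detectedTimes", function(x) standardGeneric("detectedTimes"))

#' @rdname IndicatorReport-class
#' @export
setGeneric("indicatorTracks", function(x) standardGeneric("indicatorTracks"))
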