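#' Accessors for sweep and spectrum objects
#'
#' `frequencies()` returns the frequency grid (Hz); `magnitude()`, `phase()`,
#' `realPart()` and `imaginaryPart()` return the per-frequency components of
#' a calibrated spectrum; `gainFactor()` and `systemPhase()` the calibration
#' constants; `decision()` and `agreement()` the outcome of a voting
#' prediction; `atssHistory()` the per-candidate decision log of an ATSS run;
#' `atssPopulation()` the current training population.
#'
#' @param object an object of the documented classes.
#' @return the slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("magnitude", function(object) standardGeneric("magnitude"))
#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("realPart", function(object) standardGeneric("realPart"))
#' @rdname accessors
#' @export
setGeneric("imaginaryPart", function(object) standardGeneric("imaginaryPart"))
#' @rdname accessors
#' @export
setGeneric("gainFactor", function(object) standardGeneric("gainFactor"))
#' @rdname accessors
#' @export
setGeneric("systemPhase", function(object) standardGeneric("systemPhase"))
#' @rdname accessors
#' @export
setGeneric("decision", function(object) standardGeneric("decision"))
#' @rdname accessors
#' @export
setGeneric("agreement", function(object) standardGeneric("agreement"))
#' @rdname accessors
#' @export
setGeneric("atssHistory", function(object) standardGeneric("atssHistory"))
#' @rdname accessors
#' @export
setGeneric("atssPopulation", function(object) standardGeneric("atssPopulation"))

#' @rdname accessors
#' @export
setMethod("frequencies", "RawSweep", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "CalibrationModel", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "ImpedanceSpectrum", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("magnitude", "ImpedanceSpectrum", function(object) object@magnitude)
#' @rdname accessors
#' @export
setMethod("phase", "ImpedanceSpectrum", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("realPart", "ImpedanceSpectrum", function(object) object@realPart)
#' @rdname accessors
#' @export
setMethod("imaginaryPart", "ImpedanceSpectrum",
    function(object) object@imaginaryPart)
#' @rdname accessors
#' @export
setMethod("gainFactor", "CalibrationModel", function(object) object@gainFactor)
#' @rdname accessors
#' @export
setMethod("systemPhase", "CalibrationModel", function(object) object@systemPhase)
#' @rdname accessors
#' @export
setMethod("decision", "VoteResult", function(object) object@decision)
#' @rdname accessors
#' @export
setMethod("agreement", "VoteResult", function(object) object@agreement)
#' @rdname accessors
#' @export
setMethod("atssHistory", "AtssState", function(object) object@history)
#' @rdname accessors
#' @export
setMethod("atssPopulation", "AtssState", function(object) object@population)

setMethod("show", "SweepConfig", function(object) {
    cat("SweepConfig:", object@nSteps + 1L, "frequencies from",
        object@startFrequency, "Hz in", object@frequencyIncrement,
        "Hz steps\n  calibration resistance:",
        object@calibrationResistance, "ohm; output",
        object@outputVoltage, "Vpp;", object@nCycles, "cycles\n")
})

setMethod("show", "RawSweep", function(object) {
    cat("RawSweep with", length(object@frequencies), "frequencies (",
        min(object@frequencies), "-", max(object@frequencies), "Hz )\n")
})

setMethod("show", "CalibrationModel", function(object) {
    cat("CalibrationModel over", length(object@frequencies),
        "frequencies; reference resistor",
        object@calibrationResistance, "ohm\n  gain factor range: [",
        format(min(object@gainFactor), digits = 4), ",",
        format(max(object@gainFactor), digits = 4), "]\n")
})

setMethod("show", "ImpedanceSpectrum", function(object) {
    cat("ImpedanceSpectrum with", length(object@frequencies),
        "frequencies\n  |Z| range: [",
        format(min(object@magnitude), digits = 6), ",",
        format(max(object@magnitude), digits = 6), "] ohm\n")
})

setMethod("show", "ClassifierModel", function(object) {
    cat("ClassifierModel (", object@solverTag, ") with",
        length(object@attributeNames), "attributes; threshold",
        object@threshold, "\n")
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf("PowerLawFit: y = %.6g * x^%.6g  (R^2 = %.4f)\n",
        object@a, object@b, object@rSquared))
})

setMethod("show", "VoteResult", function(object) {
    cat("VoteResult:", object@decision,
        sprintf("(agreement %.2f over %d valid measurements)\n",
            object@agreement, object@nValid))
    if (nzchar(object@reason)) cat("  note:", object@reason, "\n")
})

setMethod("show", "AtssState", function(object) {
    acc <- object@history$decision
    cat("AtssState: population", nrow(object@population), "/",
        object@capacity, "samples;",
        sum(acc != "rejected"), "commits over", length(acc),
        "candidates\n  mean silhouette width:",
        format(mean(object@sw), digits = 4), "\n")
})
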