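#' @import methods
NULL

.TWO_PI <- 2 * pi

## wrap an angle (radians) into (-pi, pi]
wrapPhase <- function(theta) {
    w <- (theta + pi) %% .TWO_PI
    w[w == 0] <- .TWO_PI
    w - pi
}

#' Frequency-sweep configuration
#'
#' Settings of the impedance-analyzer frequency sweep and its single-resistor
#' calibration, mirroring the configuration registers of an AD5933-class
#' device. The defaults reproduce the device configuration used for the
#' clinical measurement campaign: a sweep from 10000 Hz in 280 Hz steps with
#' 255 increments (256 frequencies total), calibrated against a 470 ohm
#' reference resistor.
#'
#' @slot startFrequency numeric(1), first sweep frequency in Hz (> 0).
#' @slot frequencyIncrement numeric(1), step between frequencies in Hz (> 0).
#' @slot nSteps integer(1), number of increments beyond the start point;
#'   the sweep contains `nSteps + 1` frequencies.
#' @slot calibrationResistance numeric(1), reference resistor in ohm.
#' @slot outputVoltage numeric(1), excitation amplitude in volt peak-to-peak.
#' @slot nCycles integer(1), settling cycles per frequency point.
#'
#' @examples
#' cfg <- SweepConfig()
#' head(sweepFrequencies(cfg))
#' @export
setClass("SweepConfig",
    representation(
        startFrequency = "numeric",
        frequencyIncrement = "numeric",
        nSteps = "integer",
        calibrationResistance = "numeric",
        outputVoltage = "numeric",
        nCycles = "integer"
    )
)

setValidity("SweepConfig", function(object) {
    msg <- character()
    if (length(object@startFrequency) != 1L || object@startFrequency <= 0)
        msg <- c(msg, "startFrequency must be a single positive number")
    if (length(object@frequencyIncrement) != 1L || object@frequencyIncrement <= 0)
        msg <- c(msg, "frequencyIncrement must be a single positive number")
    if (length(object@nSteps) != 1L || object@nSteps < 1L)
        msg <- c(msg, "nSteps must be a single integer >= 1")
    if (length(object@calibrationResistance) != 1L ||
        object@calibrationResistance <= 0)
        msg <- c(msg, "calibrationResistance must be positive")
    if (length(msg)) msg else TRUE
})

#' @param startFrequency,frequencyIncrement,nSteps,calibrationResistance,outputVoltage,nCycles
#'   see the corresponding slots.
#' @rdname SweepConfig-class
#' @export
SweepConfig <- function(startFrequency = 10000, frequencyIncrement = 280,
                        nSteps = 255L, calibrationResistance = 470,
                        outputVoltage = 2, nCycles = 511L) {
    new("SweepConfig",
        startFrequency = as.numeric(startFrequency),
        frequencyIncrement = as.numeric(frequencyIncrement),
        nSteps = as.integer(nSteps),
        calibrationResistance = as.numeric(calibrationResistance),
        outputVoltage = as.numeric(outputVoltage),
        nCycles = as.integer(nCycles))
}

#' Raw (uncalibrated) frequency sweep
#'
#' Per-frequency raw device readouts: the dimensionless real (`rr`) and
#' imaginary (`ir`) register values returned by the analyzer, which become
#' physical impedances only after calibration (see [applyCalibration()]).
#'
#' @slot frequencies numeric, sweep frequencies in Hz.
#' @slot rr numeric, raw real-part readouts, one per frequency.
#' @slot ir numeric, raw imaginary-part readouts, one per frequency.
#' @export
setClass("RawSweep",
    representation(frequencies = "numeric", rr = "numeric", ir = "numeric")
)

setValidity("RawSweep", function(object) {
    n <- length(object@frequencies)
    if (length(object@rr) != n || length(object@ir) != n)
        return("frequencies, rr and ir must have equal length")
    TRUE
})

#' @param frequencies,rr,ir see the corresponding slots.
#' @rdname RawSweep-class
#' @export
RawSweep <- function(frequencies, rr, ir) {
    new("RawSweep", frequencies = as.numeric(frequencies),
        rr = as.numeric(rr), ir = as.numeric(ir))
}

#' Single-resistor calibration model
#'
#' Per-frequency gain factor and system phase measured on a known reference
#' resistor. The gain factor converts a raw readout magnitude into an
#' impedance magnitude in ohm; the system phase is the instrument's intrinsic
#' phase, subtracted from every subsequent measurement.
#'
#' @slot frequencies numeric, sweep frequencies in Hz.
#' @slot gainFactor numeric, per-frequency gain factor (1/(ohm * raw unit)).
#' @slot systemPhase numeric, per-frequency instrument phase in radians,
#'   wrapped to (-pi, pi].
#' @slot calibrationResistance numeric(1), the reference resistor in ohm.
#' @export
setClass("CalibrationModel",
    representation(
        frequencies = "numeric",
        gainFactor = "numeric",
        systemPhase = "numeric",
        calibrationResistance = "numeric"
    )
)

setValidity("CalibrationModel", function(object) {
    n <- length(object@frequencies)
    msg <- character()
    if (length(object@gainFactor) != n || length(object@systemPhase) != n)
        msg <- c(msg, "gainFactor and systemPhase must match frequencies")
    if (any(!is.finite(object@gainFactor)) || any(object@gainFactor <= 0))
        msg <- c(msg, "gainFactor must be finite and positive everywhere")
    if (any(object@systemPhase <= -pi | object@systemPhase > pi))
        msg <- c(msg, "systemPhase must lie in (-pi, pi]")
    if (length(msg)) msg else TRUE
})

#' Calibrated impedance spectrum
#'
#' Physical impedance per frequency after calibration: magnitude (ohm),
#' calibrated phase (radians), and the derived real/imaginary parts.
#'
#' @slot frequencies numeric, Hz.
#' @slot magnitude numeric, impedance magnitude in ohm (>= 0).
#' @slot phase numeric, calibrated phase in radians, in (-pi, pi].
#' @slot realPart,imaginaryPart numeric, resistance and reactance in ohm;
#'   consistent with magnitude and phase by construction.
#' @export
setClass("ImpedanceSpectrum",
    representation(
        frequencies = "numeric",
        magnitude = "numeric",
        phase = "numeric",
        realPart = "numeric",
        imaginaryPart = "numeric"
    )
)

setValidity("ImpedanceSpectrum", function(object) {
    n <- length(object@frequencies)
    msg <- character()
    if (length(object@magnitude) != n || length(object@phase) != n ||
        length(object@realPart) != n || length(object@imaginaryPart) != n)
        msg <- c(msg, "all per-frequency slots must match frequencies")
    else {
        if (any(object@magnitude < 0))
            msg <- c(msg, "magnitude must be non-negative")
        if (any(object@phase <= -pi | object@phase > pi))
            msg <- c(msg, "phase must lie in (-pi, pi]")
        m2 <- object@realPart^2 + object@imaginaryPart^2
        tol <- 1e-9 * pmax(object@magnitude^2, 1e-300)
        if (any(abs(m2 - object@magnitude^2) > pmax(tol, 1e-12)))
            msg <- c(msg, "real^2 + imaginary^2 must equal magnitude^2")
    }
    if (length(msg)) msg else TRUE
})

#' @param frequencies,magnitude,phase see the corresponding slots; real and
#'   imaginary parts are derived as `magnitude * cos(phase)` and
#'   `magnitude * sin(phase)`.
#' @rdname ImpedanceSpectrum-class
#' @export
ImpedanceSpectrum <- function(frequencies, magnitude, phase) {
    frequencies <- as.numeric(frequencies)
    magnitude <- as.numeric(magnitude)
    phase <- wrapPhase(as.numeric(phase))
    new("ImpedanceSpectrum", frequencies = frequencies,
        magnitude = magnitude, phase = phase,
        realPart = magnitude * cos(phase),
        imaginaryPart = magnitude * sin(phase))
}

#' Logistic-regression screening model
#'
#' A fitted binary logistic-regression classifier P = 1 / (1 + exp(-h)),
#' h = w . z + b, where z is the feature vector standardized with the
#' training-set scaler stored alongside the coefficients. The positive class
#' (label 1) is "diabetic".
#'
#' @slot attributeNames character, feature names in model order.
#' @slot weights numeric, one coefficient per attribute (standardized scale).
#' @slot bias numeric(1), intercept on the standardized scale.
#' @slot scalerMean,scalerSd numeric, per-attribute standardization
#'   parameters learned on the training data.
#' @slot solverTag character(1), provenance tag of the fitting routine.
#' @slot threshold numeric(1), probability cut for the class decision
#'   (default 0.5).
#' @export
setClass("ClassifierModel",
    representation(
        attributeNames = "character",
        weights = "numeric",
        bias = "numeric",
        scalerMean = "numeric",
        scalerSd = "numeric",
        solverTag = "character",
        threshold = "numeric"
    )
)

setValidity("ClassifierModel", function(object) {
    p <- length(object@attributeNames)
    msg <- character()
    if (length(object@weights) != p || length(object@scalerMean) != p ||
        length(object@scalerSd) != p)
        msg <- c(msg, "weights and scaler must match attributeNames length")
    if (length(object@bias) != 1L || !is.finite(object@bias))
        msg <- c(msg, "bias must be a single finite number")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold >= 1)
        msg <- c(msg, "threshold must lie in (0, 1)")
    if (any(object@scalerSd <= 0))
        msg <- c(msg, "scaler standard deviations must be positive")
    if (length(msg)) msg else TRUE
})

#' Power-law fit of a magnitude spectrum
#'
#' Least-squares fit of y = a * x^b to an impedance magnitude spectrum in
#' log-log space, used as the physical-plausibility check on each repeated
#' measurement before it may enter the voting prediction.
#'
#' @slot a numeric(1), coefficient (ohm * Hz^-b); positive for physical
#'   spectra.
#' @slot b numeric(1), exponent (dimensionless, typically negative).
#' @slot rSquared numeric(1), coefficient of determination of the log-log
#'   regression, in [0, 1].
#' @export
setClass("PowerLawFit",
    representation(a = "numeric", b = "numeric", rSquared = "numeric"))

setValidity("PowerLawFit", function(object) {
    if (length(object@rSquared) != 1L ||
        object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
        return("rSquared must lie in [0, 1]")
    TRUE
})

#' Voting prediction result
#'
#' Outcome of the repeated-measurement voting procedure: each measurement is
#' screened with the power-law validity check, valid measurements are
#' classified, and a class is returned only when the modal class reaches the
#' vote threshold among valid measurements; otherwise the decision is
#' "undefined".
#'
#' @slot decision character(1), one of "diabetic", "nondiabetic", "undefined".
#' @slot agreement numeric(1), modal-class share among valid measurements.
#' @slot nValid integer(1), number of measurements passing the validity check.
#' @slot perMeasurement data.frame with one row per input measurement:
#'   `measurement_id`, `r2`, `valid`, `class`, `probability`.
#' @slot reason character(1), "" or a quality flag such as
#'   "insufficient valid measurements".
#' @export
setClass("VoteResult",
    representation(
        decision = "character",
        agreement = "numeric",
        nValid = "integer",
        perMeasurement = "data.frame",
        reason = "character"
    )
)

setValidity("VoteResult", function(object) {
    if (!object@decision %in% c("diabetic", "nondiabetic", "undefined"))
        return("decision must be diabetic, nondiabetic or undefined")
    TRUE
})

#' State of an active-training-by-seed-selection run
#'
#' The capacity-bounded training population with its per-sample silhouette
#' widths, the classifier fitted on the current population, the held-out
#' monitor set on which the indicator gates are evaluated, and the per-step
#' decision history.
#'
#' @slot population data.frame of the current training population, in the
#'   feature-table schema (see [buildFeatures()]).
#' @slot sw numeric, silhouette width of each population sample (standardized
#'   feature space).
#' @slot addedStep integer, step at which each population sample entered
#'   (0 for seed samples); used to break ties when replacing.
#' @slot capacity integer(1), maximum population size.
#' @slot model the [ClassifierModel-class] trained on the current population.
#' @slot monitor data.frame, held-out labeled samples for indicator gating.
#' @slot scaler list with `mean` and `sd`, the standardization fixed at
#'   seeding time.
#' @slot history data.frame, one row per candidate considered: `step`,
#'   `decision`, `s_candidate`, `s_min`, `acc_before`, `acc_after`,
#'   `prec_delta`, `rec_delta`.
#' @slot stepCounter integer(1), number of candidates considered so far.
#' @export
setClass("AtssState",
    representation(
        population = "data.frame",
        sw = "numeric",
        addedStep = "integer",
        capacity = "integer",
        model = "ClassifierModel",
        monitor = "data.frame",
        scaler = "list",
        history = "data.frame",
        stepCounter = "integer"
    )
)

setValidity("AtssState", function(object) {
    msg <- character()
    if (nrow(object@population) > object@capacity)
        msg <- c(msg, "population exceeds capacity")
    if (length(object@sw) != nrow(object@population))
        msg <- c(msg, "sw must have one entry per population sample")
    if (length(object@addedStep) != nrow(object@population))
        msg <- c(msg, "addedStep must have one entry per population sample")
    if (nrow(object@population) &&
        length(unique(object@population$label)) < 2L)
        msg <- c(msg, "population must contain both classes")
    if (length(msg)) msg else TRUE
})
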