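#' Frequencies of a configured sweep
#'
#' Expands a [SweepConfig-class] into its frequency grid
#' `start + i * increment`, `i = 0 ... nSteps`. With the default
#' configuration this is the 256-frequency grid 10000, 10280, ..., 81400 Hz.
#'
#' @param config a [SweepConfig-class].
#' @return numeric vector of `nSteps + 1` strictly increasing frequencies, Hz.
#' @examples
#' f <- sweepFrequencies(SweepConfig())
#' f[c(1, 241, 256)]   # 10000, 77200, 81400
#' @export
sweepFrequencies <- function(config) {
    stopifnot(is(config, "SweepConfig"))
    validObject(config)
    config@startFrequency +
        (0:config@nSteps) * config@frequencyIncrement
}

#' Raw readout magnitude
#'
#' Magnitude of a raw device readout, `sqrt(rr^2 + ir^2)` (dimensionless).
#'
#' @param rr,ir raw real/imaginary readouts (vectorized).
#' @return non-negative magnitude, same length as the inputs.
#' @export
rawMagnitude <- function(rr, ir) {
    stopifnot(is.finite(rr), is.finite(ir))
    sqrt(rr^2 + ir^2)
}

#' Gain factor from a calibration readout
#'
#' The per-frequency gain factor `(1 / R_cal) / raw_magnitude`: the constant
#' that makes the calibrated impedance `1 / (FG * raw_magnitude)` return the
#' reference resistance on the calibration readings themselves.
#'
#' @param calibrationResistance reference resistor, ohm (> 0).
#' @param rawMag raw readout magnitude on that resistor (> 0; vectorized).
#' @return gain factor, 1/(ohm * raw unit).
#' @export
gainFactorFrom <- function(calibrationResistance, rawMag) {
    stopifnot(calibrationResistance > 0)
    if (any(rawMag <= 0))
        stop("degenerate calibration: raw magnitude must be positive")
    (1 / calibrationResistance) / rawMag
}

#' Raw readout phase
#'
#' Four-quadrant angle of the raw readout `(rr, ir)`, in (-pi, pi]. The
#' single-argument arctangent loses quadrant information, so `atan2` is used.
#'
#' @param rr,ir raw readouts (vectorized); `(0, 0)` is an error.
#' @return phase in radians.
#' @export
rawPhase <- function(rr, ir) {
    if (any(rr == 0 & ir == 0))
        stop("undefined phase: (rr, ir) = (0, 0)")
    wrapPhase(atan2(ir, rr))
}

#' Calibrate the system from a reference-resistor sweep
#'
#' Computes the per-frequency gain factor and system phase from a raw sweep
#' taken on the known calibration resistor. These constants are then applied
#' to every subsequent measurement with [applyCalibration()].
#'
#' @param calSweep a [RawSweep-class] measured on the reference resistor.
#' @param calibrationResistance the reference resistor, ohm.
#' @return a [CalibrationModel-class].
#' @examples
#' cfg <- SweepConfig(nSteps = 3L)
#' f <- sweepFrequencies(cfg)
#' cal <- RawSweep(f, rr = rep(2e-3, 4), ir = rep(0, 4))
#' m <- calibrateSystem(cal, 470)
#' systemPhase(m)   # all zero: a resistor has no phase
#' @export
calibrateSystem <- function(calSweep, calibrationResistance) {
    stopifnot(is(calSweep, "RawSweep"))
    validObject(calSweep)
    m <- rawMagnitude(calSweep@rr, calSweep@ir)
    bad <- which(m == 0)
    if (length(bad))
        stop("degenerate calibration: zero raw magnitude at ",
             calSweep@frequencies[bad[1L]], " Hz")
    new("CalibrationModel",
        frequencies = calSweep@frequencies,
        gainFactor = gainFactorFrom(calibrationResistance, m),
        systemPhase = rawPhase(calSweep@rr, calSweep@ir),
        calibrationResistance = as.numeric(calibrationResistance))
}

#' Apply a calibration model to a raw sweep
#'
#' Converts raw readouts into a physical impedance spectrum:
#' magnitude `|Z| = 1 / (FG * raw_magnitude)`, calibrated phase
#' `phaseC = raw phase - system phase` (wrapped to (-pi, pi]), and
#' `real = |Z| cos(phaseC)`, `imaginary = |Z| sin(phaseC)`.
#'
#' @param sweep a [RawSweep-class]; its frequencies must match the model's.
#' @param model a [CalibrationModel-class].
#' @return an [ImpedanceSpectrum-class].
#' @export
applyCalibration <- function(sweep, model) {
    stopifnot(is(sweep, "RawSweep"), is(model, "CalibrationModel"))
    validObject(sweep)
    if (length(sweep@frequencies) != length(model@frequencies) ||
        any(sweep@frequencies != model@frequencies))
        stop("alignment error: sweep frequencies do not match the ",
             "calibration model")
    m <- rawMagnitude(sweep@rr, sweep@ir)
    if (any(m == 0))
        stop("infinite impedance: zero raw magnitude in the sweep")
    ImpedanceSpectrum(
        frequencies = sweep@frequencies,
        magnitude = 1 / (model@gainFactor * m),
        phase = wrapPhase(rawPhase(sweep@rr, sweep@ir) - model@systemPhase))
}

#' Relative error percentage
#'
#' Absolute relative deviation of a measured value from a theoretical one,
#' `|(vt - vm) / vt| * 100`, used to verify the calibration against a known
#' RC phantom.
#'
#' @param vt theoretical value (nonzero).
#' @param vm measured value.
#' @return error in percent (vectorized).
#' @export
errorPercentage <- function(vt, vm) {
    if (any(vt == 0)) stop("theoretical value must be nonzero")
    abs((vt - vm) / vt) * 100
}

#' Impedance of a series RC phantom
#'
#' Magnitude and phase of a resistor and capacitor in series, the reference
#' phantom used to verify the calibration: `|Z| = sqrt(R^2 + Xc^2)` with
#' `Xc = 1 / (2 pi f C)`, and phase `atan2(-Xc, R)`.
#'
#' @param resistance ohm (> 0).
#' @param capacitance farad (> 0).
#' @param frequency Hz (> 0; vectorized).
#' @return list with `magnitude` (ohm) and `phase` (radians) vectors.
#' @examples
#' rcSeriesImpedance(100, 100e-9, 10000)$magnitude   # ~187.97 ohm
#' @export
rcSeriesImpedance <- function(resistance, capacitance, frequency) {
    stopifnot(resistance > 0, capacitance > 0)
    if (any(frequency <= 0)) stop("frequency must be positive")
    xc <- 1 / (2 * pi * frequency * capacitance)
    list(magnitude = sqrt(resistance^2 + xc^2),
         phase = atan2(-xc, resistance))
}
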