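test_that("sweep frequency grid matches the device configuration", {
    cfg <- SweepConfig()
    f <- sweepFrequencies(cfg)
    expect_length(f, 256L)
    expect_equal(f[1], 10000)
    expect_equal(f[241], 77200)   # index 240 from the start point
    expect_equal(f[256], 10000 + 255 * 280)
    expect_true(all(diff(f) > 0))
    expect_true(all(DEFAULT_FREQUENCIES %in% f))
    expect_error(SweepConfig(startFrequency = -1), "positive")
})

test_that("raw magnitude, gain factor and phase follow their closed forms", {
    expect_equal(rawMagnitude(3, 4), 5)
    expect_equal(rawMagnitude(0, 0), 0)
    expect_equal(rawMagnitude(-3, 4), 5)
    expect_equal(gainFactorFrom(100, 2), 0.005)
    expect_equal(gainFactorFrom(470, 1), 1 / 470)
    expect_error(gainFactorFrom(470, 0), "degenerate")
    expect_equal(rawPhase(1, 1), pi / 4)
    expect_equal(rawPhase(1, 0), 0)
    expect_equal(rawPhase(0, 1), pi / 2)
    expect_equal(rawPhase(-1, 0), pi)  # wrapped into (-pi, pi]
    expect_error(rawPhase(0, 0), "undefined")
})

test_that("system calibration on a pure resistor has zero phase and self-calibrates", {
    cfg <- SweepConfig(nSteps = 7L)
    f <- sweepFrequencies(cfg)
    cal <- RawSweep(f, rr = rep(2e-3, 8), ir = rep(0, 8))
    m <- calibrateSystem(cal, 470)
    expect_equal(systemPhase(m), rep(0, 8))
    sp <- applyCalibration(cal, m)
    expect_equal(magnitude(sp), rep(470, 8), tolerance = 1e-12)
    expect_equal(phase(sp), rep(0, 8))

    cal45 <- RawSweep(f, rr = rep(1e-3, 8), ir = rep(1e-3, 8))
    expect_equal(systemPhase(calibrateSystem(cal45, 470)),
                 rep(pi / 4, 8))
    expect_error(calibrateSystem(RawSweep(f[1], 0, 0), 470),
                 "degenerate")
})

test_that("calibration inverts raw encoding to 1e-9 relative on random spectra", {
    model <- syntheticCalibration(SweepConfig())
    f <- frequencies(model)
    set.seed(42)
    for (rep in 1:5) {
        sp <- ImpedanceSpectrum(f,
                                magnitude = exp(runif(length(f), 3, 8)),
                                phase = runif(length(f), -1.2, 1.2))
        back <- applyCalibration(encodeRaw(sp, model), model)
        expect_equal(magnitude(back), magnitude(sp), tolerance = 1e-9)
        expect_equal(phase(back), phase(sp), tolerance = 1e-9)
        expect_equal(realPart(back), realPart(sp), tolerance = 1e-9)
        ## Eq-consistency invariant
        expect_equal(realPart(back)^2 + imaginaryPart(back)^2,
                     magnitude(back)^2, tolerance = 1e-9)
    }
})

test_that("scaling all raw magnitudes by k scales impedances by 1/k", {
    model <- syntheticCalibration(SweepConfig(nSteps = 15L))
    f <- frequencies(model)
    set.seed(7)
    sp <- ImpedanceSpectrum(f, exp(runif(16, 4, 7)), runif(16, -1, 1))
    raw <- encodeRaw(sp, model)
    raw3 <- RawSweep(f, 3 * raw@rr, 3 * raw@ir)
    expect_equal(magnitude(applyCalibration(raw3, model)),
                 magnitude(sp) / 3, tolerance = 1e-12)
})

test_that("series RC phantom and error percentage verify the calibration", {
    expect_equal(rcSeriesImpedance(100, 100e-9, 10000)$magnitude,
                 sqrt(100^2 + (1 / (2 * pi * 1e4 * 1e-7))^2))
    expect_equal(rcSeriesImpedance(100, 100e-9, 10000)$magnitude,
                 187.97, tolerance = 1e-4)
    expect_equal(rcSeriesImpedance(100, 100e-9, 77200)$magnitude,
                 102.10, tolerance = 1e-4)
    ## the capacitor vanishes at high frequency
    expect_equal(rcSeriesImpedance(100, 100e-9, 1e12)$magnitude, 100,
                 tolerance = 1e-6)
    expect_lt(rcSeriesImpedance(100, 100e-9, 10000)$phase, 0)
    expect_equal(errorPercentage(100, 96), 4)
    expect_equal(errorPercentage(100, 100), 0)
    expect_equal(errorPercentage(200, 190), 5)
    expect_error(errorPercentage(0, 1), "nonzero")
})

test_that("applying a mismatched calibration model is an alignment error", {
    model <- syntheticCalibration(SweepConfig(nSteps = 3L))
    raw <- RawSweep(c(1, 2, 3, 4), rep(1, 4), rep(0, 4))
    expect_error(applyCalibration(raw, model), "alignment")
})

test_that("raw sweeps, spectra and calibration models round-trip through disk", {
    model <- syntheticCalibration(SweepConfig(nSteps = 7L))
    f <- frequencies(model)
    sp <- ImpedanceSpectrum(f, exp(seq(4, 5, length.out = 8)),
                            seq(-0.4, -0.1, length.out = 8))
    raw <- encodeRaw(sp, model)

    fr <- tempfile(fileext = ".csv")
    writeRawSweepCsv(raw, fr)
    raw2 <- readRawSweepCsv(fr)
    expect_equal(raw2@rr, raw@rr)
    expect_equal(raw2@ir, raw@ir)

    fs <- tempfile(fileext = ".csv")
    writeSpectrumCsv(sp, fs)
    sp2 <- readSpectrumCsv(fs)
    expect_equal(magnitude(sp2), magnitude(sp), tolerance = 1e-12)

    fj <- tempfile(fileext = ".json")
    saveCalibrationJson(model, fj)
    model2 <- loadCalibrationJson(fj)
    expect_equal(gainFactor(model2), gainFactor(model))
    expect_equal(systemPhase(model2), systemPhase(model))

    expect_error(readRawSweepCsv(fs), "validation")
})
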