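test_that("power-law fits recover noiseless parameters exactly", {
    f <- DEFAULT_FREQUENCIES
    fit <- fitPowerLaw(f, 2 * f^-0.5)
    expect_equal(fit@a, 2, tolerance = 1e-9)
    expect_equal(fit@b, -0.5, tolerance = 1e-9)
    expect_equal(fit@rSquared, 1, tolerance = 1e-9)

    flat <- fitPowerLaw(f, rep(150, 4))
    expect_equal(flat@a, 150, tolerance = 1e-9)
    expect_equal(flat@b, 0, tolerance = 1e-12)
    expect_equal(flat@rSquared, 1)

    expect_error(fitPowerLaw(f, c(-1, 1, 1, 1)), "domain")
    expect_error(fitPowerLaw(f[1:2], c(1, 2)))
})

test_that("power-law fits agree with a brute-force grid minimizer", {
    set.seed(23)
    for (rep in 1:10) {
        f <- sort(runif(6, 1e3, 1e5))
        a <- exp(runif(1, 2, 8)); b <- runif(1, -1, 0.5)
        y <- a * f^b * exp(rnorm(6, 0, 0.1))
        fit <- fitPowerLaw(f, y)
        ref <- gridPowerLaw(f, y)
        expect_equal(log(fit@a), log(ref$a), tolerance = 1e-6)
        expect_equal(fit@b, ref$b, tolerance = 1e-6)
    }
})

test_that("noisy recovery stays within 5% at 1% multiplicative noise", {
    f <- sweepFrequencies(SweepConfig())
    set.seed(24)
    for (rep in 1:20) {
        a <- 3000; b <- -0.4
        y <- a * f^b * exp(rnorm(length(f), 0, 0.01))
        fit <- fitPowerLaw(f, y)
        expect_lt(abs(fit@a - a) / a, 0.05)
        expect_lt(abs(fit@b - b) / abs(b), 0.05)
    }
})

test_that("measurement validation thresholds the goodness of fit", {
    good <- fitPowerLaw(DEFAULT_FREQUENCIES,
                        2 * DEFAULT_FREQUENCIES^-0.5)
    expect_true(validateMeasurement(good, 1))
    fake <- new("PowerLawFit", a = 1, b = 0, rSquared = 0.5)
    expect_false(validateMeasurement(fake, 0.9))
    expect_true(validateMeasurement(fake, 0.5))   # closed comparison

    ## a pure-noise spectrum over the full sweep essentially never passes
    f <- sweepFrequencies(SweepConfig())
    set.seed(25)
    r2 <- replicate(100, fitPowerLaw(f, exp(rnorm(length(f))))@rSquared)
    expect_gte(mean(r2 < 0.9), 0.95)
})

## measurements whose magnitudes follow a power law scaled so that the
## classifier below labels them by overall impedance level
voteFixture <- function(nDiab, nNondiab, corrupt = 0) {
    f <- DEFAULT_FREQUENCIES
    mk <- function(a, id) {
        sp <- powerLawSpectrum(a, -0.35, f)
        cbind(measurement_id = id, buildFeatures(sp))
    }
    rows <- do.call(rbind, c(
        lapply(seq_len(nDiab), function(i) mk(7500, paste0("d", i))),
        lapply(seq_len(nNondiab), function(i) mk(5000, paste0("n", i)))))
    if (corrupt > 0) {
        magCols <- paste0("f", f, "_mag")
        for (i in seq_len(corrupt))
            rows[i, magCols] <- c(100, 400, 100, 400)  # not a power law
    }
    rows[, !(names(rows) %in% c("subject_id", "label"))]
}

voteModel <- function() {
    f <- DEFAULT_FREQUENCIES
    tr <- rbind(
        do.call(rbind, lapply(1:12, function(i)
            buildFeatures(powerLawSpectrum(7500 * exp(rnorm(1, 0, 0.03)),
                                           -0.35, f), label = 1,
                          subjectId = paste0("a", i)))),
        do.call(rbind, lapply(1:12, function(i)
            buildFeatures(powerLawSpectrum(5000 * exp(rnorm(1, 0, 0.03)),
                                           -0.35, f), label = 0,
                          subjectId = paste0("b", i)))))
    trainLogistic(tr)
}

test_that("voting needs 80% agreement among valid measurements", {
    set.seed(26)
    m <- voteModel()
    v8 <- votePredict(m, voteFixture(8, 2))
    expect_equal(decision(v8), "diabetic")
    expect_equal(agreement(v8), 0.8)
    expect_equal(v8@nValid, 10L)

    v7 <- votePredict(m, voteFixture(7, 3))
    expect_equal(decision(v7), "undefined")

    v10 <- votePredict(m, voteFixture(0, 10))
    expect_equal(decision(v10), "nondiabetic")
    expect_equal(agreement(v10), 1)

    ## order invariance
    meas <- voteFixture(8, 2)
    shuffled <- meas[c(5, 9, 1, 10, 2, 7, 3, 8, 4, 6), ]
    expect_equal(decision(votePredict(m, shuffled)), "diabetic")

    ## raising the threshold can only push toward undefined
    expect_equal(decision(votePredict(m, voteFixture(8, 2),
                                      voteThreshold = 0.9)), "undefined")
})

test_that("invalid and insufficient measurements are handled explicitly", {
    set.seed(27)
    m <- voteModel()
    ## two corrupted nondiabetic measurements are excluded: 8 diabetic of
    ## 8 valid -> unanimous
    vc <- votePredict(m, voteFixture(8, 2, corrupt = 2))
    ## corruption hits the first rows (diabetic ones)
    expect_equal(vc@nValid, 8L)
    expect_false(all(vc@perMeasurement$valid))

    vin <- votePredict(m, voteFixture(8, 2, corrupt = 6))
    expect_equal(decision(vin), "undefined")
    expect_match(vin@reason, "insufficient")

    expect_error(votePredict(m, voteFixture(1, 0)[0, ]), "1")
})
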