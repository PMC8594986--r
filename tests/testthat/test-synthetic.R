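test_that("the default cohort matches the study composition exactly", {
    co <- generateCohort(CohortSpec(), seed = 1)
    feat <- co$features
    subj <- co$truth$subjects
    expect_equal(nrow(feat), 256L)
    expect_equal(ncol(feat), 22L)   # subject_id, label, 20 attributes
    expect_equal(length(unique(feat$subject_id)), 53L)
    expect_equal(sum(subj$sex == 0), 34L)
    expect_equal(sum(subj$true_label), 20L)
    expect_true(all(subj$age >= 19 & subj$age <= 76))
    ## every row traces back to its subject record
    expect_true(all(feat$subject_id %in% subj$subject_id))
    expect_equal(as.vector(table(feat$subject_id)[subj$subject_id]),
                 subj$n_measurements)
    expect_equal(sum(subj$n_measurements), 256L)
    ## labels propagate from the subject record
    expect_equal(feat$label,
                 subj$label[match(feat$subject_id, subj$subject_id)])
})

test_that("generation is deterministic given the seed, down to the bytes", {
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    writeFeatureCsv(generateCohort(CohortSpec(), seed = 7)$features, f1)
    writeFeatureCsv(generateCohort(CohortSpec(), seed = 7)$features, f2)
    expect_identical(readLines(f1), readLines(f2))
    f3 <- tempfile(fileext = ".csv")
    writeFeatureCsv(generateCohort(CohortSpec(), seed = 8)$features, f3)
    expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("a null cohort carries no class signal", {
    co <- generateCohort(CohortSpec(classEffect = 1,
                                    biometricShift = c(0, 0)),
                         seed = 30)
    feat <- co$features
    ## grouped folds: repeated measurements of a subject must not leak
    ## across the split, or the model can memorize subject profiles
    foldId <- impedScreen:::withSeed(
        1, impedScreen:::.assignFolds(feat, 2, TRUE))
    accs <- vapply(1:2, function(k) {
        m <- trainLogistic(feat[foldId != k, ])
        mean(predictClass(m, feat[foldId == k, ]) ==
                 feat$label[foldId == k])
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("label noise flips the recorded labels of whole subjects", {
    co <- generateCohort(CohortSpec(labelNoise = 0.15), seed = 31)
    subj <- co$truth$subjects
    expect_equal(sum(subj$label != subj$true_label), round(0.15 * 53))
    ## a subject's measurements all share the recorded label
    agg <- tapply(co$features$label, co$features$subject_id,
                  function(v) length(unique(v)))
    expect_true(all(agg == 1))
})

test_that("noise-free spectra recover the subject's power law exactly", {
    co <- generateCohort(CohortSpec(noiseSd = 0), seed = 32)
    feat <- co$features
    subj <- co$truth$subjects
    magCols <- paste0("f", DEFAULT_FREQUENCIES, "_mag")
    for (s in c(1, 20, 53)) {
        row <- feat[match(subj$subject_id[s], feat$subject_id), ]
        fit <- fitPowerLaw(DEFAULT_FREQUENCIES, as.numeric(row[magCols]))
        expect_equal(fit@a, subj$a[s], tolerance = 1e-9)
        expect_equal(fit@b, subj$b[s], tolerance = 1e-9)
        expect_equal(fit@rSquared, 1, tolerance = 1e-9)
    }
})

test_that("raw encoding inverts calibration and scales as expected", {
    model <- syntheticCalibration(SweepConfig())
    f <- frequencies(model)
    set.seed(33)
    sp <- ImpedanceSpectrum(f, exp(runif(length(f), 4, 7)),
                            runif(length(f), -1, 0))
    back <- applyCalibration(encodeRaw(sp, model), model)
    expect_equal(magnitude(back), magnitude(sp), tolerance = 1e-9)
    expect_equal(phase(back), phase(sp), tolerance = 1e-9)

    ## a spectrum at the calibration resistance encodes to the
    ## calibration raw magnitude
    spCal <- ImpedanceSpectrum(f, rep(model@calibrationResistance,
                                      length(f)), rep(0, length(f)))
    rawCal <- encodeRaw(spCal, model)
    expect_equal(rawMagnitude(rawCal@rr, rawCal@ir),
                 1 / (gainFactor(model) * model@calibrationResistance),
                 tolerance = 1e-12)

    ## doubling the magnitude halves the raw magnitude
    sp2 <- ImpedanceSpectrum(f, 2 * magnitude(sp), phase(sp))
    raw1 <- encodeRaw(sp, model); raw2 <- encodeRaw(sp2, model)
    expect_equal(rawMagnitude(raw2@rr, raw2@ir),
                 rawMagnitude(raw1@rr, raw1@ir) / 2, tolerance = 1e-12)
})

test_that("repeat-measurement stability reflects the configured noise", {
    rsdPerHour <- function(series) {
        agg <- aggregate(magnitude_ohm ~ hour + frequency_hz, series,
                         function(v) 100 * sd(v) / mean(v))
        mean(agg$magnitude_ohm)
    }
    s2 <- stabilitySeries(CohortSpec(), nHours = 12, perHour = 10,
                          seed = 34)
    expect_equal(nrow(s2), 12 * 10 * 4)
    rsd2 <- rsdPerHour(s2)
    expect_gt(rsd2, 1.4); expect_lt(rsd2, 2.6)   # ~2% by design

    s0 <- stabilitySeries(CohortSpec(noiseSd = 0), seed = 34)
    expect_equal(rsdPerHour(s0), 0)

    s4 <- stabilitySeries(CohortSpec(noiseSd = 0.04), seed = 34)
    ## RSD scales roughly linearly in the small-noise regime
    expect_gt(rsdPerHour(s4) / rsd2, 1.6)
    expect_lt(rsdPerHour(s4) / rsd2, 2.4)
})

test_that("infeasible cohort specifications are rejected", {
    expect_error(generateCohort(CohortSpec(totalSamples = 40L)),
                 "totalSamples")
    expect_error(CohortSpec(nFemale = 60L), "nFemale")
    expect_error(CohortSpec(labelNoise = 1.5), "labelNoise")
})
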