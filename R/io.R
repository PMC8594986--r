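#' Read and write the package's file formats
#'
#' Plain-text interchange for every pipeline stage: raw sweeps and
#' calibrated spectra as CSV, calibration models and classifiers as JSON,
#' feature tables as CSV, ATSS history as JSON lines, and prediction /
#' comparison reports as JSON. All writers round-trip losslessly through
#' the matching reader.
#'
#' @param path file path.
#' @param sweep,model,spectrum,table,state,vote objects to serialize.
#' @name impedScreen-io
NULL

#' @rdname impedScreen-io
#' @export
writeRawSweepCsv <- function(sweep, path) {
    stopifnot(is(sweep, "RawSweep"))
    utils::write.csv(data.frame(frequency_hz = sweep@frequencies,
                                rr = sweep@rr, ir = sweep@ir),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname impedScreen-io
#' @export
readRawSweepCsv <- function(path) {
    df <- utils::read.csv(path)
    need <- c("frequency_hz", "rr", "ir")
    if (!all(need %in% names(df)))
        stop("validation error in ", path, ": expected columns ",
             paste(need, collapse = ", "))
    RawSweep(df$frequency_hz, df$rr, df$ir)
}

#' @rdname impedScreen-io
#' @export
writeSpectrumCsv <- function(spectrum, path) {
    stopifnot(is(spectrum, "ImpedanceSpectrum"))
    utils::write.csv(data.frame(frequency_hz = spectrum@frequencies,
                                magnitude_ohm = spectrum@magnitude,
                                phase_rad = spectrum@phase,
                                real_ohm = spectrum@realPart,
                                imag_ohm = spectrum@imaginaryPart),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname impedScreen-io
#' @export
readSpectrumCsv <- function(path) {
    df <- utils::read.csv(path)
    ImpedanceSpectrum(df$frequency_hz, df$magnitude_ohm, df$phase_rad)
}

#' @rdname impedScreen-io
#' @export
saveCalibrationJson <- function(model, path) {
    stopifnot(is(model, "CalibrationModel"))
    jsonlite::write_json(
        list(calibration_resistance = model@calibrationResistance,
             frequencies = model@frequencies,
             gain_factor = model@gainFactor,
             system_phase = model@systemPhase),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname impedScreen-io
#' @export
loadCalibrationJson <- function(path) {
    obj <- jsonlite::fromJSON(path)
    new("CalibrationModel",
        frequencies = as.numeric(obj$frequencies),
        gainFactor = as.numeric(obj$gain_factor),
        systemPhase = as.numeric(obj$system_phase),
        calibrationResistance = as.numeric(obj$calibration_resistance))
}

#' @rdname impedScreen-io
#' @export
writeFeatureCsv <- function(table, path) {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname impedScreen-io
#' @export
readFeatureCsv <- function(path) {
    df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
    if (!all(c("subject_id", "label") %in% names(df)))
        stop("validation error in ", path,
             ": expected subject_id and label columns")
    df
}

#' @rdname impedScreen-io
#' @export
writeHistoryJsonl <- function(state, path) {
    stopifnot(is(state, "AtssState"))
    h <- state@history
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(h)))
        writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE,
                                    digits = NA, na = "null"), con)
    invisible(path)
}

#' @rdname impedScreen-io
#' @export
writeVoteJson <- function(vote, path = NULL) {
    stopifnot(is(vote, "VoteResult"))
    obj <- list(decision = vote@decision,
                agreement = vote@agreement,
                n_valid = vote@nValid,
                reason = vote@reason,
                per_measurement = vote@perMeasurement)
    if (is.null(path))
        return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}

#' Write a screening report (attribute significance + model fit)
#'
#' @param screen output of [chiSquareScreen()].
#' @param hosmer output of [hosmerLemeshow()], or `NULL`.
#' @param path JSON file to write.
#' @export
writeScreeningJson <- function(screen, hosmer = NULL, path) {
    attrs <- stats::setNames(
        lapply(seq_len(nrow(screen)), function(i)
            list(chi2_p = screen$chi2_p[i],
                 significant = screen$significant[i])),
        screen$attribute)
    obj <- list(attributes = attrs)
    if (!is.null(hosmer))
        obj$model_fit <- list(hosmer_stat = hosmer$statistic,
                              hosmer_p = hosmer$p_value)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a method-comparison report
#'
#' @param report output of [compareMethods()].
#' @param jsonPath JSON report file.
#' @param csvPath optional CSV of the paired accuracy lists.
#' @export
writeComparisonJson <- function(report, jsonPath, csvPath = NULL) {
    jsonlite::write_json(
        list(summary = report$summary,
             kappa = as.list(report$kappa),
             wilcoxon_p = report$wilcoxon_p,
             sw_summary = report$sw_summary),
        jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(csvPath))
        utils::write.csv(report$accuracy, csvPath, row.names = FALSE,
                         quote = FALSE)
    invisible(jsonPath)
}
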