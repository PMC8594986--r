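#' Fit a power law to a magnitude spectrum
#'
#' Least-squares fit of `y = a * x^b` in log-log space: ordinary regression
#' of `log y` on `log x` gives `log a` and `b`, and the goodness of fit is
#' the R-squared of that regression. Physical impedance magnitude spectra
#' follow this form closely, so a poor fit flags a corrupted measurement
#' (electrode slip, motion, contact loss).
#'
#' @param frequencies Hz, at least 3 points.
#' @param magnitudes ohm, strictly positive.
#' @return a [PowerLawFit-class].
#' @examples
#' f <- c(10000, 32400, 54800, 77200)
#' fitPowerLaw(f, 2 * f^-0.5)   # recovers a = 2, b = -0.5, R^2 = 1
#' @export
fitPowerLaw <- function(frequencies, magnitudes) {
    stopifnot(length(frequencies) == length(magnitudes),
              length(frequencies) >= 3L)
    if (any(magnitudes <= 0))
        stop("domain error: magnitudes must be positive for a log-log fit")
    if (any(frequencies <= 0))
        stop("domain error: frequencies must be positive")
    lx <- log(frequencies)
    ly <- log(magnitudes)
    mx <- mean(lx); my <- mean(ly)
    b <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
    la <- my - b * mx
    ssRes <- sum((ly - (la + b * lx))^2)
    ssTot <- sum((ly - my)^2)
    r2 <- if (ssTot < 1e-24) {
        if (ssRes < 1e-24) 1 else 0
    } else max(0, min(1, 1 - ssRes / ssTot))
    new("PowerLawFit", a = exp(la), b = b, rSquared = r2)
}

#' Validity check of a measurement from its power-law fit
#'
#' @param fit a [PowerLawFit-class].
#' @param r2Threshold minimum R-squared for a measurement to count as valid
#'   (default 0.90).
#' @return `TRUE` iff `rSquared >= r2Threshold`.
#' @export
validateMeasurement <- function(fit, r2Threshold = 0.90) {
    stopifnot(is(fit, "PowerLawFit"))
    fit@rSquared >= r2Threshold
}

#' Voting prediction over repeated measurements
#'
#' The screening decision for one participant from a batch of repeated
#' measurements (10 in the device protocol). Each measurement's magnitude
#' spectrum is checked against the power law `y = a * x^b`; measurements
#' below the R-squared threshold are excluded. Each valid measurement is
#' classified, and the modal class becomes the decision only when its share
#' among valid measurements reaches the vote threshold (closed comparison:
#' 8/10 passes at 0.8); otherwise the decision is "undefined". When fewer
#' than `minValid` measurements survive the validity check the decision is
#' "undefined" with reason "insufficient valid measurements".
#'
#' @param model a fitted [ClassifierModel-class].
#' @param measurements feature table, one row per measurement; magnitude
#'   attributes (`f<freq>_mag`) must be present for the fit check. An
#'   optional `measurement_id` column labels the report.
#' @param frequencies the frequencies of the magnitude attributes
#'   (default [DEFAULT_FREQUENCIES]).
#' @param voteThreshold minimum modal-class share (default 0.8).
#' @param r2Threshold minimum power-law R-squared (default 0.9).
#' @param minValid minimum number of valid measurements for a class
#'   decision (default 5).
#' @return a [VoteResult-class].
#' @export
votePredict <- function(model, measurements,
                        frequencies = DEFAULT_FREQUENCIES,
                        voteThreshold = 0.8, r2Threshold = 0.9,
                        minValid = 5L) {
    stopifnot(is(model, "ClassifierModel"), nrow(measurements) >= 1L,
              voteThreshold > 0, voteThreshold <= 1)
    magCols <- paste0("f", format(frequencies, scientific = FALSE,
                                  trim = TRUE), "_mag")
    missing <- setdiff(magCols, names(measurements))
    if (length(missing))
        stop("schema error: missing magnitude column(s) ",
             paste(missing, collapse = ", "))
    ids <- if ("measurement_id" %in% names(measurements))
        as.character(measurements$measurement_id)
    else as.character(seq_len(nrow(measurements)))
    r2 <- vapply(seq_len(nrow(measurements)), function(i)
        fitPowerLaw(frequencies,
                    as.numeric(measurements[i, magCols]))@rSquared,
        numeric(1L))
    valid <- r2 >= r2Threshold
    prob <- predictProbability(model, measurements)
    cls <- as.numeric(prob >= model@threshold)
    per <- data.frame(measurement_id = ids, r2 = r2, valid = valid,
                      class = ifelse(cls == 1, "diabetic", "nondiabetic"),
                      probability = prob, row.names = NULL)
    nValid <- sum(valid)
    if (nValid < minValid) {
        return(new("VoteResult", decision = "undefined",
                   agreement = NA_real_, nValid = as.integer(nValid),
                   perMeasurement = per,
                   reason = "insufficient valid measurements"))
    }
    votes <- cls[valid]
    shares <- table(factor(votes, levels = c(0, 1))) / nValid
    top <- which.max(shares)
    agreement <- as.numeric(shares[top])
    dec <- if (agreement >= voteThreshold) {
        if (names(shares)[top] == "1") "diabetic" else "nondiabetic"
    } else "undefined"
    new("VoteResult", decision = dec, agreement = agreement,
        nValid = as.integer(nValid), perMeasurement = per, reason = "")
}
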