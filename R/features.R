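#' Biometric attributes of a participant
#'
#' @param age years, in [0, 120].
#' @param weight kilograms, > 0.
#' @param sex 0 = female, 1 = male (coding fixed package-wide and persisted
#'   with exported models).
#' @param height centimeters, > 0.
#' @return a validated named list.
#' @export
Biometrics <- function(age, weight, sex, height) {
    stopifnot(age >= 0, age <= 120, weight > 0, height > 0,
              sex %in% c(0, 1))
    list(age = as.numeric(age), weight = as.numeric(weight),
         sex = as.numeric(sex), height = as.numeric(height))
}

.BIOMETRIC_NAMES <- c("age", "weight", "sex", "height")

#' Attribute names of the impedance feature blocks
#'
#' One block of `mag`, `phase`, `real`, `imag` per frequency, in frequency
#' order, e.g. `f10000_mag, f10000_phase, f10000_real, f10000_imag, ...`.
#'
#' @param freqs frequencies in Hz.
#' @param biometrics if `TRUE` (default) append the four biometric names.
#' @return character vector of attribute names in canonical order.
#' @export
featureNames <- function(freqs, biometrics = TRUE) {
    blocks <- as.vector(vapply(freqs, function(f)
        paste0("f", format(f, scientific = FALSE, trim = TRUE), "_",
               c("mag", "phase", "real", "imag")),
        character(4L)))
    if (biometrics) c(blocks, .BIOMETRIC_NAMES) else blocks
}

#' The four default screening frequencies (Hz)
#'
#' A subset of the 256-frequency sweep retained for classification; chosen
#' for adequate tissue penetration while keeping the model small enough for
#' statistical screening and microcontroller deployment.
#' @export
DEFAULT_FREQUENCIES <- c(10000, 32400, 54800, 77200)

#' Restrict a spectrum to target frequencies
#'
#' @param spectrum an [ImpedanceSpectrum-class].
#' @param targetFrequencies frequencies to keep (Hz); all must be present.
#' @return the restricted [ImpedanceSpectrum-class], target order preserved.
#' @export
selectFrequencies <- function(spectrum,
                              targetFrequencies = DEFAULT_FREQUENCIES) {
    stopifnot(is(spectrum, "ImpedanceSpectrum"))
    idx <- match(targetFrequencies, spectrum@frequencies)
    if (anyNA(idx))
        stop("frequency not present in spectrum: ",
             paste(targetFrequencies[is.na(idx)], collapse = ", "), " Hz")
    ImpedanceSpectrum(spectrum@frequencies[idx],
                      spectrum@magnitude[idx],
                      spectrum@phase[idx])
}

#' Build a feature row from a spectrum and biometrics
#'
#' Flattens a (frequency-restricted) spectrum into per-frequency blocks of
#' magnitude, phase, real and imaginary parts, followed by the biometric
#' attributes: with the four default frequencies, 4 x 4 + 4 = 20 attributes.
#'
#' @param spectrum an [ImpedanceSpectrum-class], already restricted to the
#'   configured frequencies.
#' @param biometrics a [Biometrics()] list, or `NULL` to emit impedance
#'   attributes only.
#' @param label binary class (1 = diabetic), or `NA` for unlabeled samples.
#' @param subjectId opaque identifier grouping repeated measurements.
#' @return a one-row data.frame: `subject_id`, `label`, then the attributes
#'   in canonical order.
#' @export
buildFeatures <- function(spectrum, biometrics = NULL, label = NA,
                          subjectId = NA_character_) {
    stopifnot(is(spectrum, "ImpedanceSpectrum"))
    vals <- as.vector(rbind(spectrum@magnitude, spectrum@phase,
                            spectrum@realPart, spectrum@imaginaryPart))
    nms <- featureNames(spectrum@frequencies, biometrics = FALSE)
    if (!is.null(biometrics)) {
        vals <- c(vals, biometrics$age, biometrics$weight,
                  biometrics$sex, biometrics$height)
        nms <- c(nms, .BIOMETRIC_NAMES)
    }
    out <- data.frame(subject_id = as.character(subjectId),
                      label = as.numeric(label),
                      t(vals))
    names(out)[-(1:2)] <- nms
    out
}

#' Attribute columns of a feature table
#'
#' @param table a feature-table data.frame as produced by [buildFeatures()]
#'   (or [generateCohort()]); identifier and label columns
#'   (`subject_id`, `label`, `measurement_id`) are dropped.
#' @return numeric matrix of attributes, samples in rows.
#' @export
featureMatrix <- function(table) {
    keep <- setdiff(names(table),
                    c("subject_id", "label", "measurement_id"))
    as.matrix(table[, keep, drop = FALSE])
}

## z-score standardization learned on training data; constant columns get
## sd 1 so they standardize to exactly zero
fitScaler <- function(x) {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    list(mean = mu, sd = sd)
}

applyScaler <- function(x, scaler) {
    sweep(sweep(x, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

## strictly monotone-invariant quantile bins (type-1 quantiles are order
## statistics, hence equivariant under increasing transforms)
.quantileBins <- function(x, nBins) {
    ## few distinct values (binary/categorical codes): use them directly
    if (length(unique(x)) <= nBins) return(factor(x))
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                                 type = 1, names = FALSE))
    if (length(br) < 2L) return(factor(rep(1L, length(x))))
    cut(x, breaks = br, include.lowest = TRUE)
}

#' Chi-square screening of attributes against the class label
#'
#' For each attribute, a Pearson chi-square test of independence between the
#' quantile-binned attribute and the binary label. Attributes with p < alpha
#' are flagged significant. Constant attributes are degenerate and reported
#' with p = 1.
#'
#' @param table feature table with a `label` column, or a plain matrix.
#' @param labels binary labels; taken from `table$label` when omitted.
#' @param nBins number of quantile bins for continuous attributes
#'   (default 4).
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame with `attribute`, `chi2_p`, `significant`.
#' @export
chiSquareScreen <- function(table, labels = NULL, nBins = 4L, alpha = 0.05) {
    stopifnot(nBins >= 2L)
    if (is.null(labels)) labels <- table$label
    x <- if (is.matrix(table)) table else featureMatrix(table)
    if (length(labels) != nrow(x))
        stop("labels must match the number of samples")
    if (min(table(labels)) < 2L || length(unique(labels)) < 2L)
        stop("insufficient data: need at least 2 samples per class")
    p <- vapply(seq_len(ncol(x)), function(j) {
        b <- .quantileBins(x[, j], nBins)
        if (nlevels(droplevels(b)) < 2L) return(1)
        suppressWarnings(
            stats::chisq.test(table(b, labels), correct = FALSE)$p.value)
    }, numeric(1L))
    data.frame(attribute = colnames(x), chi2_p = p,
               significant = p < alpha, row.names = NULL)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups samples into `nGroups` equal-size risk groups by predicted
#' probability and compares observed against expected outcome counts in each
#' group; the statistic is referred to a chi-square distribution with
#' `nGroups - 2` degrees of freedom. A small p-value indicates poor
#' calibration of the fitted probabilities.
#'
#' @param labels binary outcomes.
#' @param probabilities predicted probabilities in [0, 1].
#' @param nGroups number of risk groups (default 10, decile-of-risk).
#' @param onDegenerate `"fail"` (default) stops when a group has a zero
#'   expected count; `"merge"` merges it with the neighbouring group.
#' @return list with `statistic`, `p_value`, `df`, `n_groups`.
#' @export
hosmerLemeshow <- function(labels, probabilities, nGroups = 10L,
                           onDegenerate = c("fail", "merge")) {
    onDegenerate <- match.arg(onDegenerate)
    n <- length(labels)
    stopifnot(length(probabilities) == n, nGroups >= 2L, n >= nGroups)
    if (any(probabilities < 0 | probabilities > 1))
        stop("probabilities must lie in [0, 1]")
    if (n < 2L * nGroups)
        stop("degenerate grouping: fewer than 2 samples per group")
    ord <- order(probabilities)
    grp <- ceiling(seq_len(n) / (n / nGroups))
    grp[grp > nGroups] <- nGroups
    o1 <- tapply(labels[ord], grp, sum)
    e1 <- tapply(probabilities[ord], grp, sum)
    ng <- tapply(rep(1, n), grp, sum)
    o0 <- ng - o1
    e0 <- ng - e1
    degen <- e1 == 0 | e0 == 0
    if (any(degen)) {
        if (onDegenerate == "fail")
            stop("degenerate group: zero expected count; ",
                 "consider onDegenerate = \"merge\"")
        while (any(degen) && length(e1) > 2L) {
            i <- which(degen)[1L]
            j <- if (i == 1L) 2L else i - 1L
            o1[j] <- o1[j] + o1[i]; e1[j] <- e1[j] + e1[i]
            o0[j] <- o0[j] + o0[i]; e0[j] <- e0[j] + e0[i]
            o1 <- o1[-i]; e1 <- e1[-i]; o0 <- o0[-i]; e0 <- e0[-i]
            degen <- e1 == 0 | e0 == 0
        }
        if (any(degen)) stop("degenerate group persists after merging")
    }
    stat <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
    df <- length(e1) - 2L
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         df = df, n_groups = length(e1))
}
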