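#' Confusion counts and performance indicators
#'
#' Tabulates true/false positives/negatives (positive class = diabetic,
#' label 1) and the three screening indicators: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#' Ratios with a zero denominator are reported as `NA`, not 0. Predictions
#' of `NA` stand for "undefined" voting outcomes: they are excluded from the
#' counts and reported in `n_undefined`.
#'
#' @param labels binary reference labels (1 = diabetic).
#' @param predictions binary predictions, `NA` for undefined outcomes.
#' @return list with `counts` (tp, tn, fp, fn), `accuracy`, `precision`,
#'   `recall`, `n_undefined`.
#' @export
performance <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("schema error: labels and predictions differ in length")
    stopifnot(length(labels) >= 1L)
    keep <- !is.na(predictions)
    nUndef <- sum(!keep)
    y <- labels[keep]; p <- predictions[keep]
    tp <- sum(y == 1 & p == 1)
    tn <- sum(y == 0 & p == 0)
    fp <- sum(y == 0 & p == 1)
    fn <- sum(y == 1 & p == 0)
    rat <- function(num, den) if (den == 0) NA_real_ else num / den
    list(counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
         accuracy = rat(tp + tn, tp + tn + fp + fn),
         precision = rat(tp, tp + fp),
         recall = rat(tp, tp + fn),
         n_undefined = nUndef)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p0 - pe) / (1 - pe)`, with `p0` the
#' observed agreement proportion and `pe` the expected agreement from the
#' marginal class frequencies of labels and predictions. Perfect agreement
#' with degenerate marginals (`pe = 1`, `p0 = 1`) is reported as 1;
#' `pe = 1` with imperfect agreement is undefined and reported as `NA`.
#'
#' @param labels,predictions equal-length binary vectors.
#' @return kappa in [-1, 1], or `NA` when undefined.
#' @export
cohenKappa <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("schema error: labels and predictions differ in length")
    n <- length(labels)
    stopifnot(n >= 1L)
    p0 <- mean(labels == predictions)
    classes <- union(unique(labels), unique(predictions))
    pe <- sum(vapply(classes, function(cl)
        mean(labels == cl) * mean(predictions == cl), numeric(1L)))
    if (abs(1 - pe) < .Machine$double.eps * 4) {
        if (p0 == 1) return(1)
        return(NA_real_)
    }
    (p0 - pe) / (1 - pe)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences are
#' discarded first; the exact distribution is used for up to 25 nonzero
#' untied differences, and the normal approximation with tie correction
#' otherwise.
#'
#' @param x,y equal-length paired samples.
#' @return two-sided p-value.
#' @export
wilcoxonSignedRank <- function(x, y) {
    if (length(x) != length(y))
        stop("schema error: x and y differ in length")
    d <- x - y
    d <- d[d != 0]
    if (length(d) == 0L)
        stop("no information: all paired differences are zero")
    if (length(d) < 5L)
        stop("need at least 5 nonzero paired differences")
    if (length(d) <= 25L) return(.exactSignedRank(d))
    res <- suppressWarnings(stats::wilcox.test(
        d, mu = 0, alternative = "two.sided",
        exact = FALSE, correct = TRUE))
    res$p.value
}

## exact two-sided signed-rank p-value by enumerating the sign-flip
## distribution of the observed (possibly tied, midranked) ranks via
## dynamic programming over doubled ranks (integers even with .5 midranks)
.exactSignedRank <- function(d) {
    r2 <- as.integer(round(2 * rank(abs(d))))
    v <- sum(r2[d > 0])
    total <- sum(r2)
    ## counts[k + 1] = number of sign assignments with statistic k
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (r in r2) {
        shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
        counts <- counts + shifted
    }
    counts <- counts / sum(counts)
    pLow <- sum(counts[seq_len(v + 1L)])
    pHigh <- sum(counts[(v + 1L):(total + 1L)])
    min(1, 2 * min(pLow, pHigh))
}
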