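#' Compare traditional training against active training by seed selection
#'
#' The repeated randomized evaluation protocol: for each repeat, a seeded
#' random permutation defines a stratified cross-validation split (grouped
#' by subject by default, so a participant's repeated measurements never
#' straddle a fold boundary) and the ATSS streaming order. On every
#' training fold both methods are fitted — traditional supervised training
#' on the full fold, and ATSS — and evaluated on the held-out fold. With 30
#' repeats of 5-fold cross-validation this yields 150 paired accuracy
#' values per method, compared with a two-sided paired Wilcoxon signed-rank
#' test; Cohen's kappa is computed on the pooled test-fold predictions of
#' each method, and the silhouette-width summary contrasts the full
#' dataset, the seed populations and the final ATSS populations.
#'
#' @param dataset labeled feature table (see [generateCohort()]).
#' @param repeats number of randomized repeats (default 30).
#' @param folds folds per repeat (default 5).
#' @param baseSeed integer; every source of randomness derives from it.
#' @param groupBySubject keep all measurements of a subject in one fold
#'   (default `TRUE`; requires a `subject_id` column).
#' @param fraction,monitorFraction,capacity,C,indicatorGate passed to
#'   [runAtss()].
#' @return list with `accuracy` (data.frame: `repeat_`, `fold`,
#'   `traditional`, `atss`), `summary` (per-method mean and sd),
#'   `kappa` (per-method pooled kappa), `wilcoxon_p`, and `sw_summary`
#'   (mean silhouette width of the full dataset, of the seed populations,
#'   of the final populations, and the final-minus-full difference).
#' @export
compareMethods <- function(dataset, repeats = 30L, folds = 5L,
                           baseSeed = 1L, groupBySubject = TRUE,
                           fraction = 0.10, monitorFraction = 0.2,
                           capacity = NULL, C = 1,
                           indicatorGate = c("strict", "nondecreasing")) {
    indicatorGate <- match.arg(indicatorGate)
    stopifnot(repeats >= 1L, folds >= 2L)
    if (length(unique(dataset$label)) < 2L)
        stop("dataset must contain both classes")
    rownames(dataset) <- NULL
    n <- nrow(dataset)
    acc <- data.frame()
    pooled <- list(traditional = list(y = numeric(), p = numeric()),
                   atss = list(y = numeric(), p = numeric()))
    swSeed <- numeric()
    swFinal <- numeric()
    xAll <- featureMatrix(dataset)
    swFull <- mean(silhouetteWidths(applyScaler(xAll, fitScaler(xAll)),
                                    dataset$label)$s)
    for (r in seq_len(repeats)) {
        repSeed <- (baseSeed * 1000L + r) %% .Machine$integer.max
        foldId <- withSeed(repSeed,
                           .assignFolds(dataset, folds, groupBySubject))
        for (k in seq_len(folds)) {
            test <- dataset[foldId == k, , drop = FALSE]
            train <- dataset[foldId != k, , drop = FALSE]
            if (length(unique(train$label)) < 2L ||
                length(unique(test$label)) < 2L)
                stop("stratification error: a fold lost a class")
            tradModel <- trainLogistic(train, C = C)
            tradPred <- predictClass(tradModel, test)
            atssRun <- runAtss(train, capacity = capacity,
                               fraction = fraction,
                               monitorFraction = monitorFraction,
                               orderSeed = (repSeed * 10L + k) %%
                                   .Machine$integer.max,
                               C = C, indicatorGate = indicatorGate)
            atssPred <- predictClass(atssRun$model, test)
            acc <- rbind(acc, data.frame(
                repeat_ = r, fold = k,
                traditional = mean(tradPred == test$label),
                atss = mean(atssPred == test$label)))
            pooled$traditional$y <- c(pooled$traditional$y, test$label)
            pooled$traditional$p <- c(pooled$traditional$p, tradPred)
            pooled$atss$y <- c(pooled$atss$y, test$label)
            pooled$atss$p <- c(pooled$atss$p, atssPred)
            swSeed <- c(swSeed, atssRun$seedMeanSw)
            swFinal <- c(swFinal, mean(atssRun$state@sw))
        }
    }
    wp <- tryCatch(wilcoxonSignedRank(acc$atss, acc$traditional),
                   error = function(e) NA_real_)
    list(accuracy = acc,
         summary = data.frame(
             method = c("traditional", "atss"),
             mean_accuracy = c(mean(acc$traditional), mean(acc$atss)),
             sd_accuracy = c(stats::sd(acc$traditional),
                             stats::sd(acc$atss))),
         kappa = c(traditional = cohenKappa(pooled$traditional$y,
                                            pooled$traditional$p),
                   atss = cohenKappa(pooled$atss$y, pooled$atss$p)),
         wilcoxon_p = wp,
         sw_summary = list(mean_sw_full = swFull,
                           mean_sw_seed = mean(swSeed),
                           mean_sw_final = mean(swFinal),
                           mean_sw_difference = mean(swFinal) - swFull))
}

## stratified fold assignment; grouped variants keep a subject's
## measurements together (stratifying subjects by their recorded label)
.assignFolds <- function(dataset, folds, groupBySubject) {
    n <- nrow(dataset)
    foldId <- integer(n)
    if (groupBySubject && !is.null(dataset$subject_id)) {
        subj <- unique(dataset$subject_id)
        subjLabel <- vapply(subj, function(s)
            dataset$label[match(s, dataset$subject_id)], numeric(1L))
        subjFold <- integer(length(subj))
        for (cl in unique(subjLabel)) {
            idx <- which(subjLabel == cl)
            idx <- idx[sample.int(length(idx))]
            subjFold[idx] <- rep_len(seq_len(folds), length(idx))
        }
        foldId <- subjFold[match(dataset$subject_id, subj)]
    } else {
        for (cl in unique(dataset$label)) {
            idx <- which(dataset$label == cl)
            idx <- idx[sample.int(length(idx))]
            foldId[idx] <- rep_len(seq_len(folds), length(idx))
        }
    }
    foldId
}

#' Two-component PCA projection
#'
#' Projects standardized features onto their top two principal components,
#' the visualization used to contrast the class separation of the full
#' dataset against the ATSS-selected population. A visual aid only: no
#' decision logic depends on it.
#'
#' @param x feature table or numeric matrix (>= 3 samples, >= 2 columns).
#' @return list with `scores` (n x 2 matrix), `explained_variance`
#'   (length-2 proportion of variance per component), and the `rotation`
#'   matrix.
#' @export
pca2d <- function(x) {
    if (is.data.frame(x)) x <- featureMatrix(x)
    stopifnot(nrow(x) >= 3L, ncol(x) >= 2L)
    sds <- apply(x, 2L, stats::sd)
    if (all(sds == 0))
        stop("degenerate input: all samples identical")
    keep <- sds > 0
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, 1:2, drop = FALSE],
         explained_variance = ev[1:2],
         rotation = pc$rotation[, 1:2, drop = FALSE])
}
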