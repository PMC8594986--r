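## evaluate an expression under a given seed without disturbing the
## caller's RNG stream
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Per-sample silhouette widths for a binary labeling
#'
#' For each sample i, `a_i` is the mean Euclidean distance to the other
#' samples of its own class and `b_i` the mean distance to the samples of
#' the other class; the silhouette width is `1 - a_i/b_i` when `a_i < b_i`,
#' `0` when equal, and `b_i/a_i - 1` when `a_i > b_i`, so it lies in
#' [-1, 1]. High widths mark samples that sit firmly inside their own class;
#' negative widths mark samples closer to the opposite class, e.g.
#' mislabeled or atypical participants. Features should be standardized
#' first so that ohm-, year- and kilogram-scaled attributes contribute
#' comparably to the distances.
#'
#' @param x numeric matrix of (standardized) features, samples in rows, or a
#'   feature table (standardized internally with its own scaler only if
#'   `standardize = TRUE`).
#' @param labels binary labels, one per row.
#' @param standardize z-score the columns of `x` first (default `FALSE`:
#'   the caller controls the scaler).
#' @return data.frame with columns `a`, `b`, `s`.
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' silhouetteWidths(x, c(0, 0, 1, 1))$s   # ~0.990 for the outer points
#' @export
silhouetteWidths <- function(x, labels, standardize = FALSE) {
    if (is.data.frame(x)) x <- featureMatrix(x)
    if (standardize) x <- applyScaler(x, fitScaler(x))
    n <- nrow(x)
    if (length(labels) != n) stop("labels must match the number of rows")
    if (min(table(labels)) < 2L)
        stop("degenerate class: silhouette needs >= 2 samples per class")
    d <- as.matrix(stats::dist(x))
    .silhouetteFromDist(d, labels)
}

## silhouette widths from a precomputed distance matrix
.silhouetteFromDist <- function(d, labels) {
    n <- nrow(d)
    cls <- sort(unique(labels))
    same <- outer(labels, labels, "==")
    nSame <- tabulate(match(labels, cls), length(cls))[match(labels, cls)]
    a <- rowSums(d * same) / (nSame - 1L)
    b <- rowSums(d * !same) / (n - nSame)
    s <- ifelse(a < b, 1 - a / b, ifelse(a == b, 0, b / a - 1))
    data.frame(a = a, b = b, s = s)
}

## silhouette width of a single candidate against a reference population
## (the candidate's own width is identical whether or not the candidate is
## counted in the reference set, since a_i excludes the self-distance)
.candidateSilhouette <- function(zPop, popLabels, zCand, candLabel) {
    d <- sqrt(colSums((t(zPop) - as.numeric(zCand))^2))
    sameIdx <- popLabels == candLabel
    if (!any(sameIdx) || all(sameIdx))
        stop("degenerate class: population must contain both classes")
    a <- mean(d[sameIdx])
    b <- mean(d[!sameIdx])
    if (a < b) 1 - a / b else if (a == b) 0 else b / a - 1
}

## stratified top-silhouette allocation: k seats split across classes by
## largest remainder, at least two per class (a one-sample class cannot
## support a fit)
.allocateSeats <- function(k, classCounts) {
    minSeats <- pmin(2, classCounts)
    raw <- k * classCounts / sum(classCounts)
    seats <- floor(raw)
    rem <- k - sum(seats)
    if (rem > 0) {
        ord <- order(raw - seats, decreasing = TRUE)
        seats[ord[seq_len(rem)]] <- seats[ord[seq_len(rem)]] + 1L
    }
    for (i in seq_along(seats)) {
        while (seats[i] < minSeats[i]) {
            j <- which.max(seats - minSeats)
            seats[j] <- seats[j] - 1L
            seats[i] <- seats[i] + 1L
        }
        if (seats[i] > classCounts[i]) {
            excess <- seats[i] - classCounts[i]
            seats[i] <- classCounts[i]
            j <- which.max(classCounts - seats)
            seats[j] <- seats[j] + excess
        }
    }
    seats
}

#' Select the seed population for active training
#'
#' Takes the `ceiling(fraction * n)` training samples with the highest
#' silhouette widths as the initial (seed) population, allocating seats per
#' class in proportion to class size so both classes are always represented,
#' and trains the initial classifier on the seed. The standardization scaler
#' is fitted on the full training pool here and stays fixed for the rest of
#' the run.
#'
#' @param train feature table with labels (the ATSS training pool).
#' @param fraction seed fraction of the pool (default 0.10).
#' @param capacity maximum population size; default 60% of the pool.
#' @param monitor held-out labeled feature table on which the indicator
#'   gates of [considerSample()] are evaluated.
#' @param C inverse ridge strength passed to [trainLogistic()].
#' @param returnIndices also return the row indices of the selected seed
#'   (used by [runAtss()] to exclude seed rows from the stream).
#' @return an [AtssState-class], or when `returnIndices = TRUE` a list with
#'   `state` and `indices`.
#' @export
selectSeed <- function(train, fraction = 0.10, capacity = NULL,
                       monitor = train, C = 1, returnIndices = FALSE) {
    stopifnot(fraction > 0, fraction < 1)
    n <- nrow(train)
    classCounts <- as.numeric(table(train$label))
    k <- as.integer(ceiling(fraction * n))
    ## a workable seed needs two samples of each class
    k <- max(k, sum(pmin(2, classCounts)))
    if (is.null(capacity)) capacity <- as.integer(ceiling(0.6 * n))
    capacity <- as.integer(capacity)
    if (capacity < k)
        stop("configuration error: capacity (", capacity,
             ") smaller than the seed size (", k, ")")
    x <- featureMatrix(train)
    scaler <- fitScaler(x)
    z <- applyScaler(x, scaler)
    sw <- silhouetteWidths(z, train$label)$s
    cls <- sort(unique(train$label))
    seats <- .allocateSeats(k, as.numeric(table(factor(train$label, cls))))
    pick <- unlist(lapply(seq_along(cls), function(i) {
        idx <- which(train$label == cls[i])
        idx[order(sw[idx], decreasing = TRUE)][seq_len(seats[i])]
    }))
    pick <- sort(pick)
    seed <- train[pick, , drop = FALSE]
    rownames(seed) <- NULL
    model <- trainLogistic(seed, C = C, scaler = scaler)
    state <- new("AtssState",
        population = seed,
        sw = sw[pick],
        addedStep = rep(0L, length(pick)),
        capacity = capacity,
        model = model,
        monitor = monitor,
        scaler = scaler,
        history = data.frame(step = integer(), decision = character(),
                             s_candidate = numeric(), s_min = numeric(),
                             acc_before = numeric(), acc_after = numeric(),
                             prec_delta = numeric(), rec_delta = numeric()),
        stepCounter = 0L)
    if (returnIndices) list(state = state, indices = pick) else state
}

## "strictly greater" / "at least" with tolerance-free semantics after
## rounding, so indicator ties never commit on floating-point noise;
## an indicator that becomes defined counts as an increase
.r12 <- function(x) round(x, 12L)
.indGT <- function(new, old) {
    if (is.na(new)) return(FALSE)
    if (is.na(old)) return(TRUE)
    .r12(new) > .r12(old)
}
.indGE <- function(new, old) {
    if (is.na(new)) return(is.na(old))
    if (is.na(old)) return(TRUE)
    .r12(new) >= .r12(old)
}

#' Offer one candidate sample to the active-training population
#'
#' Implements the two acceptance rules of active training by seed
#' selection. Rule 1: the candidate's silhouette width with respect to the
#' current population must exceed the lowest width in the population,
#' otherwise it is rejected without retraining. Rule 2: the classifier is
#' retrained on the tentative population (the candidate added if below
#' capacity, else replacing the lowest-width sample) and, on the monitor
#' set, accuracy must not decrease while precision or recall strictly
#' increases; otherwise the tentative change is reverted. Ties on the
#' minimum width are broken by removing the earliest-added sample.
#'
#' @param state an [AtssState-class].
#' @param candidate a one-row labeled feature table.
#' @param C inverse ridge strength for retraining.
#' @param indicatorGate `"strict"` (default) requires monitor accuracy not
#'   to decrease while precision or recall strictly increases — the
#'   conservative reading of the acceptance rule, under which the
#'   population grows only when a candidate demonstrably improves an
#'   indicator. `"nondecreasing"` relaxes the second part to "does not
#'   decrease", letting the population grow toward capacity with any
#'   harmless high-silhouette candidate.
#' @return list with `decision` ("accepted", "replaced" or "rejected") and
#'   the updated `state` (the input state when rejected, with the history
#'   extended either way).
#' @export
considerSample <- function(state, candidate, C = 1,
                           indicatorGate = c("strict", "nondecreasing")) {
    indicatorGate <- match.arg(indicatorGate)
    stopifnot(is(state, "AtssState"), nrow(candidate) == 1L)
    if (is.na(candidate$label))
        stop("candidate must be labeled")
    step <- state@stepCounter + 1L
    pop <- state@population
    zPop <- applyScaler(featureMatrix(pop), state@scaler)
    zCand <- applyScaler(featureMatrix(candidate), state@scaler)
    sCand <- .candidateSilhouette(zPop, pop$label, zCand, candidate$label)
    sMin <- min(state@sw)

    monX <- featureMatrix(state@monitor)
    monY <- state@monitor$label
    perfOld <- performance(monY, predictClass(state@model, monX))

    logRow <- function(decision, accAfter, precD, recD) {
        data.frame(step = step, decision = decision,
                   s_candidate = sCand, s_min = sMin,
                   acc_before = perfOld$accuracy, acc_after = accAfter,
                   prec_delta = precD, rec_delta = recD)
    }
    reject <- function(accAfter = NA_real_, precD = NA_real_,
                       recD = NA_real_) {
        state@history <- rbind(state@history,
                               logRow("rejected", accAfter, precD, recD))
        state@stepCounter <- step
        list(decision = "rejected", state = state)
    }

    ## rule 1: silhouette gate
    if (!(sCand > sMin)) return(reject())

    ## tentative population
    if (nrow(pop) < state@capacity) {
        tentative <- rbind(pop, candidate)
        added <- rep(NA_integer_, 0L)
        removed <- integer(0)
        decision <- "accepted"
    } else {
        cand <- which(state@sw == sMin)
        removed <- cand[which.min(state@addedStep[cand])]
        tentative <- rbind(pop[-removed, , drop = FALSE], candidate)
        decision <- "replaced"
    }
    rownames(tentative) <- NULL

    ## rule 2: indicator gate on the monitor set
    newModel <- trainLogistic(tentative, C = C, scaler = state@scaler)
    perfNew <- performance(monY, predictClass(newModel, monX))
    precD <- perfNew$precision - perfOld$precision
    recD <- perfNew$recall - perfOld$recall
    cmp <- if (indicatorGate == "strict") .indGT else .indGE
    ok <- .indGE(perfNew$accuracy, perfOld$accuracy) &&
        (cmp(perfNew$precision, perfOld$precision) ||
         cmp(perfNew$recall, perfOld$recall))
    if (!ok) return(reject(perfNew$accuracy, precD, recD))

    ## commit
    zNew <- applyScaler(featureMatrix(tentative), state@scaler)
    state@population <- tentative
    state@sw <- silhouetteWidths(zNew, tentative$label)$s
    oldSteps <- if (decision == "accepted") state@addedStep
                else state@addedStep[-removed]
    state@addedStep <- c(oldSteps, step)
    state@model <- newModel
    state@history <- rbind(state@history,
                           logRow(decision, perfNew$accuracy, precD, recD))
    state@stepCounter <- step
    list(decision = decision, state = state)
}

#' Run active training by seed selection
#'
#' Holds out a stratified monitor fraction of the training data, selects a
#' high-silhouette seed from the remaining pool, and streams the other pool
#' samples in a seeded random order through [considerSample()]. The result
#' is the final classifier together with the full run state, whose history
#' log makes every accept/replace/reject decision replayable.
#'
#' @param train labeled feature table.
#' @param capacity maximum population size; default 60% of the pool
#'   (training data minus the monitor split).
#' @param fraction seed fraction (default 0.10).
#' @param monitorFraction held-out fraction for the indicator gates
#'   (default 0.2).
#' @param orderSeed integer seed controlling the monitor split and the
#'   streaming order.
#' @param C inverse ridge strength for all fits.
#' @param indicatorGate see [considerSample()].
#' @return list with `model` (the final [ClassifierModel-class]), `state`
#'   (the final [AtssState-class]) and `seedMeanSw` (mean silhouette width
#'   of the seed population).
#' @export
runAtss <- function(train, capacity = NULL, fraction = 0.10,
                    monitorFraction = 0.2, orderSeed = 1L, C = 1,
                    indicatorGate = c("strict", "nondecreasing")) {
    indicatorGate <- match.arg(indicatorGate)
    stopifnot(monitorFraction > 0, monitorFraction < 1)
    n <- nrow(train)
    rownames(train) <- NULL
    split <- withSeed(orderSeed, {
        monIdx <- sort(unlist(lapply(sort(unique(train$label)),
            function(cl) {
                idx <- which(train$label == cl)
                sample(idx, max(1L, round(monitorFraction * length(idx))))
            })))
        list(mon = monIdx, order = sample.int(n - length(monIdx)))
    })
    monitor <- train[split$mon, , drop = FALSE]
    pool <- train[-split$mon, , drop = FALSE]
    rownames(monitor) <- rownames(pool) <- NULL
    if (min(table(pool$label)) < 2L)
        stop("training pool too small: need >= 2 samples per class")
    seeded <- selectSeed(pool, fraction = fraction, capacity = capacity,
                         monitor = monitor, C = C, returnIndices = TRUE)
    state <- seeded$state
    seedMeanSw <- mean(state@sw)
    streamOrder <- split$order[!(split$order %in% seeded$indices)]
    for (i in streamOrder) {
        res <- considerSample(state, pool[i, , drop = FALSE], C = C,
                              indicatorGate = indicatorGate)
        state <- res$state
    }
    list(model = state@model, state = state, seedMeanSw = seedMeanSw)
}
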