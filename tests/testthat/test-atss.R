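test_that("silhouette widths match hand computation and the brute-force oracle", {
    x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
    lab <- c(0, 0, 1, 1)
    s <- silhouetteWidths(x, lab)
    expect_equal(s$a[1], 0.1)
    expect_equal(s$b[1], (10 + 10.1) / 2)
    expect_equal(s$s[1], 1 - 0.1 / 10.05, tolerance = 1e-12)

    ## a = b gives zero width: point 0 has a = 2, b = mean(1, 3) = 2
    xm <- matrix(c(0, 2, 1, 3), ncol = 1)
    sm <- silhouetteWidths(xm, c(0, 0, 1, 1))
    expect_equal(sm$s[1], 0)

    ## a mislabeled point inside the opposite cluster is negative
    x6 <- matrix(c(0, 0.2, 0.1, 10, 10.2, 10.1), ncol = 1)
    s6 <- silhouetteWidths(x6, c(0, 0, 1, 1, 1, 0))
    expect_lt(s6$s[3], 0)   # labeled 1 but sits in the 0-cluster
    expect_lt(s6$s[6], 0)

    ## brute-force agreement on random instances
    set.seed(14)
    for (rep in 1:20) {
        n <- sample(6:20, 1)
        p <- sample(1:4, 1)
        xr <- matrix(rnorm(n * p), n, p)
        lr <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
        expect_equal(silhouetteWidths(xr, lr)$s, bruteSilhouette(xr, lr),
                     tolerance = 1e-10)
    }

    expect_error(silhouetteWidths(x, c(0, 1, 1, 1)), "degenerate")
})

test_that("seed selection takes the top-silhouette fraction, stratified", {
    tab <- makeToyTable(nPerClass = 100, gap = 3, seed = 15)
    st <- selectSeed(tab, fraction = 0.10)
    expect_equal(nrow(atssPopulation(st)), 20L)
    expect_setequal(unique(atssPopulation(st)$label), c(0, 1))

    tab53 <- makeToyTable(nPerClass = 30, gap = 3, seed = 16)[1:53, ]
    st53 <- selectSeed(tab53, fraction = 0.10)
    expect_equal(nrow(atssPopulation(st53)), 6L)   # ceiling(5.3)

    ## top-k property: the seed's mean width dominates the pool's
    x <- featureMatrix(tab)
    swAll <- silhouetteWidths(x, tab$label, standardize = TRUE)$s
    expect_gte(mean(st@sw), mean(swAll))

    expect_error(selectSeed(tab, fraction = 0.10, capacity = 5),
                 "configuration error")
})

test_that("the silhouette gate rejects weak candidates without retraining", {
    tab <- makeToyTable(nPerClass = 30, gap = 4, seed = 17)
    st <- selectSeed(tab[1:50, ], fraction = 0.2, monitor = tab[51:60, ])
    ## a candidate halfway between the clusters has low width
    cand <- tab[1, ]
    cand[, c("v1", "v2", "v3")] <- 2
    cand$label <- 1
    res <- considerSample(st, cand)
    expect_equal(res$decision, "rejected")
    h <- atssHistory(res$state)
    expect_true(is.na(h$acc_after[1]))   # rule 1 fired: no retraining
    expect_lt(h$s_candidate[1], h$s_min[1])
})

test_that("a redundant duplicate fails the strict indicator gate", {
    tab <- makeToyTable(nPerClass = 30, gap = 4, seed = 18)
    st <- selectSeed(tab[1:50, ], fraction = 0.2, monitor = tab[51:60, ])
    best <- atssPopulation(st)[which.max(st@sw), ]
    res <- considerSample(st, best)
    expect_equal(res$decision, "rejected")
    h <- atssHistory(res$state)
    expect_false(is.na(h$acc_after[1]))  # it passed rule 1 and retrained
    expect_equal(nrow(atssPopulation(res$state)), nrow(atssPopulation(st)))
})

test_that("a full run respects capacity and keeps monitor accuracy non-decreasing", {
    co <- generateCohort(CohortSpec(labelNoise = 0.15), seed = 21)
    res <- runAtss(co$features, orderSeed = 5)
    st <- res$state
    expect_lte(nrow(atssPopulation(st)), st@capacity)
    h <- atssHistory(st)
    commits <- h[h$decision != "rejected", ]
    if (nrow(commits) > 0) {
        expect_true(all(commits$s_candidate > commits$s_min))
        expect_true(all(commits$acc_after >= commits$acc_before))
        expect_true(all(commits$prec_delta > 0 | commits$rec_delta > 0 |
                        (is.na(commits$prec_delta) & commits$rec_delta > 0) |
                        (is.na(commits$rec_delta) & commits$prec_delta > 0)))
        expect_true(all(diff(commits$acc_after) >= -1e-12))
    }
    ## the selected population is more cohesive than the full data
    swFull <- silhouetteWidths(featureMatrix(co$features),
                               co$features$label, standardize = TRUE)$s
    expect_gt(mean(st@sw), mean(swFull))
})

test_that("at capacity, every acceptance is an exchange", {
    tab <- makeToyTable(nPerClass = 25, gap = 2.0, seed = 19)
    ## pool = 50 - 10 monitor samples; seed = ceiling(0.2 * 40) = 8
    k <- 8L
    res <- runAtss(tab, capacity = k, fraction = 0.2,
                   monitorFraction = 0.2, orderSeed = 2,
                   indicatorGate = "nondecreasing")
    h <- atssHistory(res$state)
    expect_false(any(h$decision == "accepted"))
    expect_equal(nrow(atssPopulation(res$state)), k)
})

test_that("runs are reproducible under a fixed order seed", {
    tab <- makeToyTable(nPerClass = 30, gap = 2.5, seed = 20)
    r1 <- runAtss(tab, orderSeed = 9)
    r2 <- runAtss(tab, orderSeed = 9)
    expect_equal(atssHistory(r1$state), atssHistory(r2$state))
    expect_equal(r1$model@weights, r2$model@weights)
})
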