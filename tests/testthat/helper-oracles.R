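## independent brute-force oracles, deliberately naive implementations

## O(n^2) silhouette widths by explicit loops
bruteSilhouette <- function(x, labels) {
    n <- nrow(x)
    s <- numeric(n)
    for (i in seq_len(n)) {
        dsame <- c(); dother <- c()
        for (j in seq_len(n)) {
            if (i == j) next
            d <- sqrt(sum((x[i, ] - x[j, ])^2))
            if (labels[i] == labels[j]) dsame <- c(dsame, d)
            else dother <- c(dother, d)
        }
        a <- mean(dsame); b <- mean(dother)
        s[i] <- if (a < b) 1 - a / b else if (a == b) 0 else b / a - 1
    }
    s
}

## zoom grid search minimizing log-space squared error of y = a * x^b,
## searched over (centered intercept, slope) so the axes decouple
gridPowerLaw <- function(x, y, stages = 9L, grid = 25L) {
    lx <- log(x); ly <- log(y)
    mx <- mean(lx)
    c0 <- mean(ly); b <- 0
    cW <- 12; bW <- 4
    for (s in seq_len(stages)) {
        cs <- seq(c0 - cW, c0 + cW, length.out = grid)
        bs <- seq(b - bW, b + bW, length.out = grid)
        best <- Inf
        for (i in seq_along(cs)) for (j in seq_along(bs)) {
            sse <- sum((ly - cs[i] - bs[j] * (lx - mx))^2)
            if (sse < best) { best <- sse; cBest <- cs[i]; bBest <- bs[j] }
        }
        c0 <- cBest; b <- bBest
        cW <- cW * 2.5 / (grid - 1)
        bW <- bW * 2.5 / (grid - 1)
    }
    list(a = exp(c0 - b * mx), b = b)
}

## parse the exported C header back into a prediction function
parseHeader <- function(lines) {
    grab <- function(name) {
        ln <- grep(paste0("\\b", name, "\\["), lines, value = TRUE)
        parts <- strsplit(sub(".*\\{(.*)\\}.*", "\\1", ln), ",\\s*")[[1]]
        as.numeric(sub("f$", "", parts))
    }
    scalar <- function(name) {
        ln <- grep(paste0("\\b", name, " ="), lines, value = TRUE)
        as.numeric(sub(".*= (.*)f;", "\\1", ln))
    }
    w <- grab("W"); mu <- grab("MU"); sg <- grab("SIGMA")
    b <- scalar("B")
    function(x) 1 / (1 + exp(-(sum(w * (x - mu) / sg) + b)))
}

## tiny two-cluster feature table in the package schema
makeToyTable <- function(nPerClass = 10, gap = 4, p = 3, seed = 1,
                         subjects = NULL) {
    set.seed(seed)
    x0 <- matrix(rnorm(nPerClass * p), nPerClass, p)
    x1 <- matrix(rnorm(nPerClass * p, mean = gap), nPerClass, p)
    x <- rbind(x0, x1)
    colnames(x) <- paste0("v", seq_len(p))
    if (is.null(subjects))
        subjects <- sprintf("T%02d", seq_len(2 * nPerClass))
    data.frame(subject_id = subjects,
               label = rep(c(0, 1), each = nPerClass), x)
}
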