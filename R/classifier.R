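#' Train the logistic-regression screening classifier
#'
#' Fits a ridge-regularized binary logistic regression
#' `P = 1 / (1 + exp(-h))`, `h = w . z + b`, on z-scored attributes. The
#' standardization parameters are learned on the training data and stored in
#' the model, so prediction takes raw attribute values. Regularization
#' follows the inverse-strength convention (penalty `1/(2C) * ||w||^2` on
#' the summed log-likelihood); the default `C = 1` gives a mild ridge that
#' keeps the fit well defined even on linearly separable populations such as
#' a small high-silhouette seed.
#'
#' @param table feature table (see [buildFeatures()]) with a `label` column,
#'   or a numeric matrix.
#' @param labels binary labels (1 = diabetic); taken from `table$label` when
#'   omitted.
#' @param C inverse regularization strength (> 0).
#' @param threshold probability cut for class decisions (default 0.5).
#' @param scaler optional fixed standardization, a list with `mean` and `sd`
#'   per attribute; when `NULL` (default) the scaler is learned from the
#'   training data. Active training passes the scaler fixed at seeding time.
#' @return a [ClassifierModel-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2,
#'             dimnames = list(NULL, c("a", "b")))
#' y <- as.numeric(x[, 1] + x[, 2] > 0)
#' m <- trainLogistic(x, y)
#' mean((predictProbability(m, x) > 0.5) == y)
#' @export
trainLogistic <- function(table, labels = NULL, C = 1, threshold = 0.5,
                          scaler = NULL) {
    if (is.null(labels)) labels <- table$label
    x <- if (is.matrix(table)) table else featureMatrix(table)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("x", seq_len(ncol(x)))
    n <- nrow(x)
    if (length(labels) != n) stop("labels must match the number of samples")
    if (length(unique(labels)) < 2L)
        stop("degenerate training: both classes must be present")
    stopifnot(C > 0)
    if (is.null(scaler)) scaler <- fitScaler(x)
    z <- applyScaler(x, scaler)
    lambda <- 1 / (n * C)
    ## seed-sized populations legitimately have few per-class samples;
    ## the ridge penalty keeps those fits well defined
    fit <- suppressWarnings(
        glmnet::glmnet(z, labels, family = "binomial", alpha = 0,
                       lambda = c(100, 10, 1) * lambda,
                       standardize = FALSE))
    cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
    new("ClassifierModel",
        attributeNames = colnames(x),
        weights = cf[-1L],
        bias = cf[1L],
        scalerMean = as.numeric(scaler$mean),
        scalerSd = as.numeric(scaler$sd),
        solverTag = "glmnet-ridge",
        threshold = as.numeric(threshold))
}

## align an input (vector, one-row df, matrix or feature table) to the
## model's attribute order; schema mismatches are errors
.alignAttributes <- function(model, x) {
    if (is.data.frame(x)) x <- featureMatrix(x)
    if (is.null(dim(x))) {
        x <- matrix(x, nrow = 1L,
                    dimnames = list(NULL, names(x)))
    }
    nms <- colnames(x)
    if (is.null(nms)) {
        if (ncol(x) != length(model@attributeNames))
            stop("schema error: expected ", length(model@attributeNames),
                 " attributes, got ", ncol(x))
        return(x)
    }
    idx <- match(model@attributeNames, nms)
    if (anyNA(idx))
        stop("schema error: missing attribute(s) ",
             paste(model@attributeNames[is.na(idx)], collapse = ", "))
    x[, idx, drop = FALSE]
}

#' Predicted probability of the positive (diabetic) class
#'
#' @param model a fitted [ClassifierModel-class].
#' @param x a feature table, matrix, or single named vector of raw attribute
#'   values; attributes are matched by name to the model's order.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictProbability <- function(model, x) {
    stopifnot(is(model, "ClassifierModel"))
    xm <- .alignAttributes(model, x)
    z <- applyScaler(xm, list(mean = model@scalerMean, sd = model@scalerSd))
    h <- drop(z %*% model@weights) + model@bias
    1 / (1 + exp(-h))
}

#' Class decision at the model threshold
#'
#' @inheritParams predictProbability
#' @return numeric vector of 0/1 labels (1 = diabetic).
#' @export
predictClass <- function(model, x) {
    as.numeric(predictProbability(model, x) >= model@threshold)
}

#' Serialize a classifier to portable JSON
#'
#' @param model a [ClassifierModel-class].
#' @param path file to write; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
saveModelJson <- function(model, path = NULL) {
    stopifnot(is(model, "ClassifierModel"))
    obj <- list(attribute_names = model@attributeNames,
                weights = model@weights,
                bias = model@bias,
                scaler = list(means = model@scalerMean,
                              sds = model@scalerSd),
                solver_tag = model@solverTag,
                threshold = model@threshold,
                sex_coding = "0=female,1=male")
    js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' @param path JSON file written by [saveModelJson()] (or its literal text).
#' @rdname saveModelJson
#' @export
loadModelJson <- function(path) {
    obj <- jsonlite::fromJSON(path)
    new("ClassifierModel",
        attributeNames = obj$attribute_names,
        weights = as.numeric(obj$weights),
        bias = as.numeric(obj$bias),
        scalerMean = as.numeric(obj$scaler$means),
        scalerSd = as.numeric(obj$scaler$sds),
        solverTag = obj$solver_tag,
        threshold = as.numeric(obj$threshold))
}

#' Export a classifier as a C header for microcontrollers
#'
#' Emits constant arrays (`W`, `B`, `MU`, `SIGMA`, `N_FEATURES`) from which
#' the device firmware reproduces `predictProbability()`:
#' `h = sum_i W[i] * (x[i] - MU[i]) / SIGMA[i] + B`, `P = 1/(1+exp(-h))`.
#' Constants are printed with 9 significant digits, which preserves float32
#' precision.
#'
#' @param model a fitted [ClassifierModel-class].
#' @param path file to write; when `NULL` the header text is returned.
#' @return header text (character vector of lines), invisibly when written.
#' @export
exportHeader <- function(model, path = NULL) {
    stopifnot(is(model, "ClassifierModel"))
    validObject(model)
    fmt <- function(v) paste0(sprintf("%.9gf", v), collapse = ", ")
    p <- length(model@weights)
    lines <- c(
        "#ifndef IMPEDSCREEN_MODEL_H",
        "#define IMPEDSCREEN_MODEL_H",
        "",
        sprintf("/* attribute order: %s */",
                paste(model@attributeNames, collapse = ", ")),
        "/* sex coding: 0 = female, 1 = male */",
        sprintf("#define N_FEATURES %d", p),
        sprintf("static const float W[N_FEATURES] = {%s};",
                fmt(model@weights)),
        sprintf("static const float B = %.9gf;", model@bias),
        sprintf("static const float MU[N_FEATURES] = {%s};",
                fmt(model@scalerMean)),
        sprintf("static const float SIGMA[N_FEATURES] = {%s};",
                fmt(model@scalerSd)),
        sprintf("static const float THRESHOLD = %.9gf;", model@threshold),
        "",
        "#endif")
    if (is.null(path)) return(lines)
    writeLines(lines, path)
    invisible(lines)
}
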