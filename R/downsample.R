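# Downsampling-reliability statistics: extraction-fraction regression,
# back-calculation of full-extraction matched counts, relative error, and
# the exponential error-decay model with its inversion to read-count
# thresholds.

#' Build extraction observations from matched-count data
#'
#' Matched counts at reduced extraction fractions are expressed as
#' percentages of the matched count obtained at 100% extraction for the
#' same (probe, file). Observations whose 100% reference count is zero are
#' excluded (the proportion is undefined).
#'
#' @param data data.frame with columns `probe`, `file`, `extraction_pct`
#'   and `matched`; rows with extraction_pct == 100 provide the references.
#' @return data.frame with columns `probe`, `file`, `x` (extraction
#'   fraction, percent), `c_x`, `c_100` and `y` = 100 * c_x / c_100.
#' @export
extractionObservations <- function(data) {
    need <- c("probe", "file", "extraction_pct", "matched")
    if (!all(need %in% names(data)))
        stop("data must have columns probe, file, extraction_pct, matched",
            call. = FALSE)
    ref <- data[data$extraction_pct == 100, c("probe", "file", "matched")]
    names(ref)[3] <- "c_100"
    obs <- data[data$extraction_pct < 100, , drop = FALSE]
    m <- merge(obs, ref, by = c("probe", "file"))
    m <- m[m$c_100 > 0, , drop = FALSE]
    out <- data.frame(probe = m$probe, file = m$file,
        x = as.numeric(m$extraction_pct), c_x = m$matched, c_100 = m$c_100,
        y = 100 * m$matched / m$c_100, stringsAsFactors = FALSE)
    out[order(out$probe, out$file, out$x), , drop = FALSE]
}

#' Fit the extraction-fraction linear model
#'
#' Ordinary least squares of the detected proportion y (percent of the
#' 100%-extraction matched count) on the extraction fraction x (percent),
#' pooling all (probe, file) observations unweighted.
#'
#' @param observations data.frame with columns `x` and `y` (e.g. from
#'   [extractionObservations()]).
#' @return an [ExtractionModel-class].
#' @examples
#' fitExtractionModel(data.frame(x = c(1, 10, 25, 50), y = c(1, 10, 25, 50)))
#' @export
fitExtractionModel <- function(observations) {
    x <- observations$x; y <- observations$y
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2L)
        stop("need at least 2 observations", call. = FALSE)
    if (length(unique(x)) < 2L)
        stop("all extraction fractions identical; slope is undetermined",
            call. = FALSE)
    fit <- stats::lm(y ~ x)
    new("ExtractionModel", slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]), n = length(x))
}

setMethod("show", "ExtractionModel", function(object) {
    cat(sprintf("ExtractionModel: y = %.4g x %s %.4g  (n = %d)\n",
        object@slope, if (object@intercept < 0) "-" else "+",
        abs(object@intercept), object@n))
})

#' Back-calculate the 100%-extraction matched count
#'
#' Inverts the extraction model: given a count observed at extraction
#' fraction x, the full-extraction estimate is
#' 100 * c_obs / (slope * x + intercept).
#'
#' @param c_obs matched count observed at extraction fraction `x`.
#' @param x extraction fraction in percent.
#' @param model an [ExtractionModel-class].
#' @return estimated matched count at 100% extraction.
#' @examples
#' backCalculate(500, 50, new("ExtractionModel", slope = 1, intercept = 0,
#'     n = 0L))  # 1000
#' @export
backCalculate <- function(c_obs, x, model) {
    stopifnot(is(model, "ExtractionModel"))
    pred <- model@slope * x + model@intercept
    if (any(pred <= 0))
        stop(sprintf(
            "predicted detected proportion is non-positive (%.4g) at x = %g",
            min(pred), x[which.min(pred)]), call. = FALSE)
    100 * c_obs / pred
}

#' Relative error of a back-calculated estimate
#'
#' @param estimate back-calculated matched count.
#' @param actual actual matched count at 100% extraction (> 0).
#' @return 100 * |estimate - actual| / actual, in percent.
#' @export
relativeError <- function(estimate, actual) {
    if (any(actual <= 0))
        stop("actual matched count must be positive", call. = FALSE)
    100 * abs(estimate - actual) / actual
}

#' Construct an error-decay model from known coefficients
#'
#' @param A amplitude (percent); predicted relative error at m = 1.
#' @param B decay rate per decade of matched reads.
#' @return an [ErrorDecayModel-class] for err(m) = A * exp(-B * log10(m)).
#' @export
ErrorDecayModel <- function(A, B) {
    new("ErrorDecayModel", A = as.numeric(A), B = as.numeric(B), n = 0L)
}

setMethod("show", "ErrorDecayModel", function(object) {
    cat(sprintf("ErrorDecayModel: err(m) = %.4g * exp(-%.4g * log10(m))%s\n",
        object@A, object@B,
        if (object@n > 0L) sprintf("  (n = %d)", object@n) else ""))
})

#' Predict relative error from matched-read abundance
#'
#' @param model an [ErrorDecayModel-class].
#' @param m matched read count(s) at 100% extraction.
#' @return predicted relative error(s) in percent.
#' @export
predictErrorDecay <- function(model, m) {
    stopifnot(is(model, "ErrorDecayModel"))
    model@A * exp(-model@B * log10(m))
}

#' Fit the relative-error decay model
#'
#' Linearises err(m) = A * exp(-B * log10(m)) as
#' ln(err) = ln(A) - B * log10(m) and fits by least squares; A is the
#' exponential of the intercept and B the negated slope.
#'
#' @param m matched read counts at 100% extraction (> 0).
#' @param err relative errors in percent (> 0).
#' @return an [ErrorDecayModel-class].
#' @export
fitErrorDecay <- function(m, err) {
    keep <- is.finite(m) & is.finite(err) & m > 0 & err > 0
    m <- m[keep]; err <- err[keep]
    if (length(m) < 2L)
        stop("need at least 2 points with m > 0 and err > 0", call. = FALSE)
    lx <- log10(m)
    if (length(unique(lx)) < 2L)
        stop("all abundances identical; decay rate is undetermined",
            call. = FALSE)
    fit <- stats::lm(log(err) ~ lx)
    new("ErrorDecayModel", A = exp(unname(stats::coef(fit)[1])),
        B = -unname(stats::coef(fit)[2]), n = length(m))
}

#' Invert an error-decay model to a matched-read threshold
#'
#' Solves err(m) = err_threshold for m: m = 10^(ln(A / err_threshold) / B),
#' rounded to the nearest integer. This converts a tolerated relative error
#' into the matched-read abundance above which back-calculation is expected
#' to stay within it.
#'
#' @param model an [ErrorDecayModel-class].
#' @param errThreshold tolerated relative error in percent, in (0, A].
#' @return matched-read threshold, nearest integer.
#' @examples
#' invertErrorDecay(ErrorDecayModel(99.44, 1.527), 5)  # 91
#' @export
invertErrorDecay <- function(model, errThreshold) {
    stopifnot(is(model, "ErrorDecayModel"))
    if (any(errThreshold <= 0))
        stop("errThreshold must be positive", call. = FALSE)
    if (any(errThreshold > model@A))
        stop(sprintf(
            "errThreshold (%g) exceeds the model amplitude A = %g; the model never predicts errors that large at m >= 1",
            max(errThreshold), model@A), call. = FALSE)
    round(10^(log(model@A / errThreshold) / model@B))
}

#' Downsampling reliability analysis over a matched-count table
#'
#' Runs the full back-calculation workflow: build extraction observations,
#' fit the pooled extraction-fraction regression, back-calculate
#' 100%-equivalent counts for every observation, compute relative errors,
#' fit one error-decay model per extraction fraction, and invert each model
#' at the requested relative-error thresholds.
#'
#' @param data data.frame with columns `probe`, `file`, `extraction_pct`,
#'   `matched` (rows at extraction_pct == 100 are the references).
#' @param errThresholds relative-error thresholds (percent) for the
#'   threshold table.
#' @return a list with `observations`, `model` ([ExtractionModel-class]),
#'   `backcalc` (observations plus `estimate` and `rel_error`),
#'   `decayModels` (named list of [ErrorDecayModel-class] per extraction
#'   fraction), and `thresholds` (data.frame: rows = error thresholds,
#'   columns = extraction fractions, cells = matched-read thresholds).
#' @export
downsampleStats <- function(data, errThresholds = c(1, 5, 10, 20)) {
    obs <- extractionObservations(data)
    model <- fitExtractionModel(obs)
    obs$estimate <- backCalculate(obs$c_x, obs$x, model)
    obs$rel_error <- relativeError(obs$estimate, obs$c_100)
    fracs <- sort(unique(obs$x))
    decayModels <- list()
    for (f in fracs) {
        sub <- obs[obs$x == f, , drop = FALSE]
        dm <- tryCatch(fitErrorDecay(sub$c_100, sub$rel_error),
            error = function(e) NULL)
        if (!is.null(dm)) decayModels[[as.character(f)]] <- dm
    }
    thr <- matrix(NA_real_, nrow = length(errThresholds),
        ncol = length(decayModels),
        dimnames = list(paste0(errThresholds, "%"), names(decayModels)))
    for (j in seq_along(decayModels)) for (i in seq_along(errThresholds)) {
        thr[i, j] <- tryCatch(
            invertErrorDecay(decayModels[[j]], errThresholds[i]),
            error = function(e) NA_real_)
    }
    list(observations = obs[, c("probe", "file", "x", "c_x", "c_100", "y")],
        model = model, backcalc = obs, decayModels = decayModels,
        thresholds = as.data.frame(thr))
}
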