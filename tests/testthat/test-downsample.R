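# Extraction-fraction regression, back-calculation, relative error, and
# the error-decay model with its inversion.

test_that("the extraction fit recovers exact and noisy linear relationships", {
    # perfect proportionality
    m <- fitExtractionModel(data.frame(x = c(1, 10, 25, 50),
        y = c(1, 10, 25, 50)))
    expect_equal(m@slope, 1)
    expect_equal(m@intercept, 0)
    # two points: the fit is the closed-form two-point line
    m2 <- fitExtractionModel(data.frame(x = c(10, 50), y = c(12, 48)))
    expect_equal(m2@slope, (48 - 12) / (50 - 10))
    expect_equal(m2@intercept, 12 - m2@slope * 10)
    # parameter recovery under Gaussian noise, checked against the
    # closed-form OLS solution as an independent oracle
    set.seed(91)
    x <- rep(c(1, 10, 25, 50), 50)
    y <- 1.004 * x - 0.557 + rnorm(200, sd = 0.5)
    m3 <- fitExtractionModel(data.frame(x = x, y = y))
    expect_equal(m3@slope, 1.004, tolerance = 0.01)
    expect_equal(m3@intercept, -0.557, tolerance = 0.3 / abs(-0.557))
    slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(m3@slope, slope_oracle)
    expect_equal(m3@intercept, mean(y) - slope_oracle * mean(x))
    # degenerate designs are rejected
    expect_error(fitExtractionModel(data.frame(x = c(10, 10), y = c(1, 2))),
        "identical")
    expect_error(fitExtractionModel(data.frame(x = 10, y = 1)), "at least 2")
})

test_that("back-calculation inverts the extraction model", {
    ident <- new("ExtractionModel", slope = 1, intercept = 0, n = 0L)
    expect_equal(backCalculate(500, 50, ident), 1000)
    expect_equal(backCalculate(7, 100, ident), 7)
    fitted <- new("ExtractionModel", slope = 1.004, intercept = -0.5570,
        n = 0L)
    expect_equal(backCalculate(500, 50, fitted), 100 * 500 / 49.643)
    neg <- new("ExtractionModel", slope = 1, intercept = -10, n = 0L)
    expect_error(backCalculate(5, 5, neg), "non-positive")
})

test_that("relative error is the absolute percent deviation", {
    expect_equal(relativeError(1000, 1000), 0)
    expect_equal(relativeError(1100, 1000), 10)
    expect_equal(relativeError(900, 1000), 10)
    expect_error(relativeError(1, 0), "positive")
})

test_that("the error-decay fit linearises exactly and recovers noisy parameters", {
    m <- c(10, 100, 1000)
    err <- 100 * exp(-1.5 * log10(m))
    fit <- fitErrorDecay(m, err)
    expect_equal(fit@A, 100)
    expect_equal(fit@B, 1.5)
    expect_equal(predictErrorDecay(fit, 1), fit@A) # log10(1) = 0
    set.seed(93)
    m2 <- 10^runif(100, 0.5, 5)
    err2 <- 120 * exp(-1.2 * log10(m2)) * exp(rnorm(100, sd = 0.1))
    fit2 <- fitErrorDecay(m2, err2)
    expect_equal(fit2@A, 120, tolerance = 0.05)
    expect_equal(fit2@B, 1.2, tolerance = 0.05)
    expect_error(fitErrorDecay(c(10, 10), c(5, 6)), "identical")
})

test_that("inverting the decay model returns the matched-read threshold", {
    expect_equal(invertErrorDecay(ErrorDecayModel(99.44, 1.527), 5), 91)
    expect_equal(invertErrorDecay(ErrorDecayModel(124.7, 1.023), 5), 1394)
    expect_equal(invertErrorDecay(ErrorDecayModel(190.4, 0.8609), 10), 2646)
    expect_equal(invertErrorDecay(ErrorDecayModel(190.4, 0.8609), 20), 414)
    # err = A corresponds to m = 1
    expect_equal(invertErrorDecay(ErrorDecayModel(77.7, 2.2), 77.7), 1)
    expect_error(invertErrorDecay(ErrorDecayModel(50, 1), 60), "exceeds")
    # round trip: err(m_inv) == threshold up to the integer rounding of m
    set.seed(95)
    for (i in 1:20) {
        mod <- ErrorDecayModel(runif(1, 50, 200), runif(1, 0.5, 2))
        thr <- runif(1, 1, mod@A)
        m_inv <- invertErrorDecay(mod, thr)
        m_exact <- 10^(log(mod@A / thr) / mod@B)
        expect_equal(m_inv, round(m_exact))
        expect_equal(predictErrorDecay(mod, m_exact), thr)
    }
})

test_that("hypergeometric downsampling round-trips through the full analysis", {
    # simulate exact subsampling without replacement: matched counts at
    # extraction x% are hypergeometric draws from c_100 positives among N
    set.seed(97)
    N <- 100000L
    c100 <- c(50L, 200L, 1000L, 5000L, 20000L)
    fracs <- c(1, 10, 25, 50)
    rows <- list()
    for (p in seq_along(c100)) {
        rows[[length(rows) + 1L]] <- data.frame(probe = paste0("p", p),
            file = "f", extraction_pct = 100, matched = c100[p])
        for (x in fracs) for (rep in 1:3) {
            draw <- stats::rhyper(1, c100[p], N - c100[p], round(N * x / 100))
            rows[[length(rows) + 1L]] <- data.frame(probe = paste0("p", p),
                file = sprintf("f_rep%d", rep), extraction_pct = x,
                matched = draw)
        }
    }
    data <- do.call(rbind, rows)
    # references are per (probe, file); replicate rows need their own ref
    refs <- data[data$extraction_pct == 100, ]
    for (rep in 1:3) {
        r2 <- refs; r2$file <- sprintf("f_rep%d", rep)
        data <- rbind(data, r2)
    }
    res <- downsampleStats(data)
    expect_equal(res$model@slope, 1, tolerance = 0.05)
    expect_lt(abs(res$model@intercept), 1)
    # back-calculation error decreases with abundance at every fraction
    bc <- res$backcalc
    for (x in fracs) {
        sub <- bc[bc$x == x, ]
        mean_err <- tapply(sub$rel_error, sub$c_100, mean)
        expect_lt(mean_err[[length(mean_err)]], mean_err[[1]])
    }
    # fitted decay models invert to finite thresholds
    expect_true(length(res$decayModels) >= 3L)
    thr <- res$thresholds
    expect_true(all(is.na(as.matrix(thr)) | as.matrix(thr) >= 1))
})

test_that("observations with a zero full-extraction reference are excluded", {
    data <- data.frame(
        probe = c("a", "a", "b", "b"),
        file = "f",
        extraction_pct = c(100, 50, 100, 50),
        matched = c(0L, 0L, 100L, 49L))
    obs <- extractionObservations(data)
    expect_equal(obs$probe, "b")
    expect_equal(obs$y, 49)
})
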