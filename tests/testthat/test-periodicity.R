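tt <- designTimes()

test_that("turning-point extraction honours exact zeros and midpoints", {
    grid <- c(1, 2, 3, 4, 5)
    # exact zero at a grid point
    expect_equal(lrclock:::.turningPoints(grid, c(1, 0.5, 0, -0.5, -1)), 3)
    # sign change between grid points -> midpoint
    expect_equal(lrclock:::.turningPoints(grid, c(1, 0.2, -0.2, -1, -2)),
                 2.5)
    # monotone derivative -> none
    expect_equal(length(lrclock:::.turningPoints(grid, c(1, 2, 3, 4, 5))),
                 0)
    # both kinds together
    expect_equal(lrclock:::.turningPoints(grid, c(-1, 0, 1, -1, -2)),
                 c(2, 3.5))
})

test_that("a 24-h cosine is recovered with interior extrema near 18/30/42", {
    est <- estimatePeriod(cos(2 * pi * (tt - 6) / 24), tt)
    expect_lt(abs(periodHours(est) - 24), 0.5)
    tp <- turningPoints(est)
    for (target in c(18, 30, 42))
        expect_lt(min(abs(tp - target)), 0.5)
})

test_that("noiseless periods across the circadian band are on-grid exact", {
    for (P in c(20, 24, 28, 32)) {
        est <- estimatePeriod(cos(2 * pi * (tt - 6) / P), tt)
        expect_lt(abs(periodHours(est) - P), 1.0)
    }
})

test_that("trend profiles yield undefined periods", {
    mono <- estimatePeriod(generateProfile("monotone", tt), tt)
    expect_equal(length(turningPoints(mono)), 0)
    expect_true(is.na(periodHours(mono)))
    imp <- estimatePeriod(
        generateProfile("impulse", tt, phase = 30, width = 8), tt)
    expect_equal(length(turningPoints(imp)), 1)
    expect_true(is.na(periodHours(imp)))
    expect_error(estimatePeriod(rep(1, 18), tt),
                 class = "degenerateProfileError")
})

test_that("period estimation is shift-equivariant and reflection-invariant", {
    y <- cos(2 * pi * (tt - 6) / 24)
    base <- estimatePeriod(y, tt)
    shifted <- estimatePeriod(y, tt + 100)
    expect_equal(turningPoints(shifted), turningPoints(base) + 100,
                 tolerance = 1e-9)
    expect_equal(periodHours(shifted), periodHours(base))
    neg <- estimatePeriod(-y, tt)
    expect_equal(turningPoints(neg), turningPoints(base))
    expect_equal(periodHours(neg), periodHours(base))
})

test_that("the oscillatory-cluster rule keeps oscillators and drops trends", {
    means <- rbind(
        osc = normalizeProfile(cos(2 * pi * (tt - 3) / 24)),
        mono = normalizeProfile(generateProfile("monotone", tt)),
        imp = normalizeProfile(generateProfile("impulse", tt, phase = 30)),
        flat = rep(0, length(tt)))
    cls <- classifyOscillatory(means, tt)
    expect_equal(unname(cls$oscillatory), c(TRUE, FALSE, FALSE, FALSE))
    expect_lt(abs(cls$period[1] - 24), 1)
    expect_gte(cls$nTurningPoints[1], 4)
})

test_that("PCA time scores are orthogonal, variance-ordered and expose a
           planted oscillation", {
    x <- simulateTimeCourse(
        nGenes = 600, noiseSd = 0.2,
        classes = list(classSpec("oscillatory", 0.4, period = 24, phase = 6),
                       classSpec("flat", 0.6)),
        seed = 61)
    qc <- pcaTimeScores(x, nComponents = 4)
    cross <- crossprod(qc$scores)
    offdiag <- cross - diag(diag(cross))
    expect_lt(max(abs(offdiag)), 1e-6 * max(diag(cross)))
    expect_true(all(diff(qc$varianceExplained) <= 1e-12))
    periods <- vapply(qc$periods, function(e)
        if (is.null(e)) NA_real_ else periodHours(e), numeric(1))
    expect_true(any(abs(periods - 24) < 1, na.rm = TRUE))
    expect_error(pcaTimeScores(x, nComponents = 30), "components")
})
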