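tt <- designTimes()

test_that("straight-line data lie in the penalty null space", {
    y <- 2 + 0.5 * tt
    for (spar in c(0.1, 0.4, 1)) {
        fit <- fitSmoothingSpline(tt, y, spar = spar)
        expect_equal(splineValues(fit, tt), y, tolerance = 1e-8)
    }
})

test_that("lambda limits reach interpolation and the least-squares line", {
    set.seed(21)
    for (rep in 1:5) {
        y <- rnorm(18)
        interp <- fitSmoothingSpline(tt, y, lambda = 1e-12)
        expect_lt(max(abs(splineValues(interp, tt) - y)), 1e-6)

        line <- fitSmoothingSpline(tt, y, lambda = 1e5)
        ols <- unname(coef(lm(y ~ tt)))
        f01 <- splineValues(line, c(0, 1))
        expect_lt(abs(f01[1] - ols[1]), 1e-4)            # intercept
        expect_lt(abs((f01[2] - f01[1]) - ols[2]), 1e-4) # slope
    }
})

test_that("the fit is linear in the data (affine equivariance)", {
    set.seed(22)
    y <- rnorm(18)
    base <- splineValues(fitSmoothingSpline(tt, y, spar = 0.4), tt)
    shifted <- splineValues(
        fitSmoothingSpline(tt, 3 * y - 2, spar = 0.4), tt)
    expect_equal(shifted, 3 * base - 2, tolerance = 1e-8)
})

test_that("the derivative evaluator matches finite differences", {
    set.seed(23)
    y <- cos(2 * pi * tt / 24) + rnorm(18, 0, 0.1)
    fit <- fitSmoothingSpline(tt, y, spar = 0.3)
    xs <- seq(10, 50, by = 2.5)
    h <- 1e-4
    fd <- (splineValues(fit, xs + h) - splineValues(fit, xs - h)) / (2 * h)
    an <- splineValues(fit, xs, deriv = 1)
    expect_lt(max(abs(an - fd) / pmax(abs(fd), 1e-6)), 1e-5)
})

test_that("input validation refuses bad designs and extrapolation", {
    expect_error(fitSmoothingSpline(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
    expect_error(fitSmoothingSpline(c(1, 2, 2, 3), 1:4), "duplicate")
    expect_error(fitSmoothingSpline(tt, rnorm(18), spar = 1.5), "spar")
    fit <- fitSmoothingSpline(tt, rnorm(18))
    expect_error(splineValues(fit, 60), "outside the observed range")
})

test_that("profile standardization is exact, idempotent and guarded", {
    z <- normalizeProfile(c(1, 2, 3))
    expect_equal(mean(z), 0)
    expect_equal(var(z), 1)
    expect_equal(normalizeProfile(z), z)
    expect_error(normalizeProfile(rep(2, 5)),
                 class = "degenerateProfileError")
    err <- tryCatch(normalizeProfile(rep(1, 4)), error = identity)
    expect_true(isDegenerateProfileError(err))
    # population divisor gives variance 1 under the n convention
    zp <- normalizeProfile(c(1, 2, 3), divisor = "population")
    expect_equal(sum(zp^2) / 3, 1)
})

test_that("bulk smoothing via the equivalent kernel matches per-gene fits
           and standardization holds for thousands of genes", {
    set.seed(24)
    m <- matrix(rnorm(50 * 18), 50, 18)
    rownames(m) <- sprintf("g%02d", 1:50)
    bulk <- normalizedSplineProfiles(m, times = tt, spar = 0.4)
    for (g in c(1, 17, 50)) {
        fit <- splineValues(fitSmoothingSpline(tt, m[g, ], spar = 0.4), tt)
        expect_equal(unname(bulk$profiles[g, ]), normalizeProfile(fit),
                     tolerance = 1e-9)
    }
    big <- matrix(rnorm(10000 * 18), 10000, 18)
    np <- normalizedSplineProfiles(big, times = tt)$profiles
    expect_lt(max(abs(rowMeans(np))), 1e-9)
    expect_lt(max(abs(apply(np, 1, var) - 1)), 1e-9)
})

test_that("degenerate genes are excluded and reported", {
    m <- rbind(a = rnorm(18), b = rep(3, 18))
    out <- normalizedSplineProfiles(m, times = tt)
    expect_equal(rownames(out$profiles), "a")
    expect_equal(out$degenerate, "b")
})
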