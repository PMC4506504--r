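tt <- designTimes()

test_that("small exact Kendall nulls match hand enumeration", {
    n2 <- exactKendallNull(2)
    expect_equal(n2$S, c(1, -1))
    expect_equal(n2$prob, c(0.5, 0.5))
    n3 <- exactKendallNull(3)
    expect_equal(n3$S, c(3, 1, -1, -3))
    expect_equal(n3$prob, c(1, 2, 2, 1) / 6)
    expect_error(exactKendallNull(1), "\\[2, 30\\]")
    expect_error(exactKendallNull(31), "\\[2, 30\\]")
})

test_that("the n = 8 null equals the full 8! enumeration", {
    got <- exactKendallNull(8)
    oracle <- enumerateKendallNull(8)
    oracle <- oracle[order(-oracle$S), ]
    expect_equal(got$S, oracle$S)
    expect_equal(got$prob, oracle$prob)
    expect_equal(sum(got$prob), 1)
})

test_that("cosine templates collapse duplicates and span the phase grid", {
    tg <- cosineTemplates(tt, periods = 20:28)
    expect_false(any(duplicated(tg$ranks)))
    expect_equal(length(tg$period), nrow(tg$ranks))
    expect_true(all(tg$period %in% 20:28))
    expect_true(all(tg$phase %% 3 == 0))
})

test_that("a noiseless 24-h cosine is matched perfectly", {
    y <- matrix(cos(2 * pi * (tt - 6) / 24), 1)
    rownames(y) <- "osc"
    res <- jtkScreen(y, times = tt, seed = 2)
    expect_equal(res$bestPeriod, 24)
    expect_equal(res$bestPhase, 6)
    expect_equal(res$tau, 1)
    expect_lt(res$p, 0.01)
})

test_that("constant series carry no rhythmic signal", {
    y <- matrix(rep(c(5, 1), each = 18), 2, byrow = TRUE)
    y[2, ] <- rnorm(18)
    res <- jtkScreen(y, times = tt, seed = 2)
    expect_gte(res$p[1], 0.99)
    expect_equal(res$tau[1], 0)
    expect_false(res$rhythmic[1])
})

test_that("negating a series shifts its phase by half a period and
           preserves the p-value", {
    set.seed(9)
    y <- cos(2 * pi * (tt - 6) / 24) + rnorm(18, 0, 0.2)
    m <- rbind(plus = y, minus = -y)
    # period 24 only: its half-period (12 h) lies on the 3-h phase grid,
    # so the template set is closed under negation
    res <- jtkScreen(m, times = tt, periods = 24, seed = 3)
    expect_equal(res$p[1], res$p[2])
    shift <- (res$bestPhase[2] - res$bestPhase[1]) %% res$bestPeriod[1]
    expect_equal(shift, res$bestPeriod[1] / 2)
})

test_that("gene-level p-values behave sensibly under both corrections", {
    set.seed(77)
    m <- matrix(rnorm(50 * 18), 50, 18)
    perm <- jtkScreen(m, times = tt, pMethod = "permutation", seed = 4)
    bonf <- jtkScreen(m, times = tt, pMethod = "bonferroni")
    expect_true(all(perm$p > 0 & perm$p <= 1))
    expect_true(all(bonf$p > 0 & bonf$p <= 1))
    expect_true(all(perm$q >= perm$p))
    expect_true(all(bonf$q >= bonf$p))
    # same template maximises S either way
    expect_equal(perm$bestPeriod, bonf$bestPeriod)
    # permutation p is reproducible under the seed
    perm2 <- jtkScreen(m, times = tt, pMethod = "permutation", seed = 4)
    expect_identical(perm$p, perm2$p)
})
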