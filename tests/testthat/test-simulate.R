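tt <- designTimes()

test_that("profile primitives have the stated shapes", {
    p <- generateProfile("oscillatory", tt, period = 24, phase = 6)
    expect_equal(p[tt == 6], 1)      # cos(0) at the peak
    expect_equal(p[tt == 18], -1)    # half a period later
    expect_equal(generateProfile("flat", tt), rep(0, length(tt)))
    mono <- generateProfile("monotone", tt, amplitude = 2)
    expect_equal(unname(mono[c(1, length(tt))]), c(-2, 2))
    expect_true(all(diff(mono) > 0))
    imp <- generateProfile("impulse", tt, phase = 30, amplitude = 1.5)
    expect_equal(max(imp), 1.5)
    expect_equal(tt[which.max(imp)], 30)
    expect_error(generateProfile("sawtooth", tt), "unknown profile class")
    expect_error(generateProfile("oscillatory", tt, period = -2), "period")
})

test_that("simulation is reproducible and honours the configuration", {
    a <- simulateTimeCourse(nGenes = 150, seed = 42)
    b <- simulateTimeCourse(nGenes = 150, seed = 42)
    expect_identical(intensities(a), intensities(b))
    expect_identical(as.data.frame(syntheticTruth(a)),
                     as.data.frame(syntheticTruth(b)))
    c <- simulateTimeCourse(nGenes = 150, seed = 43)
    expect_false(identical(intensities(a), intensities(c)))

    x <- simulateTimeCourse(nGenes = 1000, tfFraction = 0.1, seed = 7)
    expect_equal(sum(isTF(x)), 100)
    cnt <- table(syntheticTruth(x)$classKind)
    expect_equal(as.vector(cnt[c("oscillatory", "monotone", "impulse",
                                 "flat")]), c(400, 150, 150, 300))
    expect_equal(timePoints(x), tt)
    expect_equal(nReplicates(x), 4L)
})

test_that("invalid configurations are refused", {
    expect_error(simulateTimeCourse(nGenes = 2), "number of classes")
    expect_error(simulateTimeCourse(nGenes = 10, nReplicates = 1),
                 "replicates")
    expect_error(simulateTimeCourse(nGenes = 10, noiseSd = -1), "noiseSd")
    expect_error(simulateTimeCourse(
        nGenes = 10,
        classes = list(classSpec("flat", 0.5), classSpec("monotone", 0.2))),
        "sum to 1")
})

test_that("noiseless planted oscillators carry their true period", {
    x <- simulateTimeCourse(
        nGenes = 4, noiseSd = 0, baselineLogSd = 0,
        classes = list(classSpec("oscillatory", 1, period = 24, phase = 6)),
        seed = 3)
    prof <- replicateMeans(x, log = TRUE)
    for (g in seq_len(nrow(prof))) {
        est <- estimatePeriod(prof[g, ], tt)
        expect_lt(abs(periodHours(est) - 24), 0.5)
    }
    expect_true(all(syntheticTruth(x)$truePeriod == 24))
})

test_that("flat-gene intensities are lognormal with the configured scale", {
    x <- simulateTimeCourse(nGenes = 10000, noiseSd = 0.25,
                            baselineLogMean = 8, baselineLogSd = 2,
                            classes = list(classSpec("flat", 1)),
                            seed = 11)
    vals <- intensities(x)[, 1L]     # one observation per gene
    ks <- suppressWarnings(stats::ks.test(
        vals, "plnorm", meanlog = 8 * log(2),
        sdlog = sqrt(2^2 + 0.25^2) * log(2)))
    expect_gt(ks$p.value, 0.001)
})
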