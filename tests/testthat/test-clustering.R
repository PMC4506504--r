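tt <- designTimes()

# well-separated standardized class profiles for recovery checks
classProfiles <- function() {
    shapes <- rbind(
        cos(2 * pi * (tt - 0) / 24),
        cos(2 * pi * (tt - 6) / 24),
        cos(2 * pi * (tt - 12) / 24),
        cos(2 * pi * (tt - 18) / 24),
        2 * (tt - min(tt)) / diff(range(tt)) - 1,
        exp(-(tt - 30)^2 / (2 * 4.5^2)))
    t(apply(shapes, 1, normalizeProfile))
}

plantedProfiles <- function(n, classes, noiseSd, seed) {
    shapes <- classProfiles()[classes, , drop = FALSE]
    cls <- rep(seq_along(classes), each = n)
    set.seed(seed)
    raw <- shapes[cls, ] + matrix(rnorm(length(cls) * length(tt), 0,
                                        noiseSd), ncol = length(tt))
    prof <- normalizedSplineProfiles(raw, times = tt)$profiles
    rownames(prof) <- sprintf("g%04d", seq_len(nrow(prof)))
    list(profiles = prof, classes = cls)
}

test_that("ward cuts at the extremes give singletons and the global mean", {
    p <- rbind(c(0, 0), c(0, 0), c(1, 1), c(5, 5), c(5, 5))
    atZero <- wardCut(p, h = 0)
    expect_equal(nrow(atZero$centres), 3)           # one per distinct row
    high <- wardCut(p, h = 1e6)
    expect_equal(nrow(high$centres), 1)
    expect_equal(as.vector(high$centres), colMeans(p))
})

test_that("two tight far-apart pairs are cut into their pair means", {
    # ward.D2 merge heights: 1 within each pair, sqrt(2)*10 between pairs
    p <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
    wc <- wardCut(p, h = 5)
    expect_equal(nrow(wc$centres), 2)
    got <- wc$centres[order(wc$centres[, 1]), ]
    expect_equal(unname(got), rbind(c(0.5, 0), c(10.5, 0)))
    expect_equal(wc$groups[1], wc$groups[2])
    expect_equal(wc$groups[3], wc$groups[4])
})

test_that("single-block clustering without consolidation reduces exactly to
           ward cut plus k-means", {
    d <- plantedProfiles(20, c(1, 3, 5), noiseSd = 0.3, seed = 31)
    viaBlock <- blockCluster(d$profiles, blockSize = 1000, hMax = 2,
                             consolidateSingleBlock = FALSE)
    seeds <- wardCut(d$profiles, h = 2)$centres
    km <- lrclock:::.lloydKMeans(d$profiles, seeds)
    expect_identical(unname(clusterAssignments(viaBlock)), km$assignments)
    expect_identical(clusterCentres(viaBlock), km$centres)
    expect_identical(viaBlock@initialCentres, seeds)
})

test_that("within-block gene order does not change the centre set", {
    d <- plantedProfiles(15, c(1, 4, 6), noiseSd = 0.2, seed = 32)
    c1 <- blockCluster(d$profiles)@initialCentres
    set.seed(1)
    perm <- sample(nrow(d$profiles))
    c2 <- blockCluster(d$profiles[perm, ])@initialCentres
    sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
    expect_equal(sortRows(c1), sortRows(c2), tolerance = 1e-9)
})

test_that("k-means objective is monotone and empty seeds are dropped", {
    d <- plantedProfiles(30, c(2, 5), noiseSd = 0.2, seed = 33)
    far <- matrix(50, 1, length(tt))
    km <- lrclock:::.lloydKMeans(
        d$profiles, rbind(classProfiles()[c(2, 5), ], far))
    expect_true(all(diff(km$withinss) <= 1e-9))
    expect_gte(km$dropped, 1)
    expect_equal(nrow(km$centres), 2)
    expect_equal(length(km$assignments), nrow(d$profiles))

    res <- blockCluster(d$profiles)
    expect_equal(sum(clusterSizes(res)), nrow(d$profiles))
})

test_that("centre merging keeps TF centres and distance-filters the rest", {
    tf <- rbind(c(0, 0, 0), c(3, 3, 3))
    other <- rbind(c(0, 0, 0),          # distance 0: excluded
                   c(2, 0, 0),          # distance 2 exactly: kept
                   c(3, 3, 3.5))        # distance 0.5: excluded
    merged <- mergeCentreSets(tf, other, distance = 2)
    expect_equal(nrow(merged), 3)
    expect_equal(merged[3, ], c(2, 0, 0))
    onlyTF <- mergeCentreSets(tf, rbind(c(0.1, 0, 0)), distance = 2)
    expect_equal(onlyTF, tf)
    expect_warning(out <- mergeCentreSets(NULL, other), "empty TF")
    expect_equal(out, other)
})

test_that("shared TF/non-TF structure collapses to the TF centres and the
           final cluster count never exceeds the merged seed count", {
    d <- plantedProfiles(60, c(1, 3), noiseSd = 0.15, seed = 34)
    tfIdx <- unlist(lapply(c(0, 60), function(o) o + 1:12))
    tfProf <- d$profiles[tfIdx, ]
    otProf <- d$profiles[-tfIdx, ]
    res <- clusterTwoPass(tfProf, otProf)
    nTF <- nrow(blockCluster(tfProf)@initialCentres)
    expect_equal(nrow(res@initialCentres), nTF)
    expect_lte(nrow(clusterCentres(res)), nrow(res@initialCentres))
    ari <- mclust::adjustedRandIndex(
        clusterAssignments(res)[rownames(d$profiles)], d$classes)
    expect_equal(ari, 1)
})

test_that("two-pass clustering requires disjoint gene sets and degrades
           gracefully without TFs", {
    d <- plantedProfiles(10, c(1, 6), noiseSd = 0.2, seed = 35)
    expect_error(clusterTwoPass(d$profiles, d$profiles), "disjoint")
    expect_warning(res <- clusterTwoPass(NULL, d$profiles), "single-pass")
    expect_equal(sum(clusterSizes(res)), nrow(d$profiles))
})
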