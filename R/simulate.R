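#' Noiseless log2 profile for a planted gene class
#'
#' The shape primitives of the synthetic generator, on the log2 scale and
#' centred at zero:
#' \describe{
#'   \item{oscillatory}{`amplitude * cos(2*pi*(t - phase)/period)`}
#'   \item{monotone}{a linear ramp from `-amplitude` to `+amplitude` over
#'     the observed range}
#'   \item{impulse}{a single Gaussian bump of height `amplitude`, centred
#'     at `phase` with s.d. `width` hours}
#'   \item{flat}{zero everywhere}
#' }
#'
#' @param kind one of `"oscillatory"`, `"monotone"`, `"impulse"`, `"flat"`.
#' @param times numeric vector of sampling times (hours), nonempty.
#' @param period oscillation period in hours (> 0; oscillatory only).
#' @param phase peak time in hours (oscillatory: cosine peak; impulse:
#'   bump centre, defaulting to mid-range).
#' @param amplitude profile amplitude in log2 units.
#' @param width impulse bump s.d. in hours.
#' @return numeric vector, one log2 value per time.
#' @examples
#' tt <- c(0, seq(6, 54, by = 3))
#' generateProfile("oscillatory", tt, period = 24, phase = 6)
#' @export
generateProfile <- function(kind, times, period = NULL, phase = NULL,
                            amplitude = 1, width = 4.5) {
    if (length(times) < 1L)
        stop("'times' must be nonempty")
    switch(kind,
        oscillatory = {
            if (is.null(period) || period <= 0)
                stop("oscillatory profiles require a period > 0")
            if (is.null(phase)) phase <- 0
            amplitude * cos(2 * pi * (times - phase) / period)
        },
        monotone = {
            r <- range(times)
            if (diff(r) == 0) rep(0, length(times))
            else amplitude * (2 * (times - r[1L]) / diff(r) - 1)
        },
        impulse = {
            if (is.null(phase)) phase <- mean(range(times))
            amplitude * exp(-(times - phase)^2 / (2 * width^2))
        },
        flat = rep(0, length(times)),
        stop(sprintf("unknown profile class '%s'", kind))
    )
}

#' Planted gene-class specification
#'
#' @param kind profile class, see [generateProfile()].
#' @param proportion fraction of genes in this class.
#' @param period,phase,amplitude,width shape parameters passed to
#'   [generateProfile()].
#' @return a `classSpec` list.
#' @export
classSpec <- function(kind, proportion, period = NULL, phase = NULL,
                      amplitude = 1, width = 4.5) {
    stopifnot(proportion >= 0)
    structure(list(kind = kind, proportion = proportion, period = period,
                   phase = phase, amplitude = amplitude, width = width),
              class = "classSpec")
}

#' Default planted class mix
#'
#' The study-design defaults of the generator: four oscillatory classes
#' sharing a 24-h period with peaks evenly spaced 6 h apart (so the
#' morning-peaking classes run in anti-phase to the evening-peaking ones,
#' as CCA1/LHY do to TOC1), a monotone developmental trend, a single
#' impulse, and a flat majority class.
#'
#' @param period oscillation period (hours) shared by the planted
#'   oscillatory classes.
#' @param nPhases number of evenly spaced oscillatory phase classes.
#' @param oscProportion total proportion of oscillatory genes, split
#'   evenly across the phase classes.
#' @return list of [classSpec()] objects whose proportions sum to 1.
#' @export
defaultClasses <- function(period = 24, nPhases = 4, oscProportion = 0.4) {
    phases <- seq(0, period - period / nPhases, length.out = nPhases)
    osc <- lapply(phases, function(ph)
        classSpec("oscillatory", oscProportion / nPhases, period = period,
                  phase = ph, amplitude = 1))
    c(osc, list(
        classSpec("monotone", 0.15, amplitude = 1),
        classSpec("impulse", 0.15, phase = 30, amplitude = 1),
        classSpec("flat", 1 - oscProportion - 0.3)
    ))
}

# largest-remainder apportionment of n genes over class proportions
.apportion <- function(props, n) {
    if (abs(sum(props) - 1) > 1e-8)
        stop("class proportions must sum to 1")
    raw <- props * n
    cnt <- floor(raw)
    left <- n - sum(cnt)
    if (left > 0) {
        extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
        cnt[extra] <- cnt[extra] + 1L
    }
    as.integer(cnt)
}

#' Simulate a seeded expression time course with known structure
#'
#' Emulates the lateral-root study design: 18 sampling times (a reference
#' plus every 3 h from 6 to 54 h post gravi-induction), four biological
#' replicates, and linear-scale intensities
#' `2^(baseline + profile(t) + offset_r + N(0, noiseSd))`, where the
#' per-gene baseline is normal on log2 (so intensities are lognormal) and
#' each gene follows one planted class profile. Ground truth (class, true
#' period/phase/amplitude, TF flag) is stored in `rowData`.
#'
#' @param nGenes number of genes (>= number of classes).
#' @param times sampling times in hours.
#' @param nReplicates replicates per time point (>= 2).
#' @param classes list of [classSpec()]; proportions must sum to 1.
#' @param noiseSd replicate noise s.d., log2 units (>= 0).
#' @param baselineLogMean,baselineLogSd mean and s.d. of the per-gene log2
#'   baseline intensity.
#' @param tfFraction fraction of genes labelled as transcription factors
#'   (drawn uniformly across classes).
#' @param replicateOffsetSd s.d. of an optional replicate-specific additive
#'   log2 offset (default 0, i.e. off); nonzero values stress-test the
#'   assumption that replicates are exchangeable.
#' @param seed integer RNG seed; identical configuration and seed give
#'   byte-identical output.
#' @return a [TimeCourseExperiment-class] with truth columns `classKind`,
#'   `classIndex`, `truePeriod`, `truePhase`, `trueAmplitude`, `isTF` in
#'   `rowData`.
#' @examples
#' x <- simulateTimeCourse(nGenes = 200, seed = 1)
#' table(syntheticTruth(x)$classKind)
#' @export
simulateTimeCourse <- function(nGenes = 2000,
                               times = c(0, seq(6, 54, by = 3)),
                               nReplicates = 4,
                               classes = defaultClasses(),
                               noiseSd = 0.25,
                               baselineLogMean = 8,
                               baselineLogSd = 2,
                               tfFraction = 0.1,
                               replicateOffsetSd = 0,
                               seed = 1) {
    if (is.unsorted(times, strictly = TRUE))
        stop("'times' must be strictly increasing")
    if (nReplicates < 2L)
        stop("at least 2 replicates are required")
    if (noiseSd < 0)
        stop("'noiseSd' must be non-negative")
    if (nGenes < length(classes))
        stop("'nGenes' must be at least the number of classes")
    counts <- .apportion(vapply(classes, `[[`, numeric(1), "proportion"),
                         nGenes)
    nt <- length(times)
    classIndex <- rep(seq_along(classes), counts)
    kinds <- vapply(classes, `[[`, character(1), "kind")

    profiles <- matrix(0, nGenes, nt)
    for (ci in seq_along(classes)) {
        sp <- classes[[ci]]
        rows <- which(classIndex == ci)
        if (length(rows))
            profiles[rows, ] <- matrix(
                generateProfile(sp$kind, times, period = sp$period,
                                phase = sp$phase, amplitude = sp$amplitude,
                                width = sp$width),
                nrow = length(rows), ncol = nt, byrow = TRUE)
    }

    withSeed(seed, {
        baseline <- stats::rnorm(nGenes, baselineLogMean, baselineLogSd)
        repOffset <- if (replicateOffsetSd > 0)
            stats::rnorm(nReplicates, 0, replicateOffsetSd)
        else rep(0, nReplicates)
        log2mat <- matrix(0, nGenes, nt * nReplicates)
        for (j in seq_len(nt)) for (r in seq_len(nReplicates)) {
            col <- (j - 1L) * nReplicates + r
            log2mat[, col] <- baseline + profiles[, j] + repOffset[r] +
                stats::rnorm(nGenes, 0, noiseSd)
        }
        nTF <- round(nGenes * tfFraction)
        tfIdx <- if (nTF > 0) sample(nGenes, nTF) else integer()
    })

    isTF <- logical(nGenes)
    isTF[tfIdx] <- TRUE
    truth <- S4Vectors::DataFrame(
        classKind = kinds[classIndex],
        classIndex = classIndex,
        truePeriod = vapply(classIndex, function(i)
            if (kinds[i] == "oscillatory") classes[[i]]$period
            else NA_real_, numeric(1)),
        truePhase = vapply(classIndex, function(i) {
            ph <- classes[[i]]$phase
            if (is.null(ph)) NA_real_ else ph
        }, numeric(1)),
        trueAmplitude = vapply(classIndex, function(i)
            classes[[i]]$amplitude, numeric(1)),
        isTF = isTF
    )
    TimeCourseExperiment(2^log2mat, times = times, nReplicates = nReplicates,
                         geneIds = sprintf("G%05d", seq_len(nGenes)),
                         rowData = truth)
}

#' Shipped synthetic benchmark fixture
#'
#' The 2,000-gene synthetic data set used throughout the examples and the
#' end-to-end tests: the default planted class mix of
#' [defaultClasses()] under the study's sampling design.
#'
#' @param seed integer RNG seed.
#' @return a [TimeCourseExperiment-class].
#' @export
exampleDataset <- function(seed = 1) simulateTimeCourse(seed = seed)
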