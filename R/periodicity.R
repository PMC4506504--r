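# Turning-point extraction from a first-derivative vector on a grid:
# grid points with derivative exactly zero are turning points; elsewhere,
# a sign change between adjacent nonzero grid values contributes the
# midpoint of the two grid points.
.turningPoints <- function(grid, deriv) {
    exact <- which(deriv == 0)
    d1 <- deriv[-length(deriv)]
    d2 <- deriv[-1L]
    flip <- which(d1 * d2 < 0)
    sort(c(grid[exact], (grid[flip] + grid[flip + 1L]) / 2))
}

#' Turning-point period estimation
#'
#' Estimates the period of an (assumed oscillatory) time profile without
#' any harmonic model: a lightly smoothed spline (`spar = 0.1`; the heavy
#' smoothing has already happened upstream when profiles were fitted at
#' `spar = 0.4`) is fitted to the profile, its first derivative is
#' evaluated on a uniform grid of `gridSize` points spanning the observed
#' time range, and the turning points (peaks and troughs) are located
#' where the derivative is exactly zero at a grid point or, otherwise, at
#' the midpoint of adjacent grid points across which its sign changes.
#' Successive turning points are on average half a period apart, so the
#' period estimate is twice the mean gap; with fewer than two turning
#' points it is undefined.
#'
#' @param values numeric profile (>= 4 points, not all equal).
#' @param times observation times in hours.
#' @param spar smoothness parameter of the period fit.
#' @param gridSize number of grid points (>= 10).
#' @param sourceId label carried into the result.
#' @return a [PeriodEstimate-class].
#' @examples
#' tt <- c(0, seq(6, 54, by = 3))
#' est <- estimatePeriod(cos(2 * pi * (tt - 6) / 24), tt)
#' periodHours(est)
#' @export
estimatePeriod <- function(values, times, spar = 0.1, gridSize = 1000,
                           sourceId = "") {
    if (gridSize < 10L)
        stop("'gridSize' must be at least 10")
    if (length(unique(values)) == 1L)
        .degenerateProfile(sourceId)
    fit <- fitSmoothingSpline(times, values, spar = spar)
    grid <- seq(min(times), max(times), length.out = gridSize)
    deriv <- splineValues(fit, grid, deriv = 1)
    tp <- .turningPoints(grid, deriv)
    period <- if (length(tp) >= 2L) 2 * mean(diff(tp)) else NA_real_
    new("PeriodEstimate", sourceId = as.character(sourceId),
        turningPoints = tp, period = period, spar = spar,
        gridSize = as.integer(gridSize))
}

#' @rdname PeriodEstimate-class
#' @export
setMethod("turningPoints", "PeriodEstimate", function(x) x@turningPoints)

#' @rdname PeriodEstimate-class
#' @export
setMethod("periodHours", "PeriodEstimate", function(x) x@period)

setMethod("show", "PeriodEstimate", function(object) {
    cat(sprintf("PeriodEstimate%s: %d turning points",
                if (nzchar(object@sourceId))
                    paste0(" [", object@sourceId, "]") else "",
                length(object@turningPoints)))
    if (is.na(object@period)) cat(", period undefined\n")
    else cat(sprintf(", period %.2f h\n", object@period))
})

#' Classify oscillatory cluster mean profiles
#'
#' Operational replacement for the visual call of which cluster means
#' "look oscillatory": a cluster is flagged when its mean profile has at
#' least `minTurningPoints` turning points and a defined period inside
#' `periodBand`. The defaults (4 turning points; 15-40 h, bracketing the
#' circadian range) keep planted oscillators and reject monotone or
#' single-impulse trends: any oscillation with period at most 40 h must
#' turn at least four times inside the 54-h window, whereas an impulse
#' contributes at most its peak flanked by two spline-undershoot minima.
#' Degenerate (constant) profiles are flagged not-oscillatory.
#'
#' @param clusterMeans numeric matrix of cluster mean profiles (clusters x
#'   time points), e.g. `clusterSummary(result)$means`.
#' @param times time points in hours.
#' @param spar,gridSize see [estimatePeriod()].
#' @param minTurningPoints minimum turning-point count.
#' @param periodBand length-2 numeric, plausible period range in hours.
#' @return a `DataFrame` with columns `clusterId`, `nTurningPoints`,
#'   `period`, `turningPoints` (comma-separated hours), `oscillatory`;
#'   the full [PeriodEstimate-class] objects are in
#'   `metadata(result)$estimates`.
#' @export
classifyOscillatory <- function(clusterMeans, times, spar = 0.1,
                                gridSize = 1000, minTurningPoints = 4,
                                periodBand = c(15, 40)) {
    .assertProfileMatrix(clusterMeans, "clusterMeans")
    k <- nrow(clusterMeans)
    ids <- rownames(clusterMeans)
    if (is.null(ids)) ids <- as.character(seq_len(k))
    ests <- lapply(seq_len(k), function(i)
        tryCatch(
            estimatePeriod(clusterMeans[i, ], times, spar = spar,
                           gridSize = gridSize, sourceId = ids[i]),
            degenerateProfileError = function(e)
                new("PeriodEstimate", sourceId = ids[i],
                    turningPoints = numeric(), period = NA_real_,
                    spar = spar, gridSize = as.integer(gridSize))))
    ntp <- vapply(ests, function(e) length(e@turningPoints), integer(1))
    per <- vapply(ests, function(e) e@period, numeric(1))
    osc <- ntp >= minTurningPoints & !is.na(per) &
        per >= periodBand[1L] & per <= periodBand[2L]
    out <- S4Vectors::DataFrame(
        clusterId = ids,
        nTurningPoints = ntp,
        period = per,
        turningPoints = vapply(ests, function(e)
            paste(sprintf("%.2f", e@turningPoints), collapse = ","),
            character(1)),
        oscillatory = osc)
    S4Vectors::metadata(out)$estimates <- ests
    out
}

#' Principal-component score curves over time
#'
#' Oscillation QC for a whole time course: genes are replicate-averaged on
#' the log2 scale and centred, and the singular value decomposition of the
#' resulting time x gene matrix yields orthogonal per-time score curves
#' ordered by explained variance. An oscillating score curve among the
#' leading components (the third, in the lateral-root data set) indicates
#' coherent rhythmic structure; [estimatePeriod()] is applied to each
#' reported component.
#'
#' @param x a [TimeCourseExperiment-class].
#' @param nComponents number of leading components to report (default 4).
#' @param spar,gridSize settings for the per-component period estimates.
#' @return list with `scores` (time points x components matrix),
#'   `varianceExplained` (fraction per component), `times`, and
#'   `periods` (list of [PeriodEstimate-class], one per component, `NULL`
#'   where degenerate).
#' @export
pcaTimeScores <- function(x, nComponents = 4, spar = 0.1, gridSize = 1000) {
    stopifnot(is(x, "TimeCourseExperiment"))
    m <- replicateMeans(x, log = TRUE)
    tp <- timePoints(x)
    if (nComponents > length(tp))
        stop(sprintf("cannot report %d components from %d time points",
                     nComponents, length(tp)))
    ctr <- m - rowMeans(m)
    sv <- svd(t(ctr), nu = nComponents, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(nComponents)],
                            nrow = nComponents)
    rownames(scores) <- sprintf("t%s", .timeLabel(tp))
    colnames(scores) <- sprintf("PC%d", seq_len(nComponents))
    periods <- lapply(seq_len(nComponents), function(j)
        tryCatch(estimatePeriod(scores[, j], tp, spar = spar,
                                gridSize = gridSize,
                                sourceId = sprintf("PC%d", j)),
                 degenerateProfileError = function(e) NULL))
    list(scores = scores,
         varianceExplained = sv$d^2 / sum(sv$d^2),
         times = tp, periods = periods)
}
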