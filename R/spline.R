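#' Fit a penalized cubic smoothing spline to one time profile
#'
#' Minimizes `sum_i (y_i - f(t_i))^2 + lambda * integral f''(u)^2 du` over
#' natural cubic splines with knots at every observation time
#' ([stats::smooth.spline()] with `all.knots = TRUE`). The roughness
#' penalty is controlled through `spar`, the dimensionless smoothness
#' parameter mapped monotonically onto `lambda`
#' (`lambda = r * 256^(3*spar - 1)` with `r` the standard trace-ratio
#' scaling); the profile clustering uses `spar = 0.4` and period
#' estimation `spar = 0.1`. `lambda` may be supplied directly to reach the
#' interpolation (`lambda -> 0`) and straight-line (`lambda -> Inf`)
#' limits.
#'
#' @param times numeric, >= 4 distinct observation times (hours).
#' @param values numeric log2 expression values, one per time.
#' @param spar smoothness parameter in (0, 1]; ignored when `lambda` is
#'   given.
#' @param lambda optional explicit roughness penalty.
#' @return a [SmoothingFit-class].
#' @seealso [splineValues()], [normalizeProfile()]
#' @export
fitSmoothingSpline <- function(times, values, spar = 0.4, lambda = NULL) {
    if (length(times) != length(values))
        stop("'times' and 'values' must have the same length")
    if (anyDuplicated(times))
        stop("duplicate observation times")
    if (length(times) < 4L)
        stop("at least 4 distinct time points are required")
    if (is.null(lambda)) {
        if (!is.numeric(spar) || spar <= 0 || spar > 1)
            stop("'spar' must lie in (0, 1]")
        fit <- stats::smooth.spline(times, values, spar = spar,
                                    all.knots = TRUE, keep.data = FALSE)
    } else {
        if (lambda <= 0)
            stop("'lambda' must be positive")
        fit <- stats::smooth.spline(times, values, lambda = lambda,
                                    all.knots = TRUE, keep.data = FALSE)
        spar <- NA_real_
    }
    new("SmoothingFit", fit = fit, times = as.numeric(times),
        values = as.numeric(values), range = range(times),
        spar = as.numeric(spar))
}

#' Evaluate a smoothing-spline fit
#'
#' @param fit a [SmoothingFit-class].
#' @param x query times within the observed range (no extrapolation).
#' @param deriv 0 for the curve, 1 for its first derivative.
#' @return numeric vector of fitted values.
#' @export
splineValues <- function(fit, x, deriv = 0) {
    stopifnot(is(fit, "SmoothingFit"))
    if (any(x < fit@range[1L] - 1e-9 | x > fit@range[2L] + 1e-9))
        stop(sprintf("query times outside the observed range [%g, %g]",
                     fit@range[1L], fit@range[2L]))
    stats::predict(fit@fit, x, deriv = deriv)$y
}

setMethod("show", "SmoothingFit", function(object) {
    cat(sprintf("SmoothingFit: %d points on [%g, %g] h, spar = %s\n",
                length(object@times), object@range[1L], object@range[2L],
                format(object@spar)))
})

#' Standardize a profile to mean 0, variance 1
#'
#' Centres and scales a vector of fitted spline values across the time
#' points. The default divisor is the sample standard deviation (n - 1);
#' the population convention (n) is available since either reading of
#' "variance 1 across the time points" is defensible.
#'
#' @param values numeric profile (typically spline fitted values at the
#'   design time points).
#' @param divisor `"sample"` (n - 1, default) or `"population"` (n).
#' @return standardized numeric vector.
#' @section Errors: a constant profile has no scale and signals a
#'   `degenerateProfileError`; callers sweeping many genes should trap it
#'   with [isDegenerateProfileError()] and drop the gene.
#' @export
normalizeProfile <- function(values, divisor = c("sample", "population")) {
    divisor <- match.arg(divisor)
    m <- mean(values)
    n <- length(values)
    ss <- sum((values - m)^2)
    if (ss == 0)
        .degenerateProfile()
    s <- sqrt(ss / if (divisor == "sample") (n - 1) else n)
    (values - m) / s
}

#' Equivalent-kernel matrix of the smoothing spline at the design times
#'
#' The smoothing spline is a linear smoother: with the design times and
#' `spar` fixed, fitted values at the observation times are `S %*% y` for
#' a single n x n matrix `S`. Computing `S` once (one unit-vector fit per
#' time point) turns per-gene spline fitting across thousands of genes
#' into one matrix product.
#'
#' @param times design time points (>= 4, distinct).
#' @param spar smoothness parameter in (0, 1].
#' @return n x n smoother matrix.
#' @export
smootherMatrix <- function(times, spar = 0.4) {
    n <- length(times)
    S <- vapply(seq_len(n), function(i) {
        e <- numeric(n); e[i] <- 1
        splineValues(fitSmoothingSpline(times, e, spar = spar), times)
    }, numeric(n))
    S
}

#' Spline-smoothed, standardized profiles for many genes
#'
#' The common substrate of clustering and cluster summaries: every gene's
#' replicate-mean log2 profile is smoothed at the given `spar` (via the
#' precomputed smoother matrix) and standardized to mean 0, variance 1
#' across the time points. Genes whose smoothed profile is constant are
#' excluded and reported.
#'
#' @param x a [TimeCourseExperiment-class], or a genes x time-points
#'   numeric matrix of (already replicate-averaged) log2 values.
#' @param times required when `x` is a plain matrix.
#' @param spar smoothness parameter.
#' @param divisor see [normalizeProfile()].
#' @return list with `profiles` (genes x time points matrix of
#'   standardized fitted values) and `degenerate` (character vector of
#'   excluded gene ids).
#' @export
normalizedSplineProfiles <- function(x, times = NULL, spar = 0.4,
                                     divisor = c("sample", "population")) {
    divisor <- match.arg(divisor)
    if (is(x, "TimeCourseExperiment")) {
        times <- timePoints(x)
        m <- replicateMeans(x, log = TRUE)
    } else {
        .assertProfileMatrix(x)
        if (is.null(times))
            stop("'times' is required for a plain matrix input")
        m <- x
    }
    S <- smootherMatrix(times, spar = spar)
    fitted <- m %*% t(S)
    ctr <- fitted - rowMeans(fitted)
    ss <- rowSums(ctr^2)
    n <- ncol(fitted)
    # a constant gene smooths to a constant up to rounding noise; treat
    # profiles with negligible scale relative to their level as degenerate
    degenerate <- sqrt(ss / (n - 1)) <=
        1e-10 * pmax(1, abs(rowMeans(fitted)))
    denom <- sqrt(ss / if (divisor == "sample") (n - 1) else n)
    out <- ctr / denom
    dimnames(out) <- dimnames(m)
    list(profiles = out[!degenerate, , drop = FALSE],
         degenerate = rownames(m)[degenerate])
}
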