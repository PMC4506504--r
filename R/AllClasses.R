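#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Gene expression time course with replicate structure
#'
#' `TimeCourseExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] for a genes x (time point x
#' replicate) matrix of linear-scale hybridization intensities. Column
#' metadata carry the sampling time in hours (`time`) and the replicate
#' index (`replicate`); every time point must be observed for every
#' replicate. Synthetic data sets additionally carry per-gene ground truth
#' in `rowData` (see [simulateTimeCourse()]).
#'
#' @slot .. inherited from `SummarizedExperiment`; the single assay is
#'   named `"exprs"`.
#' @seealso [TimeCourseExperiment()], [simulateTimeCourse()], [readMatrix()]
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("time", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'time' and 'replicate'")
    if (length(msg))
        return(msg)
    v <- SummarizedExperiment::assay(object, "exprs")
    if (any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, "intensities must be finite and non-negative")
    tab <- table(cd$time)
    if (length(unique(tab)) > 1L)
        msg <- c(msg, "every time point needs the same number of replicates")
    if (is.unsorted(unique(sort(cd$time)), strictly = TRUE))
        msg <- c(msg, "time points must be distinct")
    if (length(msg)) msg else TRUE
})

#' Final hybrid-clustering result
#'
#' Holds the outcome of [blockCluster()] or [clusterTwoPass()]: the k-means
#' assignment of every clustered gene, the initial (seed) centres that came
#' out of the hierarchical stage, the converged centres, and per-cluster
#' per-time-point mean and standard deviation of the member standardized
#' profiles (the mean +/- 2 s.d. summaries used to draw cluster panels).
#'
#' @slot assignments named integer vector, one cluster id per gene.
#' @slot centres numeric matrix, k x time points; converged k-means centres.
#' @slot initialCentres numeric matrix; the centres that seeded k-means.
#' @slot sizes integer vector of cluster sizes (sums to the gene count).
#' @slot profileMeans,profileSds k x time-point matrices summarizing member
#'   profiles per cluster.
#' @slot times numeric vector of time points (hours).
#' @slot droppedCentres integer, number of seed centres that ended up empty
#'   during k-means and were removed.
#' @slot iterations integer, Lloyd iterations to the assignment fixpoint.
#' @slot withinss numeric, within-cluster sum of squares per iteration
#'   (non-increasing).
#' @export
setClass("ClusterResult",
    representation(
        assignments    = "integer",
        centres        = "matrix",
        initialCentres = "matrix",
        sizes          = "integer",
        profileMeans   = "matrix",
        profileSds     = "matrix",
        times          = "numeric",
        droppedCentres = "integer",
        iterations     = "integer",
        withinss       = "numeric"
    )
)

setValidity("ClusterResult", function(object) {
    msg <- character()
    k <- nrow(object@centres)
    if (length(object@sizes) != k)
        msg <- c(msg, "one size per cluster required")
    if (sum(object@sizes) != length(object@assignments))
        msg <- c(msg, "cluster sizes must sum to the number of genes")
    if (length(object@assignments) &&
        (min(object@assignments) < 1L || max(object@assignments) > k))
        msg <- c(msg, "assignments out of range")
    if (ncol(object@centres) != length(object@times))
        msg <- c(msg, "centres must have one column per time point")
    if (length(msg)) msg else TRUE
})

#' Turning-point period estimate
#'
#' Result of [estimatePeriod()]: the turning-point times of a low-smoothing
#' spline fit (grid points where the first derivative is exactly zero, else
#' midpoints of grid neighbours across which it changes sign) and the
#' period estimate, defined as twice the mean gap between successive
#' turning points. With fewer than two turning points the period is
#' undefined (`NA`).
#'
#' @slot sourceId character label of the profile (gene, cluster or PC).
#' @slot turningPoints numeric, strictly increasing times (hours) inside
#'   the observed range.
#' @slot period numeric, hours, or `NA_real_` when undefined.
#' @slot spar,gridSize the fit settings used.
#' @export
setClass("PeriodEstimate",
    representation(
        sourceId      = "character",
        turningPoints = "numeric",
        period        = "numeric",
        spar          = "numeric",
        gridSize      = "integer"
    )
)

setValidity("PeriodEstimate", function(object) {
    msg <- character()
    tp <- object@turningPoints
    if (length(tp) > 1L && is.unsorted(tp, strictly = TRUE))
        msg <- c(msg, "turning points must be strictly increasing")
    if (length(tp) >= 2L && is.na(object@period))
        msg <- c(msg, "period must be defined with >= 2 turning points")
    if (length(tp) < 2L && !is.na(object@period))
        msg <- c(msg, "period must be NA with < 2 turning points")
    if (length(msg)) msg else TRUE
})

#' Penalized cubic smoothing-spline fit
#'
#' Thin wrapper around a [stats::smooth.spline()] fit with knots at every
#' observation, keeping the observed time range so that evaluation outside
#' it is refused (the fit is only meaningful over the data). Use
#' [splineValues()] to evaluate the curve or its first derivative.
#'
#' @slot fit the underlying `smooth.spline` object.
#' @slot times,values the fitting data.
#' @slot range numeric length-2, observed time range.
#' @slot spar the smoothness parameter used (`NA` when `lambda` was given
#'   directly).
#' @export
setClass("SmoothingFit",
    representation(
        fit    = "ANY",
        times  = "numeric",
        values = "numeric",
        range  = "numeric",
        spar   = "numeric"
    )
)
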