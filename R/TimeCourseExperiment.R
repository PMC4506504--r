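#' Construct a TimeCourseExperiment
#'
#' Builds the package's central container from a linear-scale intensity
#' matrix whose columns run over time points and replicates.
#'
#' @param values numeric matrix, genes x (time x replicate), linear-scale
#'   intensities (non-negative). Columns must be ordered replicate within
#'   time, matching `times`/`replicates`.
#' @param times numeric vector of sampling times in hours, one per time
#'   point, strictly increasing.
#' @param nReplicates integer, replicates per time point (>= 1; the
#'   analyses require >= 2).
#' @param geneIds character vector of gene identifiers (defaults to
#'   rownames of `values`).
#' @param rowData optional `DataFrame` of per-gene metadata.
#' @return a [TimeCourseExperiment-class] object.
#' @examples
#' tt <- c(0, seq(6, 54, by = 3))
#' m <- matrix(2^rnorm(5 * 18 * 4, mean = 8), nrow = 5)
#' x <- TimeCourseExperiment(m, times = tt, nReplicates = 4)
#' timePoints(x)
#' @export
TimeCourseExperiment <- function(values, times, nReplicates,
                                 geneIds = rownames(values),
                                 rowData = NULL) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.unsorted(times, strictly = TRUE))
        stop("'times' must be strictly increasing")
    nReplicates <- as.integer(nReplicates)
    if (ncol(values) != length(times) * nReplicates)
        stop(sprintf("expected %d columns (%d times x %d replicates), got %d",
                     length(times) * nReplicates, length(times),
                     nReplicates, ncol(values)))
    if (is.null(geneIds))
        geneIds <- sprintf("G%05d", seq_len(nrow(values)))
    timeCol <- rep(times, each = nReplicates)
    repCol <- rep(seq_len(nReplicates), times = length(times))
    colnames(values) <- sprintf("t%s_r%d", .timeLabel(timeCol), repCol)
    rownames(values) <- geneIds
    cd <- S4Vectors::DataFrame(time = timeCol, replicate = repCol,
                               row.names = colnames(values))
    args <- list(assays = list(exprs = values), colData = cd)
    if (!is.null(rowData)) args$rowData <- rowData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("TimeCourseExperiment", se)
}

#' @rdname TimeCourseExperiment-class
#' @aliases timePoints,TimeCourseExperiment-method
#' @export
setMethod("timePoints", "TimeCourseExperiment", function(x)
    sort(unique(SummarizedExperiment::colData(x)$time)))

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("nReplicates", "TimeCourseExperiment", function(x)
    as.integer(table(SummarizedExperiment::colData(x)$time)[1L]))

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("intensities", "TimeCourseExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("log2Intensities", "TimeCourseExperiment", function(x)
    log2(SummarizedExperiment::assay(x, "exprs")))

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("replicateMeans", "TimeCourseExperiment", function(x, log = TRUE) {
    v <- if (log) log2Intensities(x) else intensities(x)
    tp <- timePoints(x)
    tcol <- SummarizedExperiment::colData(x)$time
    out <- vapply(tp, function(t0) rowMeans(v[, tcol == t0, drop = FALSE]),
                  numeric(nrow(v)))
    out <- matrix(out, nrow = nrow(v),
                  dimnames = list(rownames(v), sprintf("t%s", .timeLabel(tp))))
    out
})

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("syntheticTruth", "TimeCourseExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"classKind" %in% colnames(rd))
        stop("no synthetic ground truth attached to this object")
    rd
})

#' @rdname TimeCourseExperiment-class
#' @export
setMethod("isTF", "TimeCourseExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"isTF" %in% colnames(rd))
        stop("no TF annotation attached to this object")
    stats::setNames(rd$isTF, rownames(x))
})

setMethod("show", "TimeCourseExperiment", function(object) {
    tp <- timePoints(object)
    cat(sprintf(
        "TimeCourseExperiment: %d genes, %d time points (%g-%g h), %d replicates\n",
        nrow(object), length(tp), min(tp), max(tp), nReplicates(object)))
    rd <- SummarizedExperiment::rowData(object)
    if ("classKind" %in% colnames(rd)) {
        cnt <- table(rd$classKind)
        cat("synthetic truth:",
            paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
    }
})
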