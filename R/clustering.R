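#' Ward hierarchical clustering cut at a fixed height
#'
#' Agglomerative clustering of standardized profiles on Euclidean
#' distances with the Ward linkage, cut at dendrogram height `h`; each
#' resulting group is summarized by its per-time-point mean (its centre).
#' `ward.D2` (merge cost expressed in Euclidean terms) is the default;
#' `ward.D` is offered because historical implementations conflated the
#' two variants.
#'
#' @param profiles numeric matrix, profiles x time points.
#' @param h cut height (>= 0).
#' @param linkage `"ward.D2"` (default) or `"ward.D"`.
#' @return list with `centres` (matrix, one row per group), `groups`
#'   (integer assignment of each profile), `heights` (merge heights).
#' @export
wardCut <- function(profiles, h, linkage = c("ward.D2", "ward.D")) {
    linkage <- match.arg(linkage)
    .assertProfileMatrix(profiles)
    if (h < 0)
        stop("'h' must be non-negative")
    if (nrow(profiles) == 1L) {
        dimnames(profiles) <- NULL
        return(list(centres = profiles, groups = 1L, heights = numeric()))
    }
    hc <- stats::hclust(stats::dist(profiles), method = linkage)
    groups <- stats::cutree(hc, h = h)
    sizes <- as.vector(table(groups))
    centres <- rowsum(profiles, groups) / sizes
    dimnames(centres) <- NULL
    list(centres = centres, groups = unname(groups), heights = hc$height)
}

# Lloyd k-means from fixed starting centres: nearest-centre assignment
# (ties broken towards the lowest centre index), centres recomputed as
# member means, empty centres dropped, stopping at the assignment fixpoint
# or maxIter. Deterministic.
.lloydKMeans <- function(profiles, centres, maxIter = 300L) {
    .assertProfileMatrix(profiles)
    if (ncol(centres) != ncol(profiles))
        stop("centres and profiles must have the same number of time points")
    aOld <- NULL
    dropped <- 0L
    wss <- numeric()
    for (it in seq_len(maxIter)) {
        d2 <- .crossDist2(profiles, centres)
        a <- max.col(-d2, ties.method = "first")
        wss <- c(wss, sum(d2[cbind(seq_len(nrow(d2)), a)]))
        present <- sort(unique(a))
        dropped <- dropped + (nrow(centres) - length(present))
        a <- match(a, present)
        centres <- rowsum(profiles, a) / as.vector(table(a))
        rownames(centres) <- NULL
        if (!is.null(aOld) && length(aOld) == length(a) && all(aOld == a))
            break
        aOld <- a
    }
    list(assignments = a, centres = centres, iterations = it,
         dropped = dropped, withinss = wss)
}

.summarizeClusters <- function(profiles, assignments, centres,
                               initialCentres, times, dropped, iterations,
                               withinss) {
    sizes <- as.vector(table(assignments))
    mns <- rowsum(profiles, assignments) / sizes
    ctr <- profiles - mns[assignments, , drop = FALSE]
    sds <- sqrt(rowsum(ctr^2, assignments) /
                pmax(sizes - 1L, 1L))
    sds[sizes == 1L, ] <- 0
    rownames(mns) <- rownames(sds) <- NULL
    new("ClusterResult",
        assignments = stats::setNames(as.integer(assignments),
                                      rownames(profiles)),
        centres = centres, initialCentres = initialCentres,
        sizes = as.integer(sizes), profileMeans = mns, profileSds = sds,
        times = times, droppedCentres = as.integer(dropped),
        iterations = as.integer(iterations), withinss = withinss)
}

#' Block-wise hybrid hierarchical/k-means clustering
#'
#' The scalable hybrid scheme for clustering thousands of standardized
#' spline profiles: (1) split the genes, in input order, into blocks of
#' `blockSize` plus a remainder block; (2) Ward-cluster each block and cut
#' at `hMax` to obtain per-block centres; (3) pool the centres; (4)
#' Ward-cluster the pooled centres and cut at `2 * hMax`, averaging each
#' group into a consolidated centre; (5) run k-means over all profiles
#' seeded with the consolidated centres.
#'
#' Step (4) is applied regardless of the number of blocks by default,
#' since it also repairs over-splitting of small gene sets; setting
#' `consolidateSingleBlock = FALSE` skips it when there is a single block,
#' making the result identical to [wardCut()] at `hMax` followed by
#' k-means.
#'
#' @param profiles numeric matrix of standardized profiles (rows named by
#'   gene).
#' @param blockSize genes per block (>= 2).
#' @param hMax per-block dendrogram cut height (> 0); pooled centres are
#'   cut at `2 * hMax`.
#' @param linkage Ward variant, see [wardCut()].
#' @param consolidateSingleBlock apply step (4) even when all genes fit in
#'   one block (default `TRUE`).
#' @param maxIter k-means iteration cap.
#' @param times optional time-point hours for the result (defaults to
#'   column index).
#' @param shuffle optional integer seed; when given, gene order is
#'   shuffled reproducibly before blocking (block composition, unlike
#'   within-block order, can affect the centres).
#' @return a [ClusterResult-class]; the seed centres of step (4)/(5) are
#'   in `initialCentres`.
#' @export
blockCluster <- function(profiles, blockSize = 1000, hMax = 2,
                         linkage = c("ward.D2", "ward.D"),
                         consolidateSingleBlock = TRUE, maxIter = 300L,
                         times = NULL, shuffle = NULL) {
    linkage <- match.arg(linkage)
    .assertProfileMatrix(profiles)
    if (blockSize < 2L)
        stop("'blockSize' must be at least 2")
    if (hMax <= 0)
        stop("'hMax' must be positive")
    ord <- seq_len(nrow(profiles))
    if (!is.null(shuffle))
        ord <- withSeed(shuffle, sample(ord))
    blocks <- split(ord, ceiling(seq_along(ord) / blockSize))
    centres <- do.call(rbind, unname(lapply(blocks, function(idx)
        wardCut(profiles[idx, , drop = FALSE], hMax, linkage)$centres)))
    if ((length(blocks) > 1L || consolidateSingleBlock) &&
        nrow(centres) > 1L)
        centres <- wardCut(centres, 2 * hMax, linkage)$centres
    if (is.null(times))
        times <- as.numeric(seq_len(ncol(profiles)))
    km <- .lloydKMeans(profiles, centres, maxIter = maxIter)
    .summarizeClusters(profiles, km$assignments, km$centres, centres,
                       times, km$dropped, km$iterations, km$withinss)
}

#' Merge TF and non-TF centre sets by distance filtering
#'
#' Keeps all transcription-factor centres, plus every other centre whose
#' minimum Euclidean distance to the TF set is at least `distance`
#' (inclusive: a centre exactly `distance` away is kept).
#'
#' @param tfCentres,otherCentres numeric centre matrices with matching
#'   columns.
#' @param distance minimum separation (>= 0), default 2.
#' @return combined centre matrix (TF centres first).
#' @export
mergeCentreSets <- function(tfCentres, otherCentres, distance = 2) {
    if (is.null(tfCentres) || nrow(tfCentres) == 0L) {
        warning("empty TF centre set; returning the other centres unchanged")
        return(otherCentres)
    }
    if (is.null(otherCentres) || nrow(otherCentres) == 0L)
        return(tfCentres)
    if (ncol(tfCentres) != ncol(otherCentres))
        stop("centre sets must have the same number of time points")
    dmin <- sqrt(apply(.crossDist2(otherCentres, tfCentres), 1L, min))
    rbind(tfCentres, otherCentres[dmin >= distance, , drop = FALSE])
}

#' Two-pass clustering with TF-guided centre merging
#'
#' The full clustering procedure for a differentially expressed gene set
#' split into transcription factors and the remaining genes: each set is
#' block-clustered independently ([blockCluster()]), the non-TF centres
#' lying within `mergeDistance` of any TF centre are discarded
#' ([mergeCentreSets()]) so that regulatory profiles are not swamped by
#' duplicate bulk centres, and a final k-means over the union of all
#' profiles is seeded with the merged centre set.
#'
#' @param tfProfiles,otherProfiles standardized profile matrices for the
#'   two disjoint gene sets (either may be empty/`NULL`; with no TF
#'   profiles the procedure degrades to [blockCluster()] of the other
#'   set).
#' @param mergeDistance Euclidean cut-off for dropping non-TF centres.
#' @inheritParams blockCluster
#' @return a [ClusterResult-class] over the union of genes; the merged
#'   centre set is in `initialCentres`.
#' @export
clusterTwoPass <- function(tfProfiles, otherProfiles, blockSize = 1000,
                           hMax = 2, mergeDistance = 2,
                           linkage = c("ward.D2", "ward.D"),
                           consolidateSingleBlock = TRUE, maxIter = 300L,
                           times = NULL) {
    linkage <- match.arg(linkage)
    noTF <- is.null(tfProfiles) || nrow(tfProfiles) == 0L
    noOther <- is.null(otherProfiles) || nrow(otherProfiles) == 0L
    if (noTF && noOther)
        stop("no profiles to cluster")
    if (!noTF && !noOther &&
        length(common <- intersect(rownames(tfProfiles),
                                   rownames(otherProfiles))))
        stop(sprintf("gene sets must be disjoint (%d shared ids)",
                     length(common)))
    bc <- function(p) blockCluster(p, blockSize = blockSize, hMax = hMax,
                                   linkage = linkage,
                                   consolidateSingleBlock =
                                       consolidateSingleBlock,
                                   maxIter = maxIter, times = times)
    if (noTF) {
        warning("no TF profiles; falling back to single-pass clustering")
        return(bc(otherProfiles))
    }
    tfCentres <- bc(tfProfiles)@initialCentres
    all <- tfProfiles
    if (!noOther) {
        otherCentres <- bc(otherProfiles)@initialCentres
        centres <- mergeCentreSets(tfCentres, otherCentres,
                                   distance = mergeDistance)
        all <- rbind(tfProfiles, otherProfiles)
    } else {
        centres <- tfCentres
    }
    if (is.null(times))
        times <- as.numeric(seq_len(ncol(all)))
    km <- .lloydKMeans(all, centres, maxIter = maxIter)
    .summarizeClusters(all, km$assignments, km$centres, centres,
                       times, km$dropped, km$iterations, km$withinss)
}

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterCentres", "ClusterResult", function(x) x@centres)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) x@sizes)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterSummary", "ClusterResult", function(x)
    list(means = x@profileMeans, sds = x@profileSds))

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf(
        "ClusterResult: %d genes in %d clusters (%d seed centres, %d dropped, %d iterations)\n",
        length(object@assignments), nrow(object@centres),
        nrow(object@initialCentres), object@droppedCentres,
        object@iterations))
    cat("sizes:", paste(object@sizes, collapse = " "), "\n")
})
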