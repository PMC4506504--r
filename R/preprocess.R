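#' Expressed-gene filter
#'
#' A gene counts as expressed when its replicate-mean linear-scale
#' intensity strictly exceeds the floor at one or more time points. The
#' default floor of 100 intensity units is the conventional ATH1 detection
#' cutoff; a gene whose mean equals the floor exactly is *not* expressed.
#'
#' @param x a [TimeCourseExperiment-class].
#' @param floor positive linear-scale intensity threshold.
#' @return named logical vector, one flag per gene.
#' @export
filterExpressed <- function(x, floor = 100) {
    stopifnot(is(x, "TimeCourseExperiment"))
    if (floor <= 0)
        stop("'floor' must be positive")
    if (nrow(x) == 0L)
        stop("empty expression matrix")
    m <- replicateMeans(x, log = FALSE)
    stats::setNames(apply(m > floor, 1L, any), rownames(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1 and order-preserving. Wraps [stats::p.adjust()] with input
#' validation.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

# Welch two-sample t-test from per-group means/variances, vectorized over
# genes. Zero-variance, zero-difference columns get t = 0, p = 1; zero
# variance with a nonzero difference gets p = 0.
.welch <- function(m1, v1, n1, m2, v2, n2) {
    se2 <- v1 / n1 + v2 / n2
    d <- m1 - m2
    t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
                ifelse(d == 0, 1, 0))
    list(t = t, p = p)
}

#' Pairwise differential expression over time points
#'
#' Welch two-sample t-tests on log2 intensities between time points of the
#' course, for every expressed gene. By default all unordered pairs of
#' time points are tested (the most inclusive reading of "a t-test between
#' two time points"); consecutive pairs or comparison against the first
#' (reference) time point are available instead. All (gene, pair) p-values
#' are pooled into a single Benjamini-Hochberg family by default.
#'
#' A gene is differentially expressed (`de`) when any pair reaches
#' `q < alpha`, and `restricted` when additionally some significant pair
#' changes at least `foldChange`-fold (|log2 fold change| >=
#' `log2(foldChange)`, computed between replicate-mean log2 values).
#'
#' @param x a [TimeCourseExperiment-class] with >= 2 replicates per time.
#' @param expressed logical vector from [filterExpressed()]; genes flagged
#'   `FALSE` are skipped. Default: filter at floor 100.
#' @param alpha FDR level for the `de` call.
#' @param foldChange linear fold-change threshold for the `restricted`
#'   call.
#' @param pairs which time-point pairs to test.
#' @param poolScope `"global"` pools all genes x pairs into one BH family;
#'   `"perPair"` adjusts each pair separately.
#' @return a `DataFrame` with per-gene columns `expressed`, `de`,
#'   `restricted`, `bestPair`, `minQ`, `maxAbsLog2FC`.
#' @export
differentialExpression <- function(x, expressed = filterExpressed(x),
                                   alpha = 0.05, foldChange = 2,
                                   pairs = c("all", "consecutive",
                                             "reference"),
                                   poolScope = c("global", "perPair")) {
    stopifnot(is(x, "TimeCourseExperiment"))
    pairs <- match.arg(pairs)
    poolScope <- match.arg(poolScope)
    tp <- timePoints(x)
    nrep <- nReplicates(x)
    if (nrep < 2L)
        stop(sprintf("time point %g has fewer than 2 replicates", tp[1L]))
    lv <- log2Intensities(x)
    tcol <- SummarizedExperiment::colData(x)$time
    means <- vars <- matrix(0, nrow(x), length(tp))
    for (j in seq_along(tp)) {
        cols <- which(tcol == tp[j])
        means[, j] <- rowMeans(lv[, cols, drop = FALSE])
        vars[, j] <- apply(lv[, cols, drop = FALSE], 1L, stats::var)
    }

    pairIdx <- switch(pairs,
        all = t(utils::combn(length(tp), 2L)),
        consecutive = cbind(seq_len(length(tp) - 1L), 2:length(tp)),
        reference = cbind(1L, 2:length(tp)))
    keep <- which(expressed)
    out <- S4Vectors::DataFrame(
        geneId = rownames(x),
        expressed = unname(expressed),
        de = FALSE, restricted = FALSE,
        bestPair = NA_character_, minQ = NA_real_,
        maxAbsLog2FC = NA_real_,
        row.names = rownames(x))
    if (length(keep) == 0L)
        return(out)
    npair <- nrow(pairIdx)
    P <- FC <- matrix(NA_real_, length(keep), npair)
    for (k in seq_len(npair)) {
        a <- pairIdx[k, 1L]; b <- pairIdx[k, 2L]
        w <- .welch(means[keep, a], vars[keep, a], nrep,
                    means[keep, b], vars[keep, b], nrep)
        P[, k] <- w$p
        FC[, k] <- means[keep, b] - means[keep, a]
    }
    Q <- if (poolScope == "global")
        matrix(bhAdjust(as.vector(P)), nrow(P), npair)
    else
        apply(P, 2L, bhAdjust)
    Q <- matrix(Q, nrow(P), npair)

    sig <- Q < alpha
    de <- rowSums(sig, na.rm = TRUE) > 0
    bigFC <- abs(FC) >= log2(foldChange)
    restricted <- rowSums(sig & bigFC, na.rm = TRUE) > 0
    minQ <- apply(Q, 1L, min)
    bestK <- apply(Q, 1L, which.min)
    pairLab <- sprintf("t%s-t%s", .timeLabel(tp[pairIdx[, 1L]]),
                       .timeLabel(tp[pairIdx[, 2L]]))

    out$de[keep] <- de
    out$restricted[keep] <- restricted
    out$bestPair[keep] <- pairLab[bestK]
    out$minQ[keep] <- minQ
    out$maxAbsLog2FC[keep] <- apply(abs(FC), 1L, max)
    out
}
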