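# cache of exact Kendall S null tables, keyed by n
.kendallCache <- new.env(parent = emptyenv())

#' Exact null distribution of the Kendall S statistic
#'
#' Distribution of `S` = concordant minus discordant pairs between a fixed
#' ranking of `n` items and a uniformly random permutation (no ties),
#' computed by the standard insertion recursion: the inversion-count
#' generating polynomial `prod_{i=1..n} (1 + x + ... + x^(i-1))`,
#' accumulated by convolution, with `S = n(n-1)/2 - 2 * inversions`.
#'
#' @param n number of items, `2 <= n <= 30`.
#' @return `data.frame` with columns `S` (descending) and `prob`
#'   (summing to 1).
#' @examples
#' exactKendallNull(3) # S = 3, 1, -1, -3 with probs 1/6, 2/6, 2/6, 1/6
#' @export
exactKendallNull <- function(n) {
    if (!is.numeric(n) || length(n) != 1L || n < 2L || n > 30L)
        stop("'n' must be a single integer in [2, 30]")
    n <- as.integer(n)
    key <- as.character(n)
    if (!is.null(.kendallCache[[key]]))
        return(.kendallCache[[key]])
    cnt <- 1
    for (i in 2:n) {
        cs <- cumsum(c(cnt, rep(0, i - 1L)))
        lag <- c(rep(0, i), cs[seq_len(length(cs) - i)])
        cnt <- cs - lag
    }
    prob <- cnt / sum(cnt)
    P <- n * (n - 1L) / 2L
    out <- data.frame(S = P - 2 * (seq_along(cnt) - 1L), prob = prob)
    .kendallCache[[key]] <- out
    out
}

# one-sided upper tail P(S_null >= s) for arbitrary integer s
.kendallSTail <- function(s, n) {
    null <- exactKendallNull(n)
    cum <- cumsum(null$prob)          # S descending, so cum is upper tail
    vapply(s, function(si) {
        idx <- which(null$S >= si)
        if (length(idx) == 0L) 0 else cum[max(idx)]
    }, numeric(1))
}

#' Cosine rank templates over a period/phase grid
#'
#' Reference templates of the rhythm screen: a cosine of each candidate
#' period, peaking at each candidate phase, evaluated at the sampling
#' times and converted to ranks (average ranks under ties). Templates
#' with duplicate rank vectors are collapsed, keeping the first
#' (period, phase) that produced each distinct ranking.
#'
#' @param times sampling times in hours.
#' @param periods candidate periods in hours (default 20-28 h in 1-h
#'   steps, bracketing the circadian range).
#' @param interval phase step in hours; defaults to the sampling interval
#'   (the most common gap between successive times). Phases run over
#'   `seq(0, period - interval, by = interval)` per period.
#' @return list with `ranks` (templates x times matrix), `period`,
#'   `phase` (per template) and `tieCorrection` (number of tied pairs per
#'   template, for the tau-b denominator).
#' @export
cosineTemplates <- function(times, periods = 20:28, interval = NULL) {
    if (is.null(interval)) {
        gaps <- diff(sort(times))
        gaps <- gaps[gaps > 0]
        interval <- as.numeric(names(sort(table(gaps),
                                          decreasing = TRUE))[1L])
    }
    per <- pha <- numeric()
    ranks <- NULL
    for (P in periods) for (ph in seq(0, P - interval, by = interval)) {
        per <- c(per, P); pha <- c(pha, ph)
        ranks <- rbind(ranks, rank(cos(2 * pi * (times - ph) / P)))
    }
    dup <- duplicated(ranks)
    ranks <- ranks[!dup, , drop = FALSE]
    n <- length(times)
    pairs <- utils::combn(n, 2L)
    ties <- apply(ranks, 1L, function(r)
        sum(r[pairs[1L, ]] == r[pairs[2L, ]]))
    list(ranks = ranks, period = per[!dup], phase = pha[!dup],
         tieCorrection = ties)
}

# pairwise sign vectors (length n(n-1)/2) for rows of a rank matrix
.pairSigns <- function(R, pairs) {
    t(apply(R, 1L, function(r) sign(r[pairs[2L, ]] - r[pairs[1L, ]])))
}

#' Nonparametric rhythm screen via Kendall tau against cosine templates
#'
#' For every gene, the replicate-averaged log2 series is rank-correlated
#' (Kendall tau-b; tied pairs contribute zero) with each cosine rank
#' template of [cosineTemplates()], and a one-sided exact p-value per
#' template is taken from [exactKendallNull()]. The gene-level p-value
#' combines the template minimum either by the permutation null of the
#' template-maximum S statistic (default: seeded draws of random
#' permutations pushed through the same template set, which calibrates the
#' min-p statistic exactly under exchangeability) or by Bonferroni over
#' the collapsed template count (the cited screen's convention, available
#' as `pMethod = "bonferroni"`; conservative under the strongly correlated
#' template grid). Benjamini-Hochberg q-values are computed across genes.
#'
#' @param x a [TimeCourseExperiment-class], or a genes x times matrix of
#'   replicate-averaged log2 values (then `times` is required).
#' @param times sampling hours (matrix input only).
#' @param periods candidate periods, hours.
#' @param pMethod gene-level multiplicity handling, see above.
#' @param nullSamples permutation draws for `pMethod = "permutation"`.
#' @param qThreshold FDR level for the `rhythmic` flag.
#' @param replicates `"average"` (default) averages replicates per time
#'   point before ranking; `"expand"` treats each replicate as a repeated
#'   time observation (normal-approximation p-values when the expanded
#'   series exceeds 30 points).
#' @param seed RNG seed for the permutation null.
#' @return `DataFrame` with columns `geneId`, `tau`, `p`, `q`,
#'   `bestPeriod`, `bestPhase`, `rhythmic`.
#' @examples
#' tt <- c(0, seq(6, 54, by = 3))
#' y <- rbind(cos(2 * pi * (tt - 6) / 24), rnorm(18))
#' rownames(y) <- c("osc", "noise")
#' jtkScreen(y, times = tt)
#' @export
jtkScreen <- function(x, times = NULL, periods = 20:28,
                      pMethod = c("permutation", "bonferroni"),
                      nullSamples = 20000, qThreshold = 0.05,
                      replicates = c("average", "expand"), seed = 1) {
    pMethod <- match.arg(pMethod)
    replicates <- match.arg(replicates)
    if (is(x, "TimeCourseExperiment")) {
        if (replicates == "average") {
            m <- replicateMeans(x, log = TRUE)
            times <- timePoints(x)
        } else {
            m <- log2Intensities(x)
            times <- SummarizedExperiment::colData(x)$time
            ord <- order(times)
            m <- m[, ord, drop = FALSE]
            times <- times[ord]
        }
    } else {
        .assertProfileMatrix(x, "x")
        if (is.null(times))
            stop("'times' is required for a plain matrix input")
        m <- x
    }
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("G%05d", seq_len(nrow(m)))
    n <- length(times)
    tg <- cosineTemplates(times, periods = periods)
    if (ncol(tg$ranks) != n)
        stop("series length does not match the template length")
    pairs <- utils::combn(n, 2L)
    P <- ncol(pairs)
    TS <- t(.pairSigns(tg$ranks, pairs))          # P x m
    tiesT <- tg$tieCorrection

    ranks <- t(apply(m, 1L, rank))
    GS <- .pairSigns(ranks, pairs)                # genes x P
    tiesG <- rowSums(GS == 0)
    S <- GS %*% TS                                # genes x m
    denom <- sqrt(outer(P - tiesG, P - tiesT))
    tau <- S / denom

    best <- max.col(S, ties.method = "first")
    bestS <- S[cbind(seq_len(nrow(S)), best)]
    constant <- tiesG == P                        # flat series: no signal

    useExact <- n <= 30L
    templateP <- function(s) {
        if (useExact) .kendallSTail(s, n)
        else {                                    # normal approximation
            v <- n * (n - 1) * (2 * n + 5) / 18
            stats::pnorm(s - 1, mean = 0, sd = sqrt(v), lower.tail = FALSE)
        }
    }
    if (pMethod == "bonferroni") {
        minP <- templateP(bestS)
        p <- pmin(1, nrow(tg$ranks) * minP)
    } else {
        nullMax <- withSeed(seed, {
            draws <- t(vapply(seq_len(nullSamples),
                              function(i) sample.int(n), integer(n)))
            NS <- .pairSigns(draws, pairs) %*% TS
            apply(NS, 1L, max)
        })
        nullSorted <- sort(nullMax)
        exceed <- nullSamples - findInterval(bestS - 0.5, nullSorted)
        p <- (1 + exceed) / (1 + nullSamples)
    }
    p[constant] <- 1
    tau[constant, ] <- 0
    q <- bhAdjust(p)
    S4Vectors::DataFrame(
        geneId = rownames(m),
        tau = tau[cbind(seq_len(nrow(S)), best)],
        p = p, q = q,
        bestPeriod = tg$period[best],
        bestPhase = tg$phase[best],
        rhythmic = q < qThreshold,
        row.names = rownames(m))
}
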