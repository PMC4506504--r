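# Independent oracles used to validate package computations.

# Literal Benjamini-Hochberg step-up: for each p_i, the minimum over all
# p_j >= p_i of p_j * m / rank(j), capped at 1.
bruteForceBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    ranked <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m)) {
        cand <- vapply(i:m, function(j) ranked[j] * m / j, numeric(1))
        q[i] <- min(1, min(cand))
    }
    out <- numeric(m)
    out[ord] <- q
    out
}

# All permutations of 1..n (n small), as a matrix with one row each.
allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- allPermutations(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    r <- 0L
    for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
        out[r <- r + 1L, ] <- append(sub[i, ], n, after = pos - 1L)
    }
    out
}

# Kendall S (concordant minus discordant pairs) between two untied
# rankings, by direct pair enumeration.
kendallS <- function(a, b) {
    n <- length(a)
    s <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    s
}

# Exact null of S by full enumeration over all n! permutations.
enumerateKendallNull <- function(n) {
    perms <- allPermutations(n)
    s <- apply(perms, 1L, function(p) kendallS(seq_len(n), p))
    tab <- table(s)
    data.frame(S = as.integer(names(tab)),
               prob = as.vector(tab) / nrow(perms))
}

# The 18-point sampling design used throughout.
designTimes <- function() c(0, seq(6, 54, by = 3))

# Build a TimeCourseExperiment directly from per-(gene, time) replicate
# means and a per-observation log2 deviation pattern.
tceFromLog2 <- function(log2means, times, nrep = 4, dev = 0) {
    ng <- nrow(log2means)
    vals <- matrix(0, ng, length(times) * nrep)
    for (j in seq_along(times)) for (r in seq_len(nrep))
        vals[, (j - 1) * nrep + r] <- 2^(log2means[, j] + dev)
    TimeCourseExperiment(vals, times = times, nReplicates = nrep)
}
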