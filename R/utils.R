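# internal helpers shared across modules

# Run `expr` under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# zero-padded whole-hour labels ("06"), general formatting otherwise
.timeLabel <- function(t) {
    if (all(abs(t - round(t)) < 1e-9))
        sprintf("%02d", as.integer(round(t)))
    else
        format(t, trim = TRUE)
}

.assertProfileMatrix <- function(profiles, what = "profiles") {
    if (!is.matrix(profiles) || !is.numeric(profiles))
        stop("'", what, "' must be a numeric matrix (genes x time points)",
             call. = FALSE)
    if (nrow(profiles) < 1L)
        stop("'", what, "' must contain at least one profile", call. = FALSE)
    if (any(!is.finite(profiles)))
        stop("'", what, "' must be finite", call. = FALSE)
    invisible(profiles)
}

# squared Euclidean cross-distances between the rows of two matrices
.crossDist2 <- function(A, B) {
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    matrix(pmax(d2, 0), nrow(A), nrow(B))
}

.degenerateProfile <- function(id = NULL) {
    msg <- if (is.null(id)) "constant profile has zero variance"
           else sprintf("constant profile has zero variance (%s)", id)
    stop(errorCondition(msg, class = c("degenerateProfileError", "error")))
}

#' Test for the degenerate-profile condition
#'
#' [normalizeProfile()] and [estimatePeriod()] refuse constant profiles by
#' signalling a condition of class `degenerateProfileError`; this predicate
#' lets callers that sweep over many genes trap and log those cases.
#'
#' @param e a condition object.
#' @return `TRUE` if `e` is a degenerate-profile error.
#' @export
isDegenerateProfileError <- function(e) inherits(e, "degenerateProfileError")
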