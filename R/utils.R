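# Seeding helpers and small shared utilities.

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps (master seed, stream name) to a 31-bit integer so
#' that independent pipeline stages (Horn nulls, k-means restarts, SOM,
#' simulation) draw from distinct, reproducible streams.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return integer in `[0, 2^31)`.
#' @export
subSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((as.double(seed) * 48271 + h * 69621) %% 2147483647)
}

#' Evaluate an expression under a temporary seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded sub-computations do not perturb the
#' surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
runWithSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to relabelling), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjustedRand <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    n <- length(a)
    sumIJ <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expected <- sumI * sumJ / choose(n, 2)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}

# Pairwise Euclidean distance matrix (dense).
.distMatrix <- function(points) as.matrix(stats::dist(points))
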