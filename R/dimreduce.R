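# Scaling, correlation-matrix PCA, and component retention by the
# conjunction of Kaiser's criterion and Horn's parallel analysis.

#' Column-wise z-scaling of a feature table
#'
#' Centres each column to mean 0 and scales to unit standard deviation
#' (n - 1 denominator). Column means and standard deviations are kept so
#' the transform is invertible with [unscaleFeatures()].
#'
#' @param table numeric matrix, cells in rows, features in columns; no
#'   missing values.
#' @return a list of class `ScaledMatrix` with elements `values`, `center`,
#'   `scale`.
#' @export
scaleFeatures <- function(table) {
    table <- as.matrix(table)
    if (nrow(table) < 2L) stop("need at least 2 rows")
    if (anyNA(table)) stop("missing values; drop incomplete cells upstream")
    sds <- apply(table, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant feature column(s): ",
             paste(colnames(table)[sds == 0], collapse = ", "))
    z <- scale(table)
    out <- list(values = z[, , drop = FALSE],
                center = attr(z, "scaled:center"),
                scale = attr(z, "scaled:scale"))
    attributes(out$values)[c("scaled:center", "scaled:scale")] <- NULL
    class(out) <- "ScaledMatrix"
    out
}

#' @rdname scaleFeatures
#' @param scaled a `ScaledMatrix`.
#' @return `unscaleFeatures`: the original-scale matrix.
#' @export
unscaleFeatures <- function(scaled) {
    sweep(sweep(scaled$values, 2L, scaled$scale, "*"), 2L, scaled$center, "+")
}

#' Correlation-matrix PCA
#'
#' Eigendecomposition of the sample correlation matrix of a z-scaled
#' table (equivalently, PCA of the z-scores). Component signs are fixed so
#' the largest-magnitude loading of each component is positive; scores are
#' the z-scores projected on the loadings.
#'
#' @param scaled a `ScaledMatrix` from [scaleFeatures()].
#' @return list with `eigenvalues` (non-increasing, summing to the number
#'   of features), `loadings` (features x components), `scores`
#'   (cells x components).
#' @export
runPCA <- function(scaled) {
    z <- scaled$values
    if (anyNA(z) || any(!is.finite(z))) stop("non-finite input")
    if (nrow(z) <= ncol(z))
        warning("fewer rows than columns + 1; eigenvalues are degenerate")
    R <- stats::cor(z)
    eig <- eigen(R, symmetric = TRUE)
    L <- eig$vectors
    flip <- apply(L, 2L, function(v) sign(v[which.max(abs(v))]))
    L <- sweep(L, 2L, flip, "*")
    rownames(L) <- colnames(z)
    colnames(L) <- paste0("PC", seq_len(ncol(L)))
    scores <- z %*% L
    list(eigenvalues = eig$values, loadings = L, scores = scores)
}

#' Kaiser's criterion
#'
#' Number of leading correlation-matrix eigenvalues strictly greater
#' than 1.
#'
#' @param eigenvalues eigenvalues sorted non-increasing.
#' @return integer count.
#' @export
kaiserK <- function(eigenvalues) {
    stopifnot(!is.unsorted(rev(eigenvalues)))
    sum(eigenvalues > 1)
}

#' Horn's parallel analysis
#'
#' Simulates `nIter` datasets of the same shape as the input with
#' independent standard-normal entries, computes each simulation's sorted
#' correlation-matrix eigenvalues, and takes the per-rank quantile as the
#' null threshold. Returns the number of leading observed eigenvalues
#' exceeding both their rank's threshold and 1 (the criterion in use
#' retains components with eigenvalues above 1 in both this analysis and
#' Kaiser's).
#'
#' @param scaled a `ScaledMatrix` from [scaleFeatures()].
#' @param nIter number of null simulations (>= 100; default 1000).
#' @param quantile per-rank quantile of the null eigenvalues used as the
#'   threshold (default 0.95); set `useMean = TRUE` to threshold on the
#'   null mean instead.
#' @param seed integer seed for the null simulations.
#' @param useMean threshold on the mean of the null eigenvalues.
#' @return integer count with attribute `thresholds` (per-rank null
#'   thresholds) and `eigenvalues` (observed).
#' @export
hornParallel <- function(scaled, nIter = 1000L, quantile = 0.95,
                         seed = 1L, useMean = FALSE) {
    stopifnot(nIter >= 100L)
    z <- scaled$values
    n <- nrow(z); p <- ncol(z)
    obs <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    null <- matrix(0, nIter, p)
    runWithSeed(seed, {
        for (i in seq_len(nIter)) {
            sim <- matrix(stats::rnorm(n * p), n, p)
            null[i, ] <- eigen(stats::cor(sim), symmetric = TRUE,
                               only.values = TRUE)$values
        }
    })
    thr <- if (useMean) colMeans(null)
           else apply(null, 2L, stats::quantile, probs = quantile,
                      names = FALSE)
    pass <- obs > thr & obs > 1
    k <- if (all(pass)) p else which.min(pass) - 1L
    structure(as.integer(k), thresholds = thr, eigenvalues = obs)
}

#' Retain principal components by Kaiser AND Horn
#'
#' Keeps the leading run of components whose eigenvalues exceed 1
#' (Kaiser) and the Horn null threshold of their rank; retention is a
#' leading prefix, so a component is retained only if all earlier
#' components are.
#'
#' @param pcaOut result of [runPCA()].
#' @param hornK result of [hornParallel()] (its `thresholds` attribute is
#'   used when present, otherwise the count itself).
#' @param minComponents optional floor: if the conjunction retains fewer
#'   components than this, retention is raised to the floor with a warning;
#'   `NULL` (default) makes zero retained components an error.
#' @return list with `retainedK`, `kaiserK`, `hornK`, `scores` (cells x
#'   retainedK), `eigenvalues`, `loadings`.
#' @export
retainComponents <- function(pcaOut, hornK, minComponents = NULL) {
    ev <- pcaOut$eigenvalues
    kk <- kaiserK(ev)
    thr <- attr(hornK, "thresholds")
    if (!is.null(thr)) {
        pass <- ev > thr & ev > 1
        hk <- if (all(pass)) length(ev) else which.min(pass) - 1L
    } else {
        hk <- as.integer(hornK)
    }
    k <- min(kk, hk)
    if (k == 0L) {
        if (is.null(minComponents))
            stop("no components retained by Kaiser AND Horn; ",
                 "set minComponents (e.g. 2) to enforce a floor")
        warning("no components retained; flooring at ", minComponents)
        k <- as.integer(minComponents)
    } else if (!is.null(minComponents) && k < minComponents) {
        warning("retention floored at ", minComponents, " components")
        k <- as.integer(minComponents)
    }
    list(retainedK = as.integer(k), kaiserK = as.integer(kk),
         hornK = as.integer(hk),
         scores = pcaOut$scores[, seq_len(k), drop = FALSE],
         eigenvalues = ev, loadings = pcaOut$loadings)
}
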