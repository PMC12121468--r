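# Discriminant analysis of principal components: multi-class LDA on PC
# scores with cluster labels, posterior-based refinement of the partition,
# and the variable-contribution filter used for cluster characterization.

#' Fit a DAPC model
#'
#' Multi-class linear discriminant analysis on principal-component scores
#' with given cluster labels: solves the between/within scatter
#' eigenproblem for up to k - 1 discriminant axes, and computes per-cell
#' posterior cluster memberships under a Gaussian model with shared
#' within-class covariance and uniform priors. All supplied PCs are used
#' (the upstream retention step already fixed them). A singular
#' within-class scatter is ridged by 1e-8 with a message.
#'
#' @param scores cells x d matrix of retained PC scores (or retained
#'   variables' scores).
#' @param labels integer cluster labels 1..k.
#' @param k number of clusters (default `max(labels)`).
#' @return a [DAPCModel-class].
#' @export
fitDAPC <- function(scores, labels, k = max(labels)) {
    scores <- as.matrix(scores)
    labels <- as.integer(labels)
    n <- nrow(scores); d <- ncol(scores)
    stopifnot(length(labels) == n, all(labels %in% seq_len(k)))
    grand <- colMeans(scores)
    means <- .labelCenters(scores, labels, k)
    W <- matrix(0, d, d)
    for (c in seq_len(k)) {
        p <- sweep(scores[labels == c, , drop = FALSE], 2L, means[c, ])
        W <- W + crossprod(p)
    }
    W <- W / (n - k)
    if (rcond(W) < 1e-12) {
        message("within-class scatter near singular; adding ridge 1e-8")
        W <- W + diag(1e-8, d)
    }
    sizes <- tabulate(labels, k)
    B <- crossprod(sweep(means, 2L, grand) * sqrt(sizes)) / n
    # symmetric whitened eigenproblem: W^{-1/2} B W^{-1/2}
    eW <- eigen(W, symmetric = TRUE)
    Wih <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-12)),
                               d) %*% t(eW$vectors)
    M <- Wih %*% B %*% Wih
    eM <- eigen(M, symmetric = TRUE)
    nAxes <- min(k - 1L, d)
    axes <- Wih %*% eM$vectors[, seq_len(nAxes), drop = FALSE]
    # scale axes to unit within-class variance: t(a) W a = 1 already holds
    # (Wih is symmetric and eigenvectors are orthonormal); fix signs
    flip <- apply(axes, 2L, function(v) {
        s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s })
    axes <- sweep(axes, 2L, flip, "*")
    u <- scores %*% axes
    mu <- means %*% axes
    # shared covariance in discriminant space is the identity by
    # construction, so posteriors reduce to distances to class means
    d2 <- vapply(seq_len(k), function(c)
        rowSums(sweep(u, 2L, mu[c, ])^2), numeric(n))
    logp <- -0.5 * d2
    logp <- logp - apply(logp, 1L, max)
    post <- exp(logp) / rowSums(exp(logp))
    colnames(post) <- paste0("cluster", seq_len(k))
    new("DAPCModel", axes = axes, classMeans = mu, posterior = post,
        assigned = as.integer(apply(post, 1L, which.max)),
        k = as.integer(k),
        eig = eM$values[seq_len(nAxes)])
}

#' Refine a partition by DAPC posteriors
#'
#' One round of reassignment of every cell to its maximum-posterior
#' cluster; the fraction of cells that moved is reported in a message. If
#' reassignment empties a cluster, the cell with the highest posterior for
#' that cluster is kept in it, with a warning. Iterating beyond one round
#' is available via `rounds` but off by default.
#'
#' @param model a [DAPCModel-class] fitted on the same cells.
#' @param labels the labels the model was fitted with.
#' @param scores the scores the model was fitted on (needed when
#'   `rounds > 1`).
#' @param rounds number of reassignment rounds (default 1).
#' @return integer vector of refined labels.
#' @export
refinePartition <- function(model, labels, scores = NULL, rounds = 1L) {
    labels <- as.integer(labels)
    for (r in seq_len(rounds)) {
        new <- model@assigned
        for (c in seq_len(model@k)) {
            if (!any(new == c)) {
                warning("cluster ", c, " emptied by reassignment; ",
                        "keeping its closest cell")
                new[which.max(model@posterior[, c])] <- c
            }
        }
        moved <- mean(new != labels)
        message(sprintf("DAPC refinement round %d: %.1f%% of cells moved",
                        r, 100 * moved))
        labels <- new
        if (r < rounds) {
            if (is.null(scores))
                stop("scores needed to iterate refinement")
            model <- fitDAPC(scores, labels, model@k)
        }
    }
    labels
}

#' Filter variables by cluster contribution
#'
#' A feature's contribution to a cluster is the absolute mean of its
#' z-scores within that cluster. A feature is retained for cluster
#' characterization when its maximum contribution over clusters exceeds
#' `threshold` AND a Kruskal-Wallis test across clusters is significant at
#' `alpha`. Dropped features are reported in a message.
#'
#' @param zTable cells x features matrix of z-scaled features.
#' @param labels integer cluster labels.
#' @param threshold contribution threshold (default 0.7).
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @return character vector of retained feature names, with attribute
#'   `contributions` (features x clusters matrix).
#' @export
variableContributionFilter <- function(zTable, labels, threshold = 0.7,
                                       alpha = 0.05) {
    zTable <- as.matrix(zTable)
    labels <- as.integer(labels)
    k <- max(labels)
    stopifnot(k >= 2)
    contrib <- t(vapply(seq_len(ncol(zTable)), function(j)
        abs(vapply(seq_len(k), function(c)
            mean(zTable[labels == c, j]), 0)), numeric(k)))
    rownames(contrib) <- colnames(zTable)
    colnames(contrib) <- paste0("cluster", seq_len(k))
    pvals <- vapply(seq_len(ncol(zTable)), function(j) {
        if (length(unique(zTable[, j])) == 1L) return(1)
        stats::kruskal.test(zTable[, j], factor(labels))$p.value
    }, 0)
    keep <- apply(contrib, 1L, max) > threshold & pvals < alpha
    if (any(!keep))
        message("dropped feature(s): ",
                paste(colnames(zTable)[!keep], collapse = ", "))
    structure(colnames(zTable)[keep], contributions = contrib,
              pvalues = stats::setNames(pvals, colnames(zTable)))
}
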