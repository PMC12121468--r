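# Clustering in retained principal-component space: four algorithms,
# internal validation indices, k selection by index vote, and algorithm
# selection by standardized index score.

.relabel <- function(labels) {
    # relabel to 1..k in order of first appearance (deterministic)
    u <- unique(labels)
    match(labels, u)
}

#' Agglomerative hierarchical clustering
#'
#' Ward (default), average, complete or single linkage on Euclidean
#' distances; the dendrogram is retained in `extra$tree` and the tree is cut
#' at `k` clusters.
#'
#' @param points cells x d numeric matrix.
#' @param k number of clusters (`2 <= k < n`).
#' @param linkage one of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @return a [ClusterSolution-class].
#' @export
hclusterFit <- function(points, k, linkage = "ward") {
    points <- as.matrix(points)
    if (k >= nrow(points)) stop("k must be < number of points")
    stopifnot(k >= 2)
    method <- c(ward = "ward.D2", average = "average",
                complete = "complete", single = "single")[[linkage]]
    tree <- stats::hclust(stats::dist(points), method = method)
    labels <- .relabel(stats::cutree(tree, k = k))
    centers <- .labelCenters(points, labels, k)
    new("ClusterSolution", algorithm = "hierarchical", k = as.integer(k),
        labels = as.integer(labels), centers = centers,
        extra = list(tree = tree, linkage = linkage))
}

.labelCenters <- function(points, labels, k)
    do.call(rbind, lapply(seq_len(k), function(c)
        colMeans(points[labels == c, , drop = FALSE])))

#' k-means clustering, best of restarts
#'
#' Lloyd/Hartigan-Wong k-means with `nRestarts` random starts; the run with
#' the smallest total within-cluster sum of squares is kept. Deterministic
#' given `seed`.
#'
#' @inheritParams hclusterFit
#' @param nRestarts number of random restarts (default 25).
#' @param seed integer seed.
#' @return a [ClusterSolution-class].
#' @export
kmeansFit <- function(points, k, nRestarts = 25L, seed = 1L) {
    points <- as.matrix(points)
    stopifnot(k >= 2)
    fit <- runWithSeed(seed,
        stats::kmeans(points, centers = k, nstart = nRestarts,
                      iter.max = 100L))
    labels <- .relabel(fit$cluster)
    new("ClusterSolution", algorithm = "kmeans", k = as.integer(k),
        labels = as.integer(labels),
        centers = .labelCenters(points, labels, k),
        extra = list(totWithinSS = fit$tot.withinss, seed = seed))
}

#' Partitioning around medoids
#'
#' PAM (BUILD + SWAP to a local optimum) on Euclidean distances; medoids
#' are data points.
#'
#' @inheritParams hclusterFit
#' @param seed kept for interface symmetry; PAM is deterministic.
#' @return a [ClusterSolution-class].
#' @export
pamFit <- function(points, k, seed = 1L) {
    points <- as.matrix(points)
    stopifnot(k >= 2)
    fit <- cluster::pam(points, k = k, metric = "euclidean")
    labels <- .relabel(fit$clustering)
    medoids <- points[fit$id.med, , drop = FALSE]
    # reorder medoids to relabelled cluster ids
    ord <- .relabel(fit$clustering)[fit$id.med]
    medoids <- medoids[order(ord), , drop = FALSE]
    new("ClusterSolution", algorithm = "pam", k = as.integer(k),
        labels = as.integer(labels), centers = medoids,
        extra = list(medoidRows = fit$id.med,
                     cost = fit$objective[["swap"]] * nrow(points)))
}

#' Self-organizing map clustering on a 1D grid
#'
#' Online SOM with `k` units on a k x 1 grid: prototypes are initialized at
#' evenly spaced data quantiles along the first principal axis, then
#' updated over `epochs` passes with linearly decaying learning rate and
#' Gaussian neighbourhood whose radius decays linearly to 0. Cells are
#' labelled by their best-matching unit. Empty units trigger a warning and
#' are dropped from the labelling (k is reduced accordingly).
#'
#' @inheritParams kmeansFit
#' @param epochs training passes over the data (default 50).
#' @return a [ClusterSolution-class].
#' @export
somFit <- function(points, k, epochs = 50L, seed = 1L) {
    points <- as.matrix(points)
    stopifnot(k >= 2)
    n <- nrow(points)
    pc1 <- prcomp(points, center = TRUE, scale. = FALSE)$x[, 1L]
    qs <- stats::quantile(pc1, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    proto <- points[vapply(qs, function(q) which.min(abs(pc1 - q)), 1L), ,
                    drop = FALSE]
    totalSteps <- epochs * n
    step <- 0L
    runWithSeed(seed, {
        for (ep in seq_len(epochs)) {
            for (i in sample.int(n)) {
                step <- step + 1L
                frac <- 1 - step / totalSteps
                alpha <- 0.01 + 0.49 * frac
                radius <- (k / 2) * frac
                d2 <- rowSums(sweep(proto, 2L, points[i, ])^2)
                bmu <- which.min(d2)
                h <- if (radius > 0)
                    exp(-((seq_len(k) - bmu)^2) / (2 * max(radius, 1e-8)^2))
                else as.numeric(seq_len(k) == bmu)
                proto <- proto + (alpha * h) *
                    (matrix(points[i, ], k, ncol(points), byrow = TRUE) - proto)
            }
        }
    })
    d2 <- .distMatrix(rbind(proto, points))[seq_len(k), k + seq_len(n),
                                            drop = FALSE]
    bmu <- apply(d2, 2L, which.min)
    occupied <- sort(unique(bmu))
    if (length(occupied) < k)
        warning("SOM left ", k - length(occupied),
                " empty unit(s); k reduced to ", length(occupied))
    labels <- .relabel(bmu)
    kEff <- length(occupied)
    new("ClusterSolution", algorithm = "som", k = as.integer(kEff),
        labels = as.integer(labels),
        centers = .labelCenters(points, labels, kEff),
        extra = list(prototypes = proto, epochs = epochs, seed = seed))
}

#' Internal cluster-validation indices
#'
#' Computes the three clValid-style internal measures of a partition:
#' connectivity with `L` nearest neighbours (for every point, neighbour
#' rank `j` adds `1/j` when that neighbour sits in another cluster; lower
#' is better), the Dunn index (smallest between-cluster point distance
#' divided by the largest within-cluster diameter; higher is better; 0 by
#' convention when a cluster has zero diameter), and the mean silhouette
#' width (singleton clusters contribute 0).
#'
#' @param points cells x d matrix.
#' @param solution a [ClusterSolution-class] or an integer label vector.
#' @param L neighbours used by connectivity (default 10).
#' @return named numeric vector `connectivity`, `dunn`, `silhouette`.
#' @export
validationIndices <- function(points, solution, L = 10L) {
    labels <- if (is(solution, "ClusterSolution")) solution@labels
              else as.integer(solution)
    points <- as.matrix(points)
    n <- nrow(points)
    L <- min(L, n - 1L)
    D <- .distMatrix(points)
    # connectivity
    conn <- 0
    for (i in seq_len(n)) {
        nb <- order(D[i, -i])  # indices into the vector without i
        idx <- seq_len(n)[-i][nb][seq_len(L)]
        conn <- conn + sum((labels[idx] != labels[i]) / seq_len(L))
    }
    # Dunn
    k <- max(labels)
    diam <- 0; minInter <- Inf
    for (c1 in seq_len(k)) {
        inC <- labels == c1
        if (sum(inC) > 1L)
            diam <- max(diam, max(D[inC, inC]))
        for (c2 in seq_len(k)) if (c2 > c1)
            minInter <- min(minInter, min(D[inC, labels == c2]))
    }
    dunn <- if (diam == 0) {
        warning("zero within-cluster diameter; Dunn set to 0")
        0
    } else if (!is.finite(minInter)) 0 else minInter / diam
    # mean silhouette
    sil <- .silhouetteWidths(D, labels)
    c(connectivity = conn, dunn = dunn, silhouette = mean(sil))
}

.silhouetteWidths <- function(D, labels) {
    n <- nrow(D)
    k <- max(labels)
    sizes <- tabulate(labels, k)
    vapply(seq_len(n), function(i) {
        ci <- labels[i]
        if (sizes[ci] == 1L) return(0)
        a <- sum(D[i, labels == ci]) / (sizes[ci] - 1L)
        b <- min(vapply(setdiff(seq_len(k), ci), function(c2)
            mean(D[i, labels == c2]), 0))
        (b - a) / max(a, b)
    }, 0)
}

# --- index panel -----------------------------------------------------------

.wss <- function(points, labels) {
    sum(vapply(unique(labels), function(c) {
        p <- points[labels == c, , drop = FALSE]
        sum(sweep(p, 2L, colMeans(p))^2)
    }, 0))
}

.panelIndices <- function(points, labels, D) {
    n <- nrow(points); k <- max(labels)
    W <- .wss(points, labels)
    Tss <- sum(sweep(points, 2L, colMeans(points))^2)
    B <- Tss - W
    ch <- if (k > 1 && W > 0) (B / (k - 1)) / (W / (n - k)) else NA_real_
    sil <- mean(.silhouetteWidths(D, labels))
    vi <- suppressWarnings(validationIndices(points, labels))
    # Davies-Bouldin
    centers <- .labelCenters(points, labels, k)
    s <- vapply(seq_len(k), function(c) {
        p <- points[labels == c, , drop = FALSE]
        sqrt(mean(rowSums(sweep(p, 2L, centers[c, ])^2)))
    }, 0)
    db <- mean(vapply(seq_len(k), function(i) {
        max(vapply(setdiff(seq_len(k), i), function(j) {
            m <- sqrt(sum((centers[i, ] - centers[j, ])^2))
            if (m == 0) Inf else (s[i] + s[j]) / m
        }, 0))
    }, 0))
    # C-index: (S - Smin) / (Smax - Smin), S = sum of within-cluster dists
    dv <- D[upper.tri(D)]
    nw <- sum(vapply(seq_len(k), function(c) choose(sum(labels == c), 2), 0))
    same <- outer(labels, labels, "==")[upper.tri(D)]
    S <- sum(dv[same])
    sorted <- sort(dv)
    smin <- sum(sorted[seq_len(nw)])
    smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
    cindex <- if (smax > smin) (S - smin) / (smax - smin) else 0
    list(wss = W, ch = ch, silhouette = sil, dunn = vi[["dunn"]],
         db = db, cindex = cindex)
}

#' Select the number of clusters by index vote
#'
#' Fits `algorithm` at every k in `kRange` and lets a panel of eight
#' internal indices each vote for its optimal k: Calinski-Harabasz (max),
#' mean silhouette (max), Dunn (max), Davies-Bouldin (min), gap statistic
#' with uniform reference sets and the one-standard-error rule,
#' Hartigan's rule (smallest k with statistic <= 10), C-index (min) and
#' Krzanowski-Lai (max). The chosen k is the majority vote, ties broken
#' toward smaller k; a fully tied vote falls back to the silhouette's k
#' with a warning.
#'
#' @param points cells x d matrix.
#' @param kRange candidate cluster counts (default `2:8`).
#' @param algorithm algorithm used to produce candidate partitions
#'   (default `"hierarchical"`).
#' @param nRefs gap-statistic reference sets (default 50).
#' @param seed integer seed (gap references, k-means restarts).
#' @param linkage hierarchical linkage.
#' @return list with `chosenK`, `votes` (named integer), `perK` (data.frame
#'   of indices by k), `solutions` (list of [ClusterSolution-class]).
#' @export
selectK <- function(points, kRange = 2:8, algorithm = "hierarchical",
                    nRefs = 50L, seed = 1L, linkage = "ward") {
    points <- as.matrix(points)
    n <- nrow(points)
    kRange <- kRange[kRange > 1 & kRange < n]
    stopifnot(length(kRange) >= 1)
    if (length(kRange) == 1L) {
        sol <- .fitAlgorithm(points, kRange, algorithm, seed, linkage)
        return(list(chosenK = kRange, votes = stats::setNames(8L, kRange),
                    perK = NULL, solutions = stats::setNames(list(sol),
                                                             kRange)))
    }
    D <- .distMatrix(points)
    # labels for kRange plus flanking k for Hartigan / Krzanowski-Lai
    kAll <- sort(unique(c(kRange, min(kRange) - 1L, max(kRange) + 1L)))
    kAll <- kAll[kAll >= 1 & kAll < n]
    labelsOf <- list(); solutions <- list()
    for (k in kAll) {
        if (k == 1L) {
            labelsOf[[as.character(k)]] <- rep(1L, n)
        } else {
            sol <- .fitAlgorithm(points, k, algorithm, seed, linkage)
            labelsOf[[as.character(k)]] <- sol@labels
            if (k %in% kRange) solutions[[as.character(k)]] <- sol
        }
    }
    wssOf <- vapply(kAll, function(k)
        .wss(points, labelsOf[[as.character(k)]]), 0)
    names(wssOf) <- kAll
    idx <- lapply(kRange, function(k)
        .panelIndices(points, labelsOf[[as.character(k)]], D))
    perK <- data.frame(k = kRange,
                       ch = vapply(idx, `[[`, 0, "ch"),
                       silhouette = vapply(idx, `[[`, 0, "silhouette"),
                       dunn = vapply(idx, `[[`, 0, "dunn"),
                       db = vapply(idx, `[[`, 0, "db"),
                       cindex = vapply(idx, `[[`, 0, "cindex"),
                       wss = vapply(idx, `[[`, 0, "wss"))
    # gap statistic
    gap <- .gapStatistic(points, kAll, labelsOf, wssOf, nRefs,
                         subSeed(seed, "gap"), algorithm, seed, linkage)
    votes <- integer(0)
    voteFor <- function(k) { votes <<- c(votes, k) }
    voteFor(kRange[which.max(perK$ch)])
    voteFor(kRange[which.max(perK$silhouette)])
    voteFor(kRange[which.max(perK$dunn)])
    voteFor(kRange[which.min(perK$db)])
    voteFor(kRange[which.min(perK$cindex)])
    voteFor(.gapVote(gap, kRange))
    voteFor(.hartiganVote(wssOf, kRange, n))
    voteFor(.klVote(wssOf, kRange, ncol(points)))
    tab <- table(factor(votes, levels = sort(unique(kRange))))
    best <- max(tab)
    if (all(tab == best) && length(tab) > 1L) {
        warning("all candidate k tie; falling back to silhouette's k")
        chosen <- kRange[which.max(perK$silhouette)]
    } else {
        chosen <- as.integer(names(tab)[tab == best][1L])  # smallest k wins
    }
    list(chosenK = chosen,
         votes = stats::setNames(as.integer(tab), names(tab)),
         perK = perK, gap = gap, solutions = solutions)
}

.fitAlgorithm <- function(points, k, algorithm, seed, linkage = "ward") {
    switch(algorithm,
        hierarchical = hclusterFit(points, k, linkage),
        kmeans = kmeansFit(points, k, seed = subSeed(seed, "kmeans")),
        pam = pamFit(points, k),
        som = somFit(points, k, seed = subSeed(seed, "som")),
        stop("unknown algorithm: ", algorithm))
}

.gapStatistic <- function(points, kAll, labelsOf, wssOf, nRefs, seed,
                          algorithm, masterSeed, linkage) {
    n <- nrow(points); d <- ncol(points)
    lo <- apply(points, 2L, min); hi <- apply(points, 2L, max)
    logWref <- matrix(0, nRefs, length(kAll))
    runWithSeed(seed, {
        for (b in seq_len(nRefs)) {
            ref <- sapply(seq_len(d), function(j)
                stats::runif(n, lo[j], hi[j]))
            for (ki in seq_along(kAll)) {
                k <- kAll[ki]
                lab <- if (k == 1L) rep(1L, n)
                       else stats::kmeans(ref, k, nstart = 5L,
                                          iter.max = 50L)$cluster
                logWref[b, ki] <- log(.wss(ref, lab))
            }
        }
    })
    gap <- colMeans(logWref) - log(wssOf)
    se <- apply(logWref, 2L, stats::sd) * sqrt(1 + 1 / nRefs)
    data.frame(k = kAll, gap = gap, se = se)
}

.gapVote <- function(gap, kRange) {
    g <- gap$gap; s <- gap$se; ks <- gap$k
    for (i in seq_along(ks)) {
        if (!(ks[i] %in% kRange)) next
        if (i < length(ks) && g[i] >= g[i + 1L] - s[i + 1L]) return(ks[i])
    }
    kRange[which.max(g[match(kRange, ks)])]
}

.hartiganVote <- function(wssOf, kRange, n) {
    ks <- as.integer(names(wssOf))
    for (k in kRange) {
        i <- match(k, ks); j <- match(k + 1L, ks)
        if (is.na(j)) break
        H <- (wssOf[i] / wssOf[j] - 1) * (n - k - 1L)
        if (is.finite(H) && H <= 10) return(k)
    }
    max(kRange)
}

.klVote <- function(wssOf, kRange, p) {
    ks <- as.integer(names(wssOf))
    kl <- vapply(kRange, function(k) {
        im <- match(k - 1L, ks); i <- match(k, ks); ip <- match(k + 1L, ks)
        if (is.na(im) || is.na(ip)) return(NA_real_)
        diffK <- (k - 1)^(2 / p) * wssOf[im] - k^(2 / p) * wssOf[i]
        diffK1 <- k^(2 / p) * wssOf[i] - (k + 1)^(2 / p) * wssOf[ip]
        if (diffK1 == 0) return(NA_real_)
        abs(diffK / diffK1)
    }, 0)
    if (all(is.na(kl))) return(kRange[1L])
    kRange[which.max(kl)]
}

#' Select the best clustering algorithm at fixed k
#'
#' Fits each candidate algorithm at `k`, scores each with the three
#' internal validation indices, standardizes each index across candidates
#' (connectivity negated so that higher is uniformly better), and returns
#' the candidate with the highest mean standardized score together with the
#' full report.
#'
#' @param points cells x d matrix.
#' @param k number of clusters.
#' @param candidates algorithms to compare (default all four).
#' @param seed integer seed.
#' @param linkage hierarchical linkage.
#' @return list with `best` (a [ClusterSolution-class]), `report`
#'   (data.frame algorithm x indices + meanScore), `solutions`.
#' @export
selectAlgorithm <- function(points, k,
                            candidates = c("hierarchical", "kmeans",
                                           "pam", "som"),
                            seed = 1L, linkage = "ward") {
    points <- as.matrix(points)
    solutions <- lapply(candidates, function(a)
        .fitAlgorithm(points, k, a, seed, linkage))
    names(solutions) <- candidates
    idx <- t(vapply(solutions, function(s)
        suppressWarnings(validationIndices(points, s)), numeric(3)))
    signed <- idx
    signed[, "connectivity"] <- -signed[, "connectivity"]
    z <- apply(signed, 2L, function(v) {
        s <- stats::sd(v)
        if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    meanScore <- rowMeans(z)
    report <- data.frame(algorithm = candidates, idx,
                         meanScore = meanScore, row.names = NULL)
    best <- solutions[[which.max(meanScore)]]
    list(best = best, report = report, solutions = solutions)
}
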