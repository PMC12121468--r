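# Fixtures built in code and independent oracle implementations used to
# cross-check the package's algorithms.

makeSkeleton <- function(mat, cellId = "fix") {
    nd <- as.data.frame(mat)
    names(nd) <- c("id", "type", "x", "y", "z", "radius", "parent")
    AstrocyteSkeleton(nd, cellId = cellId)
}

# straight radial arm of `n` segments of length `step` along direction v
.armRows <- function(startId, parentId, v, n, step = 1, r = 0.5) {
    v <- v / sqrt(sum(v^2))
    t(sapply(seq_len(n), function(i)
        c(startId + i - 1, 3, i * step * v[1], i * step * v[2],
          i * step * v[3], r,
          if (i == 1) parentId else startId + i - 2)))
}

# k straight 20-um arms from a soma at the origin
starSkeleton <- function(k = 5, armLength = 20) {
    dirs <- cbind(cos(2 * pi * seq_len(k) / k), sin(2 * pi * seq_len(k) / k),
                  0)
    rows <- list(c(1, 1, 0, 0, 0, 2, -1))
    nid <- 2
    for (i in seq_len(k)) {
        rows[[i + 1]] <- .armRows(nid, 1, dirs[i, ], armLength)
        nid <- nid + armLength
    }
    makeSkeleton(do.call(rbind, rows), "star")
}

# one stem to (5,0,0) bifurcating into two arms reaching radius 15
ySkeleton <- function() {
    stem <- .armRows(2, 1, c(1, 0, 0), 5)
    a1 <- t(sapply(1:11, function(i)
        c(6 + i, 3, 5 + i * 10 / 11 * cos(0.3), i * 10 / 11 * sin(0.3), 0,
          0.5, if (i == 1) 6 else 5 + i)))
    a2 <- t(sapply(1:11, function(i)
        c(17 + i, 3, 5 + i * 10 / 11 * cos(0.3), -i * 10 / 11 * sin(0.3), 0,
          0.5, if (i == 1) 6 else 16 + i)))
    makeSkeleton(rbind(c(1, 1, 0, 0, 0, 2, -1), stem, a1, a2), "y")
}

# 4 primaries each bifurcating once at 5 um into two arms reaching 15 um
fourBifSkeleton <- function() {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    rows <- list(c(1, 1, 0, 0, 0, 2, -1))
    nid <- 2
    for (i in 1:4) {
        v <- dirs[i, ]
        stem <- .armRows(nid, 1, v, 5)
        bifNode <- nid + 4
        perp <- if (abs(v[1]) > 0) c(0, 0, 1) else c(0, 0, 1)
        rows[[length(rows) + 1]] <- stem
        nid <- nid + 5
        for (sgn in c(-1, 1)) {
            # daughter from (5v) outward to radius 15: direction mixes v and z
            dd <- (v + sgn * 0.35 * perp)
            dd <- dd / sqrt(sum(dd^2))
            arm <- t(sapply(1:11, function(j) {
                pos <- 5 * v + j * (10.8 / 11) * dd
                c(nid + j - 1, 3, pos[1], pos[2], pos[3], 0.4,
                  if (j == 1) bifNode else nid + j - 2)
            }))
            rows[[length(rows) + 1]] <- arm
            nid <- nid + 11
        }
    }
    makeSkeleton(do.call(rbind, rows), "fourbif")
}

# Dense-resampling Sholl oracle: sample every process segment at `ds`
# arc-length steps and count transitions of the indicator d >= r along the
# sampled path of each segment, for every integer sphere radius.
denseShollOracle <- function(skeleton, ds = 0.001) {
    nd <- skeletonNodes(skeleton)
    centre <- unlist(nd[1, c("x", "y", "z")])
    child <- which(nd$parent != -1)
    parent <- match(nd$parent[child], nd$id)
    keep <- !(nd$type[child] == 1 & nd$type[parent] == 1)
    child <- child[keep]; parent <- parent[keep]
    dAll <- sqrt((nd$x - centre[1])^2 + (nd$y - centre[2])^2 +
                 (nd$z - centre[3])^2)
    rmaxGuess <- ceiling(max(dAll)) + 1
    counts <- integer(rmaxGuess)
    for (i in seq_along(child)) {
        p0 <- unlist(nd[parent[i], c("x", "y", "z")]) - centre
        p1 <- unlist(nd[child[i], c("x", "y", "z")]) - centre
        len <- sqrt(sum((p1 - p0)^2))
        ts <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
        pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
        d <- sqrt(rowSums(pts^2))
        for (r in seq.int(max(1L, floor(min(d))),
                          min(rmaxGuess, ceiling(max(d))))) {
            inside <- d >= r - 1e-12
            counts[r] <- counts[r] + sum(diff(inside) != 0L)
        }
    }
    rmax <- max(which(counts > 0L), 0L)
    counts[seq_len(rmax)]
}

# Branch-depth oracle: a branch starts on every process edge leaving the
# soma or a branching point; its depth is the number of branching points
# on the explicit parent-walk from its start node to the root (the start
# node included when it is itself a branching point, the root never).
# Returns the sorted multiset of branch depths.
branchDepthOracle <- function(skeleton) {
    nd <- skeletonNodes(skeleton)
    child <- which(nd$parent != -1)
    parent <- match(nd$parent[child], nd$id)
    keep <- !(nd$type[child] == 1 & nd$type[parent] == 1)
    nKids <- tabulate(parent[keep], nbins = nrow(nd))
    isBP <- nd$type != 1 & nKids >= 2
    parentRow <- rep(NA_integer_, nrow(nd))
    parentRow[child[keep]] <- parent[keep]
    origins <- which((nd$type == 1 | isBP) & nKids > 0)
    depths <- integer(0)
    for (o in origins) {
        nBranches <- nKids[o]
        d <- 0L
        node <- o
        while (!is.na(node)) {
            if (isBP[node]) d <- d + 1L
            node <- parentRow[node]
        }
        depths <- c(depths, rep(d, nBranches))
    }
    sort(depths)
}

# Naive O(n^3) Ward agglomeration on centroids: repeatedly merge the pair
# with the smallest increase in within-cluster SS.
naiveWard <- function(points, k) {
    n <- nrow(points)
    clusters <- lapply(seq_len(n), identity)
    repeat {
        m <- length(clusters)
        if (m == k) break
        best <- c(Inf, 0, 0)
        for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
            a <- points[clusters[[i]], , drop = FALSE]
            b <- points[clusters[[j]], , drop = FALSE]
            ca <- colMeans(a); cb <- colMeans(b)
            cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
                sum((ca - cb)^2)
            if (cost < best[1]) best <- c(cost, i, j)
        }
        i <- best[2]; j <- best[3]
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        clusters[[j]] <- NULL
    }
    labels <- integer(n)
    for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
    labels
}

# exhaustive best 2-partition by within-cluster SS (n small)
bestTwoPartitionWSS <- function(points) {
    n <- nrow(points)
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
        lab <- as.integer(intToBits(code))[1:n]
        if (all(lab == 0) || all(lab == 1)) next
        w <- 0
        for (c in 0:1) {
            p <- points[lab == c, , drop = FALSE]
            w <- w + sum(sweep(p, 2, colMeans(p))^2)
        }
        best <- min(best, w)
    }
    best
}

# exhaustive best medoid pair by total distance to closest medoid
bestPamCost <- function(points, k = 2) {
    D <- as.matrix(dist(points))
    n <- nrow(points)
    best <- Inf
    combs <- combn(n, k)
    for (j in seq_len(ncol(combs))) {
        cost <- sum(apply(D[, combs[, j], drop = FALSE], 1, min))
        best <- min(best, cost)
    }
    best
}

# definitional (independent) implementations of the validation indices
defConnectivity <- function(points, labels, L = 10) {
    D <- as.matrix(dist(points))
    n <- nrow(points)
    total <- 0
    for (i in seq_len(n)) {
        ord <- setdiff(order(D[i, ]), i)
        for (j in seq_len(min(L, n - 1)))
            if (labels[ord[j]] != labels[i]) total <- total + 1 / j
    }
    total
}
defDunn <- function(points, labels) {
    D <- as.matrix(dist(points))
    inter <- Inf; diam <- 0
    n <- nrow(points)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        if (labels[i] == labels[j]) diam <- max(diam, D[i, j])
        else inter <- min(inter, D[i, j])
    }
    if (diam == 0) 0 else inter / diam
}

# explicit sums-of-squares nested ANOVA (balanced designs)
nestedAnovaOracle <- function(values, genotype, mouse) {
    grand <- mean(values)
    g <- split(values, genotype)
    ssG <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
    byMouse <- split(values, mouse)
    mouseGeno <- vapply(split(as.character(genotype), mouse),
                        function(x) x[1], "")
    ssM <- sum(vapply(names(byMouse), function(m) {
        v <- byMouse[[m]]
        length(v) * (mean(v) - mean(g[[mouseGeno[m]]]))^2
    }, 0))
    ssE <- sum(vapply(byMouse, function(v) sum((v - mean(v))^2), 0))
    gN <- length(g); mN <- length(byMouse); N <- length(values)
    msG <- ssG / (gN - 1); msM <- ssM / (mN - gN)
    list(F = msG / msM, df = c(gN - 1, mN - gN),
         ss = c(genotype = ssG, mouse = ssM, residual = ssE),
         p = pf(msG / msM, gN - 1, mN - gN, lower.tail = FALSE))
}

# small deterministic blob generator
blobs <- function(centers, nPer, sd = 0.5, seed = 1) {
    set.seed(seed)
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
        matrix(rnorm(nPer * ncol(centers), sd = sd), nPer) +
            matrix(centers[i, ], nPer, ncol(centers), byrow = TRUE)))
    list(points = pts, labels = rep(seq_len(nrow(centers)), each = nPer))
}
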