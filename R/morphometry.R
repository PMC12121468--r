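# Per-cell morphometry: 3D Sholl curve, branch decomposition, and the
# ten-feature morphological profile.

# Edge table of a skeleton: child row index, parent row index, flags.
# Soma-to-soma edges are internal to the soma and excluded from process
# measures; an edge leaving the soma (soma parent, process child) counts.
.edges <- function(skeleton) {
    nd <- skeleton@nodes
    child <- which(nd$parent != -1L)
    parent <- match(nd$parent[child], nd$id)
    somaEdge <- nd$type[child] == 1L & nd$type[parent] == 1L
    list(nodes = nd, child = child, parent = parent, process = !somaEdge)
}

#' Compute the 3D Sholl intersection curve of a skeleton
#'
#' Counts intersections of process segments with concentric spheres of
#' radius `step, 2*step, ...` centred on the root soma node. Each straight
#' segment between consecutive nodes (soma-to-soma segments excluded) whose
#' endpoint distances to the centre straddle a sphere radius contributes one
#' crossing; the half-open rule `min(d) < r <= max(d)` makes a sphere
#' passing exactly through a node count once. The curve ends at the largest
#' radius with a non-zero count; a soma-only cell yields an empty curve.
#'
#' @param skeleton an [AstrocyteSkeleton-class].
#' @param step sphere spacing in micrometres (default 1).
#' @return a [ShollCurve-class].
#' @examples
#' sk <- simulateSkeleton(morphotypeParams("medium"), seed = 7)
#' shollCurve(sk)
#' @export
shollCurve <- function(skeleton, step = 1) {
    stopifnot(is(skeleton, "AstrocyteSkeleton"), step > 0)
    e <- .edges(skeleton)
    nd <- e$nodes
    centre <- c(nd$x[1L], nd$y[1L], nd$z[1L])
    d <- sqrt((nd$x - centre[1])^2 + (nd$y - centre[2])^2 +
              (nd$z - centre[3])^2)
    ci <- e$child[e$process]
    pi_ <- e$parent[e$process]
    if (length(ci) == 0L)
        return(new("ShollCurve", radii = numeric(0), counts = integer(0),
                   cellId = skeleton@cellId))
    lo <- pmin(d[ci], d[pi_])
    hi <- pmax(d[ci], d[pi_])
    # index of last sphere at or below a distance: floor(d / step) with a
    # tolerance so exact hits land on their sphere
    kLo <- floor(lo / step + 1e-9)
    kHi <- floor(hi / step + 1e-9)
    nSphere <- max(kHi)
    if (nSphere == 0L)
        return(new("ShollCurve", radii = numeric(0), counts = integer(0),
                   cellId = skeleton@cellId))
    counts <- integer(nSphere)
    cross <- kHi > kLo
    if (any(cross)) {
        # each crossing edge increments spheres kLo+1 .. kHi
        add <- tabulate(unlist(mapply(function(a, b) seq.int(a + 1L, b),
                                      kLo[cross], kHi[cross],
                                      SIMPLIFY = FALSE)),
                        nbins = nSphere)
        counts <- counts + add
    }
    rmax <- max(which(counts > 0L), 0L)
    counts <- counts[seq_len(rmax)]
    new("ShollCurve", radii = step * seq_len(rmax),
        counts = as.integer(counts), cellId = skeleton@cellId)
}

#' Decompose a skeleton into branches
#'
#' A branch is a maximal path of process edges between consecutive
#' topological nodes: the soma, a branching point (a non-soma node with at
#' least two children), or a terminal. For every branch the decomposition
#' reports its depth (number of branching points on the root path up to and
#' including the branch's start node; the soma root is never a branching
#' point, so primary branches have depth 0), its level (depth + 1), and its
#' length (sum of Euclidean segment lengths along the branch).
#'
#' @param skeleton an [AstrocyteSkeleton-class].
#' @return data.frame with columns `depth`, `level`, `length`, one row per
#'   branch (zero rows for a soma-only cell).
#' @export
branchDecomposition <- function(skeleton) {
    stopifnot(is(skeleton, "AstrocyteSkeleton"))
    e <- .edges(skeleton)
    nd <- e$nodes
    n <- nrow(nd)
    # children along process edges only
    kids <- vector("list", n)
    pe <- which(e$process)
    for (i in pe) kids[[e$parent[i]]] <- c(kids[[e$parent[i]]], e$child[i])
    # soma-internal edges connect soma nodes; process branches may start at
    # any soma node, all treated as origins at depth 0
    isSoma <- nd$type == 1L
    nKids <- lengths(kids)
    isBranchPt <- !isSoma & nKids >= 2L
    segLen <- function(a, b)
        sqrt((nd$x[a] - nd$x[b])^2 + (nd$y[a] - nd$y[b])^2 +
             (nd$z[a] - nd$z[b])^2)
    out <- list()
    # stack of (startNode, firstChild, depth)
    starts <- list()
    for (s in which(isSoma & nKids > 0L))
        for (c0 in kids[[s]])
            starts[[length(starts) + 1L]] <- c(s, c0, 0L)
    while (length(starts)) {
        st <- starts[[length(starts)]]
        starts[[length(starts)]] <- NULL
        node <- st[1L]; nxt <- st[2L]; depth <- st[3L]
        len <- 0
        repeat {
            len <- len + segLen(node, nxt)
            node <- nxt
            if (isBranchPt[node] || nKids[node] == 0L) break
            nxt <- kids[[node]][1L]
        }
        out[[length(out) + 1L]] <- c(depth, len)
        if (isBranchPt[node])
            for (c0 in kids[[node]])
                starts[[length(starts) + 1L]] <- c(node, c0, depth + 1L)
    }
    if (length(out) == 0L)
        return(data.frame(depth = integer(0), level = integer(0),
                          length = numeric(0)))
    m <- do.call(rbind, out)
    data.frame(depth = as.integer(m[, 1]), level = as.integer(m[, 1]) + 1L,
               length = m[, 2])
}

#' Names of the ten morphometric features
#'
#' The ten per-cell features used by the clustering model, in canonical
#' order.
#' @return character vector of length 10.
#' @export
morphometryFeatures <- function() {
    c("soma_diameter", "total_process_length", "branch_depth_median",
      "branch_level_median", "n_branches", "n_branching_points",
      "sholl_median", "sholl_peak_count", "n_primary_branches",
      "ramification_index")
}

#' Extract the morphometric profile of one cell
#'
#' Computes the ten morphological features of a skeleton:
#' soma diameter (twice the root radius unless a measured value is
#' supplied), total process length (sum of non-soma segment lengths),
#' median branch depth and level across branches, number of branches,
#' number of branching points (non-soma nodes with >= 2 children; the soma
#' root is not a branching point even with several primary processes),
#' median and peak of the 1-um Sholl curve (median over radii 1..Rmax, peak
#' ties broken toward the smallest radius), the number of primary branches
#' estimated as the Sholl count at radius 1 um, and the ramification index
#' (Sholl peak count / primary branches; `NA` with a warning when there are
#' no primary branches). `sholl_peak_radius` is reported alongside.
#'
#' @param skeleton an [AstrocyteSkeleton-class].
#' @param somaDiameter optional measured soma diameter (micrometres)
#'   overriding the root-radius-derived value.
#' @return one-row data.frame with the ten features plus
#'   `sholl_peak_radius` and `cell_id`.
#' @export
extractProfile <- function(skeleton, somaDiameter = NA_real_) {
    stopifnot(is(skeleton, "AstrocyteSkeleton"))
    nd <- skeleton@nodes
    e <- .edges(skeleton)
    pe <- which(e$process)
    segLen <- sqrt((nd$x[e$child[pe]] - nd$x[e$parent[pe]])^2 +
                   (nd$y[e$child[pe]] - nd$y[e$parent[pe]])^2 +
                   (nd$z[e$child[pe]] - nd$z[e$parent[pe]])^2)
    br <- branchDecomposition(skeleton)
    nKids <- tabulate(e$parent[pe], nbins = nrow(nd))
    nBranchPts <- sum(nd$type != 1L & nKids >= 2L)
    sc <- shollCurve(skeleton, step = 1)
    counts <- sc@counts
    if (length(counts)) {
        shollMedian <- stats::median(counts)
        peak <- max(counts)
        peakRadius <- sc@radii[which.max(counts)]
        nPrimary <- counts[1L]
    } else {
        shollMedian <- 0; peak <- 0L; peakRadius <- NA_real_; nPrimary <- 0L
    }
    if (nPrimary > 0L) {
        ri <- peak / nPrimary
    } else {
        if (length(counts))
            warning("cell '", skeleton@cellId,
                    "': no intersections at radius 1 um; ",
                    "ramification index undefined")
        ri <- NA_real_
    }
    data.frame(
        cell_id = skeleton@cellId,
        soma_diameter = if (is.na(somaDiameter)) 2 * nd$radius[1L]
                        else somaDiameter,
        total_process_length = sum(segLen),
        branch_depth_median = if (nrow(br)) stats::median(br$depth) else 0,
        branch_level_median = if (nrow(br)) stats::median(br$level) else 0,
        n_branches = nrow(br),
        n_branching_points = nBranchPts,
        sholl_median = shollMedian,
        sholl_peak_count = as.integer(peak),
        n_primary_branches = as.integer(nPrimary),
        ramification_index = ri,
        sholl_peak_radius = peakRadius,
        stringsAsFactors = FALSE)
}

#' Extract profiles for a whole cohort
#'
#' Runs [extractProfile()] on every cell of a cohort (as returned by
#' [loadCohort()] or [simulateCohort()]) and assembles a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay `"morphometry"` (features x cells, the ten features plus
#' `sholl_peak_radius`), the cohort metadata as `colData`, and the per-cell
#' [ShollCurve-class] objects in `metadata(se)$sholl`.
#'
#' @param cohort list with `skeletons` and `metadata` (with a `cell_id`
#'   column aligned to the skeletons), e.g. from [loadCohort()].
#' @return a `SummarizedExperiment`.
#' @export
extractProfiles <- function(cohort) {
    sk <- cohort$skeletons
    md <- cohort$metadata
    stopifnot(length(sk) == nrow(md))
    sd <- if ("soma_diameter" %in% names(md)) md$soma_diameter
          else rep(NA_real_, length(sk))
    rows <- mapply(extractProfile, sk, sd, SIMPLIFY = FALSE)
    tab <- do.call(rbind, rows)
    featCols <- c(morphometryFeatures(), "sholl_peak_radius")
    assay <- t(as.matrix(tab[, featCols]))
    colnames(assay) <- tab$cell_id
    sholl <- lapply(sk, shollCurve)
    names(sholl) <- tab$cell_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(morphometry = assay),
        colData = S4Vectors::DataFrame(md, row.names = tab$cell_id))
    S4Vectors::metadata(se)$sholl <- sholl
    se
}

#' Feature table of a profiled cohort
#'
#' Returns the cells x features matrix of the ten clustering features from
#' a `SummarizedExperiment` produced by [extractProfiles()].
#'
#' @param se a `SummarizedExperiment` from [extractProfiles()].
#' @param dropIncomplete drop cells with an undefined ramification index
#'   (logged); default `TRUE`.
#' @return numeric matrix, cells in rows.
#' @export
featureTable <- function(se, dropIncomplete = TRUE) {
    m <- t(SummarizedExperiment::assay(se, "morphometry")[
        morphometryFeatures(), , drop = FALSE])
    if (dropIncomplete && anyNA(m)) {
        bad <- apply(is.na(m), 1L, any)
        message("dropping ", sum(bad),
                " cell(s) with incomplete profiles")
        m <- m[!bad, , drop = FALSE]
    }
    m
}
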