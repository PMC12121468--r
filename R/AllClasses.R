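#' @import methods
NULL

#' AstrocyteSkeleton: a rooted 3D cell skeleton
#'
#' An `AstrocyteSkeleton` holds the node table of one reconstructed astrocyte
#' in SWC convention: node id, structure type code (1 = soma, any other code
#' a process), 3D position in micrometres, node radius in micrometres, and
#' parent id (-1 for the root).  The node table is kept in topological order
#' (every parent precedes its children), the parent relation must form a
#' single rooted tree, and the root must be a soma-type node.  Multi-node
#' somas (several contiguous type-1 nodes) are permitted; the root type-1
#' node is taken as the soma centre.
#'
#' @slot nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @slot cellId single character identifier of the cell.
#'
#' @seealso [readSWC()], [writeSWC()], [shollCurve()], [extractProfile()]
#' @export
setClass("AstrocyteSkeleton",
    representation(nodes = "data.frame", cellId = "character"))

.validSkeleton <- function(object) {
    nd <- object@nodes
    need <- c("id", "type", "x", "y", "z", "radius", "parent")
    if (!all(need %in% names(nd)))
        return(sprintf("node table must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(nd) == 0L) return("skeleton has no nodes")
    if (anyDuplicated(nd$id)) return("duplicate node id")
    if (any(!is.finite(nd$radius)) || any(nd$radius <= 0))
        return("radius must be positive")
    if (any(!is.finite(c(nd$x, nd$y, nd$z))))
        return("non-finite coordinate")
    rootIdx <- which(nd$parent == -1L)
    if (length(rootIdx) == 0L) return("no root (parent -1) node")
    if (length(rootIdx) > 1L) return("more than one root node")
    if (nd$type[rootIdx] != 1L) return("root node is not soma type (1)")
    nonroot <- nd$parent != -1L
    if (!all(nd$parent[nonroot] %in% nd$id)) return("missing parent")
    # topological order implies acyclicity; check parent precedes child
    pos <- match(nd$parent[nonroot], nd$id)
    if (any(pos >= which(nonroot))) return("cycle or non-topological order")
    if (length(object@cellId) != 1L) return("cellId must be length 1")
    TRUE
}
setValidity("AstrocyteSkeleton", .validSkeleton)

#' @describeIn AstrocyteSkeleton construct and validate a skeleton from a
#'   node table; rows are topologically sorted (parents before children)
#'   before validation.
#' @param nodes node data.frame (see slots).
#' @param cellId cell identifier.
#' @export
AstrocyteSkeleton <- function(nodes, cellId = "cell") {
    nodes <- .topoSortNodes(nodes)
    new("AstrocyteSkeleton", nodes = nodes, cellId = as.character(cellId))
}

# Kahn-style topological sort of an SWC node table; errors on cycles or
# missing parents so validity failures carry a usable message.
.topoSortNodes <- function(nd) {
    nd$id <- as.integer(nd$id)
    nd$type <- as.integer(nd$type)
    nd$parent <- as.integer(nd$parent)
    rootIdx <- which(nd$parent == -1L)
    if (length(rootIdx) != 1L) return(nd)  # leave for validity to report
    if (!all(nd$parent[-rootIdx] %in% nd$id))
        stop("missing parent: node(s) ",
             paste(nd$id[-rootIdx][!(nd$parent[-rootIdx] %in% nd$id)],
                   collapse = ", "), " reference absent parent ids")
    childIdx <- split(seq_len(nrow(nd)), factor(nd$parent, levels = nd$id))
    order <- integer(nrow(nd))
    order[1L] <- rootIdx
    head <- 1L; tail <- 1L
    while (head <= tail) {
        kids <- childIdx[[match(nd$id[order[head]], nd$id)]]
        if (length(kids)) {
            order[(tail + 1L):(tail + length(kids))] <- kids
            tail <- tail + length(kids)
        }
        head <- head + 1L
    }
    if (tail != nrow(nd))
        stop("cycle: ", nrow(nd) - tail,
             " node(s) unreachable from the root")
    nd <- nd[order, , drop = FALSE]
    rownames(nd) <- NULL
    nd
}

setMethod("show", "AstrocyteSkeleton", function(object) {
    nd <- object@nodes
    cat("AstrocyteSkeleton '", object@cellId, "': ", nrow(nd), " nodes (",
        sum(nd$type == 1L), " soma), extent ",
        sprintf("%.1f", max(sqrt((nd$x - nd$x[1])^2 + (nd$y - nd$y[1])^2 +
                                 (nd$z - nd$z[1])^2))),
        " um from root\n", sep = "")
})

#' @describeIn AstrocyteSkeleton accessor for the node table.
#' @param x an `AstrocyteSkeleton`.
#' @export
skeletonNodes <- function(x) x@nodes

#' @describeIn AstrocyteSkeleton accessor for the cell identifier.
#' @export
cellId <- function(x) x@cellId

#' ShollCurve: intersections with concentric spheres
#'
#' Counts of process intersections with spheres of radius `step, 2*step,
#' ..., Rmax` centred on the soma root.  `Rmax` is the largest radius with a
#' non-zero count; a soma-only cell has an empty curve.
#'
#' @slot radii numeric, the arithmetic radius sequence (micrometres).
#' @slot counts integer intersection count per radius.
#' @slot cellId character cell identifier.
#' @export
setClass("ShollCurve",
    representation(radii = "numeric", counts = "integer", cellId = "character"))

setValidity("ShollCurve", function(object) {
    if (length(object@radii) != length(object@counts))
        return("radii and counts lengths differ")
    if (any(object@counts < 0L)) return("negative count")
    n <- length(object@counts)
    if (n > 0L && object@counts[n] < 1L)
        return("curve must end at the last non-zero radius")
    TRUE
})

setMethod("show", "ShollCurve", function(object) {
    n <- length(object@radii)
    if (n == 0L) {
        cat("ShollCurve '", object@cellId, "': no processes\n", sep = "")
    } else {
        cat("ShollCurve '", object@cellId, "': Rmax ", object@radii[n],
            " um, peak ", max(object@counts), " at r = ",
            object@radii[which.max(object@counts)], " um\n", sep = "")
    }
})

#' @describeIn ShollCurve accessor for the radius sequence.
#' @param x a `ShollCurve`.
#' @export
shollRadii <- function(x) x@radii

#' @describeIn ShollCurve accessor for the intersection counts.
#' @export
shollCounts <- function(x) x@counts

#' ClusterSolution: one clustering of cells
#'
#' @slot algorithm one of `"hierarchical"`, `"kmeans"`, `"pam"`, `"som"`.
#' @slot k number of clusters.
#' @slot labels integer cluster id per cell, covering `1..k` with no empty
#'   cluster.
#' @slot centers cluster centroid/medoid coordinates (k x d), or a 0-row
#'   matrix when not applicable.
#' @slot extra list of algorithm extras (e.g. the `hclust` tree, SOM
#'   prototypes, seeds).
#' @export
setClass("ClusterSolution",
    representation(algorithm = "character", k = "integer",
                   labels = "integer", centers = "matrix", extra = "list"))

setValidity("ClusterSolution", function(object) {
    if (!object@algorithm %in% c("hierarchical", "kmeans", "pam", "som"))
        return("unknown algorithm")
    tab <- tabulate(object@labels, nbins = object@k)
    if (any(object@labels < 1L) || any(object@labels > object@k))
        return("labels outside 1..k")
    if (any(tab == 0L)) return("empty cluster")
    TRUE
})

setMethod("show", "ClusterSolution", function(object) {
    cat("ClusterSolution: ", object@algorithm, ", k = ", object@k,
        ", sizes ", paste(tabulate(object@labels, object@k), collapse = "/"),
        "\n", sep = "")
})

#' @describeIn ClusterSolution accessor for the per-cell cluster labels.
#' @param x a `ClusterSolution`.
#' @export
clusterLabels <- function(x) x@labels

#' DAPCModel: discriminant analysis of principal components
#'
#' Linear discriminant analysis fitted on principal-component scores with
#' cluster labels as classes: up to k - 1 discriminant axes from the
#' between/within scatter eigenproblem, and per-cell posterior cluster
#' membership under a shared within-class covariance with uniform priors.
#'
#' @slot axes loadings of the discriminant axes in PC space (d x (k-1)).
#' @slot classMeans class means in discriminant space (k x (k-1)).
#' @slot posterior cells x k posterior membership matrix (rows sum to 1).
#' @slot assigned integer maximum-posterior cluster per cell.
#' @slot k number of clusters.
#' @slot eig discriminant eigenvalues (between/within variance ratios).
#' @export
setClass("DAPCModel",
    representation(axes = "matrix", classMeans = "matrix",
                   posterior = "matrix", assigned = "integer",
                   k = "integer", eig = "numeric"))

setValidity("DAPCModel", function(object) {
    if (nrow(object@posterior) != length(object@assigned))
        return("posterior rows != assigned length")
    if (ncol(object@posterior) != object@k) return("posterior cols != k")
    rs <- rowSums(object@posterior)
    if (any(abs(rs - 1) > 1e-9)) return("posterior rows must sum to 1")
    TRUE
})

setMethod("show", "DAPCModel", function(object) {
    cat("DAPCModel: ", object@k, " clusters, ", ncol(object@axes),
        " discriminant axes, ", length(object@assigned), " cells\n", sep = "")
})

#' @describeIn DAPCModel accessor for the posterior membership matrix.
#' @param x a `DAPCModel`.
#' @export
dapcPosterior <- function(x) x@posterior

#' @describeIn DAPCModel accessor for the maximum-posterior assignments.
#' @export
dapcAssigned <- function(x) x@assigned
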