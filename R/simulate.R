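# Stochastic branching-process simulator for astrocyte skeletons and
# cohorts with known morphotype / genotype / mouse structure.

#' Morphotype growth parameters
#'
#' Parameters of the stochastic branching process that grows one synthetic
#' astrocyte skeleton. Three named archetypes of graded branching
#' complexity are provided (`"simple"`, `"medium"`, `"complex"`); their
#' generated feature distributions are ordered in the number of branches,
#' branching points and ramification index.
#'
#' @param archetype one of `"simple"`, `"medium"`, `"complex"`, or `NULL`
#'   to use the explicit parameters.
#' @param nPrimary mean number of primary processes (Poisson, floored
#'   at 2).
#' @param branchRate bifurcations per micrometre of process path
#'   (inter-bifurcation distances are gamma-distributed with shape 8 and
#'   mean `1/branchRate`).
#' @param segmentStep growth step (micrometres).
#' @param meanBranchLength mean total path length of a branch before
#'   terminating (micrometres; gamma-distributed with shape 8).
#' @param territoryRadius growth stops at this distance from the soma
#'   (micrometres; hippocampal astrocytes tile at roughly this scale).
#' @param tortuosity sd of the per-step angular perturbation (radians).
#' @param somaRadius soma radius (micrometres).
#' @param taper per-step fractional radius decay (floor 0.1 um).
#' @param cellJitter sd of the per-cell log-normal jitter applied at
#'   growth time to the territory radius and branching rate (and, doubled,
#'   to the soma radius), emulating biological cell-to-cell variability.
#' @return list of class `MorphotypeParams`.
#' @export
morphotypeParams <- function(archetype = NULL,
                             nPrimary = 5, branchRate = 0.05,
                             segmentStep = 1, meanBranchLength = 25,
                             territoryRadius = 40, tortuosity = 0.25,
                             somaRadius = 3, taper = 0.02,
                             cellJitter = 0.05) {
    if (!is.null(archetype)) {
        preset <- switch(archetype,
            simple = list(nPrimary = 3, branchRate = 0.004,
                          meanBranchLength = 9, territoryRadius = 15,
                          somaRadius = 2.2),
            medium = list(nPrimary = 6, branchRate = 0.03,
                          meanBranchLength = 30, territoryRadius = 46,
                          somaRadius = 4.6),
            complex = list(nPrimary = 12, branchRate = 0.1,
                           meanBranchLength = 24, territoryRadius = 30,
                           somaRadius = 2.8),
            stop("unknown archetype: ", archetype))
        for (nm in names(preset)) assign(nm, preset[[nm]])
    }
    p <- list(nPrimary = nPrimary, branchRate = branchRate,
              segmentStep = segmentStep,
              meanBranchLength = meanBranchLength,
              territoryRadius = territoryRadius, tortuosity = tortuosity,
              somaRadius = somaRadius, taper = taper,
              cellJitter = cellJitter,
              archetype = if (is.null(archetype)) "custom" else archetype)
    stopifnot(all(vapply(p[c(1, 3:8)], function(v) is.numeric(v) && v > 0,
                         TRUE)),
              is.numeric(branchRate), branchRate >= 0, cellJitter >= 0)
    # refuse parameter sets whose expected node count explodes: each
    # branch wins its bifurcation-vs-budget race with probability ~
    # rate*L/(1 + rate*L), giving offspring mean m; sub-critical growth is
    # budget-limited, super-critical growth is territory-limited
    pBif <- branchRate * meanBranchLength /
        (1 + branchRate * meanBranchLength)
    m <- 2 * pBif
    expBranches <- if (m < 0.95) nPrimary / (1 - m)
                   else nPrimary * 2^(branchRate * territoryRadius)
    expNodes <- expBranches *
        min(meanBranchLength, territoryRadius) / segmentStep
    if (expNodes > 1e5)
        stop("expected node count ", round(expNodes), " exceeds 1e5; ",
             "reduce branchRate or territoryRadius")
    class(p) <- "MorphotypeParams"
    p
}

# unit vectors roughly evenly spread on the sphere (Fibonacci lattice)
.sphereDirections <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.perturb <- function(dir, sd) {
    v <- dir + stats::rnorm(3, sd = sd)
    v / sqrt(sum(v^2))
}

#' Simulate one astrocyte skeleton
#'
#' Grows `nPrimary ~ max(2, Poisson)` primary processes from the soma in
#' quasi-uniform directions. Each process advances in `segmentStep`
#' increments with its direction perturbed by `tortuosity`; bifurcations
#' occur along the path at rate `branchRate` with gamma-distributed
#' inter-bifurcation distances (shape 8, so the rate is stable rather
#' than memoryless; daughters diverge by a fixed 25-degree half-angle
#' plus jitter); a branch terminates when it reaches `territoryRadius` or
#' exhausts its gamma-drawn length budget. Territory radius, soma radius
#' and branching rate receive a per-cell log-normal jitter
#' (`cellJitter`). Radii taper from the soma outward with a floor of
#' 0.1 um. The result is a valid, SWC-writable tree.
#'
#' @param params a `MorphotypeParams` from [morphotypeParams()].
#' @param seed integer seed; the same seed and parameters reproduce the
#'   identical node table.
#' @param cellId cell identifier.
#' @return an [AstrocyteSkeleton-class].
#' @export
simulateSkeleton <- function(params, seed = 1L, cellId = "sim") {
    stopifnot(inherits(params, "MorphotypeParams"))
    runWithSeed(seed, .growSkeleton(params, cellId))
}

.BRANCH_SHAPE <- 8  # gamma shape of budgets / inter-bifurcation lengths

.growSkeleton <- function(p, cellId) {
    # per-cell biological variability
    p$territoryRadius <- p$territoryRadius *
        exp(stats::rnorm(1, 0, p$cellJitter))
    p$somaRadius <- p$somaRadius * exp(stats::rnorm(1, 0, 2 * p$cellJitter))
    p$branchRate <- p$branchRate * exp(stats::rnorm(1, 0, p$cellJitter))
    drawBudget <- function() stats::rgamma(1, .BRANCH_SHAPE,
        scale = p$meanBranchLength / .BRANCH_SHAPE)
    nodes <- list(c(id = 1, type = 1, x = 0, y = 0, z = 0,
                    radius = p$somaRadius, parent = -1))
    nid <- 1L
    nPrim <- max(2L, stats::rpois(1L, p$nPrimary))
    dirs <- .sphereDirections(nPrim)
    # stack entries: parent id, position, direction, radius, length budget
    stack <- lapply(seq_len(nPrim), function(i)
        list(parent = 1L, pos = c(0, 0, 0), dir = .perturb(dirs[i, ], 0.1),
             radius = max(0.1, p$somaRadius * 0.3),
             budget = drawBudget()))
    halfAngle <- 25 * pi / 180
    while (length(stack)) {
        br <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pos <- br$pos; dir <- br$dir; parent <- br$parent
        radius <- br$radius; budget <- br$budget
        nextBif <- if (p$branchRate > 0)
            stats::rgamma(1, .BRANCH_SHAPE,
                          scale = 1 / (.BRANCH_SHAPE * p$branchRate))
        else Inf
        travelled <- 0
        repeat {
            if (nid + 1L > 1e5) stop("node bound exceeded during growth")
            dir <- .perturb(dir, p$tortuosity)
            # slight outward bias keeps processes radial within territory
            out <- pos + 1e-9
            outDir <- out / sqrt(sum(out^2))
            dir <- dir + 0.15 * outDir
            dir <- dir / sqrt(sum(dir^2))
            pos <- pos + p$segmentStep * dir
            travelled <- travelled + p$segmentStep
            radius <- max(0.1, radius * (1 - p$taper))
            nid <- nid + 1L
            nodes[[nid]] <- c(id = nid, type = 3, x = pos[1], y = pos[2],
                              z = pos[3], radius = radius, parent = parent)
            parent <- nid
            if (sqrt(sum(pos^2)) >= p$territoryRadius) break
            if (travelled >= budget) break
            if (travelled >= nextBif) {
                # bifurcate: two daughters diverging around current dir
                perp <- .perturb(dir, 1); perp <- perp - sum(perp * dir) * dir
                perp <- perp / sqrt(sum(perp^2))
                for (sgn in c(-1, 1)) {
                    ang <- halfAngle * (1 + stats::rnorm(1, sd = 0.15))
                    ddir <- cos(ang) * dir + sgn * sin(ang) * perp
                    stack[[length(stack) + 1L]] <- list(
                        parent = parent, pos = pos, dir = ddir,
                        radius = radius,
                        budget = drawBudget())
                }
                break
            }
        }
    }
    nd <- as.data.frame(do.call(rbind, nodes))
    AstrocyteSkeleton(nd, cellId = cellId)
}

#' Cohort specification
#'
#' Describes a synthetic cohort: genotypes x age groups x mice x
#' subregions with per-group morphotype mixture proportions and a
#' mouse-level random effect. The default emulates the study design: 2
#' genotypes x 3 age groups x 3 mice x 3 subregions x 15 cells each (810
#' cells), with mixtures over the `simple`/`medium`/`complex` archetypes
#' that follow the reported per-age genotype differences (wild-type
#' complexity peaking at middle age; tau transgenics simplified early and
#' partly complexified late).
#'
#' @param genotypes genotype labels (default `c("WT", "TAU")`).
#' @param ageGroups age groups in months (default `c(3, 9, 23)`).
#' @param micePerGroup mice per genotype x age group (default 3).
#' @param subregions subregion labels (default `c("CA1so","CA1sr","Sub")`).
#' @param cellsPerMouseSubregion cells per mouse per subregion
#'   (default 15).
#' @param mixtures named list `"<genotype>.<age>"` -> proportions over
#'   `archetypes` (summing to 1); defaults mirror the reported cluster
#'   proportions per genotype and age.
#' @param archetypes archetype names, ordered by complexity.
#' @param mouseSd sd of the mouse-level multiplicative random effect on
#'   `branchRate` (default 0.1).
#' @param seed master seed.
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(genotypes = c("WT", "TAU"),
                       ageGroups = c(3L, 9L, 23L),
                       micePerGroup = 3L,
                       subregions = c("CA1so", "CA1sr", "Sub"),
                       cellsPerMouseSubregion = 15L,
                       mixtures = NULL,
                       archetypes = c("simple", "medium", "complex"),
                       mouseSd = 0.1, seed = 1L) {
    if (is.null(mixtures))
        mixtures <- list(
            WT.3   = c(0.757, 0.072, 0.171),
            TAU.3  = c(0.953, 0.019, 0.028),
            WT.9   = c(0.007, 0.333, 0.660),
            TAU.9  = c(0.634, 0.306, 0.060),
            WT.23  = c(0.838, 0.153, 0.009),
            TAU.23 = c(0.693, 0.092, 0.215))[
                paste(rep(genotypes, each = length(ageGroups)),
                      rep(ageGroups, length(genotypes)), sep = ".")]
    stopifnot(!anyNA(names(mixtures)),
              all(abs(vapply(mixtures, sum, 0) - 1) < 1e-9),
              all(lengths(mixtures) == length(archetypes)))
    spec <- list(genotypes = genotypes, ageGroups = as.integer(ageGroups),
                 micePerGroup = as.integer(micePerGroup),
                 subregions = subregions,
                 cellsPerMouseSubregion = as.integer(cellsPerMouseSubregion),
                 mixtures = mixtures, archetypes = archetypes,
                 mouseSd = mouseSd, seed = as.integer(seed))
    class(spec) <- "CohortSpec"
    spec
}

#' Simulate a cohort of skeletons
#'
#' Draws each cell's morphotype from its genotype x age group's mixture,
#' applies the mouse-level multiplicative random effect on the branching
#' rate, grows every skeleton, and returns the skeletons with a manifest
#' and the ground-truth morphotype labels. Optionally writes the SWC
#' files, manifest CSV and truth CSV to a directory.
#'
#' @param spec a `CohortSpec` from [cohortSpec()].
#' @param dir optional output directory; when given, SWC files plus
#'   `manifest.csv` and `truth.csv` are written there.
#' @return list with `skeletons` (named list), `metadata` (manifest
#'   data.frame), `truth` (data.frame `cell_id`, `true_morphotype`,
#'   `mouse_effect`).
#' @export
simulateCohort <- function(spec, dir = NULL) {
    stopifnot(inherits(spec, "CohortSpec"))
    meta <- list(); truth <- list(); skeletons <- list()
    cellN <- 0L
    for (g in spec$genotypes) for (a in spec$ageGroups) {
        mix <- spec$mixtures[[paste(g, a, sep = ".")]]
        for (m in seq_len(spec$micePerGroup)) {
            mouseId <- sprintf("%s_%d_m%d", g, a, m)
            mEffect <- runWithSeed(subSeed(spec$seed, paste0("mouse.", mouseId)),
                                   exp(stats::rnorm(1, 0, spec$mouseSd)))
            for (s in spec$subregions) for (i in seq_len(
                    spec$cellsPerMouseSubregion)) {
                cellN <- cellN + 1L
                cellId <- sprintf("%s_%s_c%03d", mouseId, s, i)
                cellSeed <- subSeed(spec$seed, paste0("cell.", cellId))
                arch <- runWithSeed(cellSeed,
                    sample(spec$archetypes, 1L, prob = mix))
                p <- morphotypeParams(arch)
                p$branchRate <- p$branchRate * mEffect
                skeletons[[cellId]] <- simulateSkeleton(
                    p, seed = subSeed(cellSeed, "grow"), cellId = cellId)
                meta[[cellN]] <- data.frame(
                    cell_id = cellId,
                    swc_path = paste0(cellId, ".swc"),
                    mouse_id = mouseId, genotype = g,
                    age_group = a, subregion = s,
                    stringsAsFactors = FALSE)
                truth[[cellN]] <- data.frame(
                    cell_id = cellId, true_morphotype = arch,
                    mouse_effect = mEffect, stringsAsFactors = FALSE)
            }
        }
    }
    metadata <- do.call(rbind, meta)
    truthDf <- do.call(rbind, truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        for (id in names(skeletons))
            writeSWC(skeletons[[id]], file.path(dir, paste0(id, ".swc")))
        utils::write.csv(metadata, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
        utils::write.csv(truthDf, file.path(dir, "truth.csv"),
                         row.names = FALSE)
    }
    list(skeletons = skeletons, metadata = metadata, truth = truthDf)
}
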