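test_that("a single straight process crosses each sphere once", {
    rows <- rbind(c(1, 1, 0, 0, 0, 2, -1),
                  .armRows(2, 1, c(1, 0, 0), 21, step = 0.5))
    sk <- makeSkeleton(rows)  # reaches (10.5, 0, 0)
    sc <- shollCurve(sk)
    expect_equal(shollRadii(sc), 1:10)
    expect_equal(shollCounts(sc), rep(1L, 10))
})

test_that("a soma-only skeleton yields an empty Sholl curve", {
    sk <- makeSkeleton(rbind(c(1, 1, 0, 0, 0, 2, -1)))
    sc <- shollCurve(sk)
    expect_length(shollRadii(sc), 0)
    prof <- extractProfile(sk)
    expect_equal(prof$n_branches, 0L)
    expect_equal(prof$n_primary_branches, 0L)
    expect_true(is.na(prof$ramification_index))
})

test_that("a sphere through a node counts once (half-open rule)", {
    # endpoint exactly at radius 2: the segment [1, 2] counts r = 2,
    # the following segment (2, 3] does not recount it
    rows <- rbind(c(1, 1, 0, 0, 0, 2, -1),
                  c(2, 3, 1, 0, 0, 0.5, 1),
                  c(3, 3, 2, 0, 0, 0.5, 2),
                  c(4, 3, 3, 0, 0, 0.5, 3))
    sc <- shollCurve(makeSkeleton(rows))
    expect_equal(shollCounts(sc), rep(1L, 3))
})

test_that("Y-shaped tree decomposes into stem plus two depth-1 daughters", {
    br <- branchDecomposition(ySkeleton())
    expect_equal(nrow(br), 3L)
    expect_equal(sort(br$depth), c(0L, 1L, 1L))
    expect_equal(sort(br$level), c(1L, 2L, 2L))
})

test_that("a 5-armed star yields the forced profile values", {
    prof <- extractProfile(starSkeleton(5, 20))
    expect_equal(prof$n_primary_branches, 5L)
    expect_equal(prof$sholl_peak_count, 5L)
    expect_equal(prof$ramification_index, 1.0)
    expect_equal(prof$n_branching_points, 0L)
    expect_equal(prof$n_branches, 5L)
    expect_equal(prof$branch_depth_median, 0)
    expect_equal(prof$total_process_length, 100)
    expect_equal(prof$soma_diameter, 4)
    # peak ties broken toward the smallest radius
    expect_equal(prof$sholl_peak_radius, 1)
})

test_that("4 primaries bifurcating at 5 um give ramification index 2", {
    prof <- extractProfile(fourBifSkeleton())
    expect_equal(prof$n_primary_branches, 4L)
    expect_equal(prof$sholl_peak_count, 8L)
    expect_equal(prof$ramification_index, 2.0)
    expect_equal(prof$n_branching_points, 4L)
    expect_equal(prof$n_branches, 12L)
})

test_that("analytic Sholl counts equal the dense-resampling oracle", {
    for (seed in 1:25) {
        arch <- c("simple", "medium", "complex")[1 + (seed %% 3)]
        sk <- simulateSkeleton(morphotypeParams(arch), seed = 200 + seed)
        expect_equal(as.integer(shollCounts(shollCurve(sk))),
                     as.integer(denseShollOracle(sk, ds = 0.005)),
                     info = paste("seed", seed))
    }
})

test_that("branch depths match the explicit parent-walk oracle", {
    for (seed in 1:20) {
        sk <- simulateSkeleton(morphotypeParams("medium"), seed = 300 + seed)
        br <- branchDecomposition(sk)
        expect_equal(sort(br$depth), as.integer(branchDepthOracle(sk)),
                     ignore_attr = TRUE)
    }
})

test_that("profiles are invariant under rigid rotation and translation", {
    sk <- simulateSkeleton(morphotypeParams("medium"), seed = 42)
    nd <- skeletonNodes(sk)
    th <- 0.7
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    xyz <- as.matrix(nd[, c("x", "y", "z")]) %*% t(R)
    nd2 <- nd
    nd2$x <- xyz[, 1] + 5; nd2$y <- xyz[, 2] - 3; nd2$z <- xyz[, 3] + 11
    sk2 <- AstrocyteSkeleton(nd2, cellId = "rot")
    p1 <- extractProfile(sk); p2 <- extractProfile(sk2)
    for (f in morphometryFeatures())
        expect_equal(p2[[f]], p1[[f]], tolerance = 1e-9)
})

test_that("uniform scaling scales lengths and preserves counts with scaled step", {
    sk <- simulateSkeleton(morphotypeParams("medium"), seed = 43)
    s <- 2.5
    nd <- skeletonNodes(sk)
    nd2 <- nd
    nd2$x <- s * nd$x; nd2$y <- s * nd$y; nd2$z <- s * nd$z
    nd2$radius <- s * nd$radius
    sk2 <- AstrocyteSkeleton(nd2, cellId = "scaled")
    p1 <- extractProfile(sk)
    expect_equal(sum(skeletonNodes(sk2)$type != 1),
                 sum(nd$type != 1))  # same topology
    expect_equal(extractProfile(sk2)$total_process_length,
                 s * p1$total_process_length, tolerance = 1e-9)
    expect_equal(as.integer(shollCounts(shollCurve(sk2, step = s))),
                 as.integer(shollCounts(shollCurve(sk, step = 1))))
})

test_that("adding a terminal branch never decreases branches or length", {
    sk <- simulateSkeleton(morphotypeParams("medium"), seed = 44)
    p1 <- extractProfile(sk)
    nd <- skeletonNodes(sk)
    tip <- max(nd$id)
    add <- c(tip + 1, 3, nd$x[nrow(nd)] + 1, nd$y[nrow(nd)],
             nd$z[nrow(nd)], 0.2, nd$id[nrow(nd)])
    sk2 <- AstrocyteSkeleton(rbind(nd, add), cellId = "grown")
    p2 <- extractProfile(sk2)
    expect_gte(p2$n_branches, p1$n_branches)
    expect_gt(p2$total_process_length, p1$total_process_length)
})

test_that("extractProfiles assembles a SummarizedExperiment with metadata", {
    spec <- cohortSpec(ageGroups = 9L, micePerGroup = 2L,
                       subregions = "Sub", cellsPerMouseSubregion = 3L,
                       mixtures = list(WT.9 = c(0, 1, 0),
                                       TAU.9 = c(0, 1, 0)), seed = 6L)
    sim <- simulateCohort(spec)
    se <- extractProfiles(sim)
    expect_s4_class(se, "SummarizedExperiment")
    expect_equal(ncol(se), 12L)
    expect_equal(nrow(se), 11L)  # 10 features + sholl_peak_radius
    expect_setequal(rownames(se),
                    c(morphometryFeatures(), "sholl_peak_radius"))
    expect_equal(SummarizedExperiment::colData(se)$genotype,
                 sim$metadata$genotype)
    ft <- featureTable(se)
    expect_equal(dim(ft), c(12L, 10L))
    # profile columns agree with per-cell extraction
    one <- extractProfile(sim$skeletons[[3]])
    expect_equal(unname(ft[3, "n_branches"]), one$n_branches)
})
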