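test_that("a minimal well-formed SWC file parses into a 3-node skeleton", {
    f <- withr::local_tempfile(fileext = ".swc")
    writeLines(c("# comment",
                 "1 1 0 0 0 2 -1",
                 "2 3 1 0 0 0.5 1",
                 "3 3 2 0 0 0.5 2"), f)
    sk <- readSWC(f)
    nd <- skeletonNodes(sk)
    expect_equal(nrow(nd), 3L)
    expect_equal(nd$type[1], 1L)
    expect_equal(nd$parent[1], -1L)
    expect_equal(nd$x, c(0, 1, 2))
})

test_that("tab-delimited files and out-of-order nodes are accepted", {
    f <- withr::local_tempfile(fileext = ".swc")
    writeLines(c("3\t3\t2\t0\t0\t0.5\t2",
                 "1\t1\t0\t0\t0\t2\t-1",
                 "2\t3\t1\t0\t0\t0.5\t1"), f)
    nd <- skeletonNodes(readSWC(f))
    # topological order restored regardless of file order
    expect_equal(nd$id, c(1L, 2L, 3L))
})

test_that("malformed and invalid files raise named errors", {
    f <- withr::local_tempfile(fileext = ".swc")
    writeLines(c("1 1 0 0 0 2 -1", "2 3 1 0 0"), f)
    expect_error(readSWC(f), "line 2")
    writeLines(c("1 1 0 0 0 2 -1", "5 3 1 0 0 0.5 99"), f)
    expect_error(readSWC(f), "missing parent")
    writeLines(c("1 1 0 0 0 2 -1", "1 3 1 0 0 0.5 1"), f)
    expect_error(readSWC(f), "duplicate")
    writeLines(c("1 1 0 0 0 2 -1", "2 3 1 0 0 0 1"), f)
    expect_error(readSWC(f), "radius")
    writeLines(c("1 1 0 0 0 2 -1", "2 1 1 0 0 2 -1"), f)
    expect_error(readSWC(f), "more than one root")
    writeLines(c("1 3 0 0 0 2 -1", "2 3 1 0 0 0.5 1"), f)
    expect_error(readSWC(f), "soma")
    # two nodes referencing each other: no root at all
    writeLines(c("1 1 0 0 0 2 2", "2 3 1 0 0 0.5 1"), f)
    expect_error(readSWC(f), "root")
})

test_that("write renumbers ids topologically and preserves geometry", {
    sk <- makeSkeleton(rbind(c(10, 1, 0, 0, 0, 2, -1),
                             c(20, 3, 1.5, 0, 0, 0.5, 10),
                             c(30, 3, 3, 0, 0, 0.5, 20)))
    f <- withr::local_tempfile(fileext = ".swc")
    writeSWC(sk, f)
    lines <- readLines(f)
    expect_match(lines[1], "^# cell_id")
    expect_equal(length(lines), 4L)
    back <- skeletonNodes(readSWC(f))
    expect_equal(back$id, 1:3)
    expect_equal(back$parent, c(-1L, 1L, 2L))
    expect_equal(back$x, c(0, 1.5, 3))
})

test_that("write -> read is the identity up to renumbering; second write is byte-identical", {
    for (seed in 1:20) {
        sk <- simulateSkeleton(morphotypeParams("medium"), seed = seed,
                               cellId = paste0("c", seed))
        f1 <- withr::local_tempfile(fileext = ".swc")
        f2 <- withr::local_tempfile(fileext = ".swc")
        writeSWC(sk, f1)
        back <- readSWC(f1, cellId = cellId(sk))
        a <- skeletonNodes(sk); b <- skeletonNodes(back)
        expect_equal(nrow(a), nrow(b))
        expect_equal(b$id, seq_len(nrow(b)))
        expect_equal(a$type, b$type)
        expect_equal(a[, c("x", "y", "z", "radius")],
                     b[, c("x", "y", "z", "radius")], tolerance = 1e-6,
                     ignore_attr = TRUE)
        writeSWC(back, f2)
        expect_identical(readLines(f1), readLines(f2))
    }
})

test_that("every simulated skeleton satisfies the tree invariants", {
    params <- list(morphotypeParams("simple"), morphotypeParams("medium"),
                   morphotypeParams("complex"))
    for (i in 1:100) {
        sk <- simulateSkeleton(params[[1 + (i %% 3)]], seed = 1000 + i)
        expect_true(isTRUE(methods::validObject(sk, test = TRUE)))
        nd <- skeletonNodes(sk)
        expect_equal(sum(nd$parent == -1L), 1L)
        expect_true(all(nd$radius > 0))
        # parent precedes child: acyclic rooted tree
        nonroot <- which(nd$parent != -1L)
        expect_true(all(match(nd$parent[nonroot], nd$id) < nonroot))
    }
})

test_that("loadCohort attaches metadata, reports the breakdown, and round-trips", {
    dir <- withr::local_tempdir()
    spec <- cohortSpec(ageGroups = 3L, micePerGroup = 2L,
                       subregions = "CA1so", cellsPerMouseSubregion = 2L,
                       mixtures = list(WT.3 = c(1, 0, 0),
                                       TAU.3 = c(1, 0, 0)),
                       seed = 3L)
    sim <- simulateCohort(spec, dir = dir)
    expect_equal(nrow(sim$metadata), 8L)
    msgs <- capture_messages(coh <- loadCohort(file.path(dir, "manifest.csv")))
    expect_match(msgs[1], "loaded 8 cells")
    expect_true(any(grepl("WT / 3 mo / CA1so: 4", msgs)))
    expect_equal(coh$metadata, sim$metadata)
    expect_equal(names(coh$skeletons), sim$metadata$cell_id)
    # loaded skeletons equal the simulated ones up to renumbering
    a <- skeletonNodes(sim$skeletons[[1]])
    b <- skeletonNodes(coh$skeletons[[1]])
    expect_equal(a[, c("x", "y", "z", "radius")],
                 b[, c("x", "y", "z", "radius")], tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("loadCohort rejects unknown tokens and names failing cells", {
    dir <- withr::local_tempdir()
    spec <- cohortSpec(ageGroups = 3L, micePerGroup = 2L,
                       subregions = "Sub", cellsPerMouseSubregion = 1L,
                       mixtures = list(WT.3 = c(1, 0, 0),
                                       TAU.3 = c(1, 0, 0)), seed = 4L)
    sim <- simulateCohort(spec, dir = dir)
    man <- read.csv(file.path(dir, "manifest.csv"))
    bad <- man; bad$genotype[1] <- "HET"
    write.csv(bad, file.path(dir, "bad1.csv"), row.names = FALSE)
    expect_error(loadCohort(file.path(dir, "bad1.csv")), "HET")
    bad <- man; bad$swc_path[2] <- "nope.swc"
    write.csv(bad, file.path(dir, "bad2.csv"), row.names = FALSE)
    err <- tryCatch(loadCohort(file.path(dir, "bad2.csv"), verbose = FALSE),
                    error = conditionMessage)
    expect_match(err, man$cell_id[2], fixed = TRUE)
    expect_match(err, "1 cell")
})
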