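test_that("Kruskal-Wallis H is 7.2 on the three consecutive triples", {
    res <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
    expect_equal(res$statistic, 7.2, tolerance = 1e-12)
    expect_equal(res$df, 2)
    expect_equal(res$descriptives$median, c(2, 5, 8))
})

test_that("identical groups give H = 0, p = 1", {
    res <- kruskalWallis(list(rep(2, 5), rep(2, 5)))
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
})

test_that("tie correction matches a definitional implementation", {
    groups <- list(c(1, 2, 2, 3), c(2, 3, 3, 5), c(5, 5, 6, 7))
    res <- kruskalWallis(groups)
    # definitional: H = (12/(N(N+1))) sum Ri^2/ni - 3(N+1), divided by
    # 1 - sum(t^3 - t)/(N^3 - N)
    x <- unlist(groups); N <- length(x); r <- rank(x)
    Ri <- tapply(r, rep(seq_along(groups), lengths(groups)), sum)
    H <- 12 / (N * (N + 1)) * sum(Ri^2 / lengths(groups)) - 3 * (N + 1)
    ties <- table(x)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(res$statistic, unname(H), tolerance = 1e-12)
})

test_that("Dunn's test yields one result per pair with BH adjustment", {
    set.seed(51)
    groups <- list(a = rnorm(12), b = rnorm(12, 1), c = rnorm(12, 3))
    res <- dunnBH(groups)
    expect_equal(nrow(res), 3L)
    expect_setequal(paste(res$group1, res$group2),
                    c("a b", "a c", "b c"))
    expect_true(all(res$adjusted.p >= res$p.value - 1e-15))
    # permuting groups permutes rows without changing p-values
    res2 <- dunnBH(groups[c(2, 3, 1)])
    expect_equal(sort(res$p.value), sort(res2$p.value), tolerance = 1e-12)
    # z for a pair matches the pooled-rank formula without ties
    x <- unlist(groups); r <- rank(x); N <- length(x)
    mr <- tapply(r, rep(1:3, each = 12), mean)
    se <- sqrt(N * (N + 1) / 12 * (1 / 12 + 1 / 12))
    expect_equal(res$z[1], unname((mr[1] - mr[2]) / se), tolerance = 1e-12)
})

test_that("BH step-up reproduces the hand-evaluated adjustment", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
                 c(0.03, 0.03, 0.04))
    groups <- list(c(1, 2, 3, 4), c(2, 3, 4, 6), c(5, 6, 7, 9))
    res <- dunnBH(groups)
    expect_equal(res$adjusted.p, p.adjust(res$p.value, "BH"))
})

test_that("nested ANOVA matches the explicit sums-of-squares oracle", {
    set.seed(52)
    genotype <- rep(c("WT", "TAU"), each = 6)
    mouse <- rep(c("m1", "m2", "m3", "m4"), each = 3)
    values <- c(rnorm(6, 5), rnorm(6, 0)) + rep(rnorm(4, sd = 0.8), each = 3)
    res <- nestedAnova(values, genotype, mouse)
    oracle <- nestedAnovaOracle(values, genotype, mouse)
    expect_equal(res$statistic, oracle$F, tolerance = 1e-10)
    expect_equal(res$df, oracle$df)
    expect_equal(res$p.value, oracle$p, tolerance = 1e-10)
    # with no mouse variance the F approaches one-way ANOVA on mouse means
    values2 <- c(rnorm(6, 5, 0.01), rnorm(6, 0, 0.01))
    res2 <- nestedAnova(values2, genotype, mouse)
    mm <- tapply(values2, mouse, mean)
    gg <- factor(rep(c("WT", "TAU"), each = 2))
    ref <- summary(aov(mm ~ gg))[[1]]["gg", "F value"]
    expect_equal(res2$statistic, ref, tolerance = 1e-6)
})

test_that("nested ANOVA handles degenerate inputs", {
    genotype <- rep(c("WT", "TAU"), each = 6)
    mouse <- rep(c("m1", "m2", "m3", "m4"), each = 3)
    res <- nestedAnova(rep(1, 12), genotype, mouse)
    expect_true(is.na(res$statistic))
    expect_error(nestedAnova(rnorm(6), rep(c("WT", "TAU"), each = 3),
                             rep(c("m1", "m2"), each = 3)),
                 ">= 2 mice")
    expect_error(nestedAnova(rnorm(12), rep(c("WT", "TAU"), 6),
                             rep(c("m1", "m2"), each = 6)),
                 "more than one genotype")
    # shuffling cell order leaves the statistic unchanged
    set.seed(53)
    values <- rnorm(12) + rep(c(0, 2), each = 6)
    r1 <- nestedAnova(values, genotype, mouse)
    perm <- sample(12)
    r2 <- nestedAnova(values[perm], genotype[perm], mouse[perm])
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
})

test_that("nested ANOVA keeps its nominal type-I error under mouse variance", {
    reps <- 800
    hits <- 0; hitsNaive <- 0
    genotype <- rep(c("WT", "TAU"), each = 30)
    mouse <- rep(paste0("m", 1:6), each = 10)
    set.seed(54)
    for (i in seq_len(reps)) {
        values <- rnorm(60) + rep(rnorm(6, sd = 1), each = 10)
        res <- nestedAnova(values, genotype, mouse)
        if (res$p.value < 0.05) hits <- hits + 1
        pNaive <- summary(aov(values ~ factor(genotype)))[[1]][1, "Pr(>F)"]
        if (pNaive < 0.05) hitsNaive <- hitsNaive + 1
    }
    rate <- hits / reps
    expect_lt(abs(rate - 0.05), 0.025)  # ~3 binomial SE
    # the naive cell-level ANOVA is anticonservative in the same setting
    expect_gt(hitsNaive / reps, rate)
})

test_that("Pearson chi-square matches hand evaluation and its invariances", {
    res0 <- chiSquareDistribution(rbind(c(10, 10), c(10, 10)))
    expect_equal(res0$statistic, 0)
    expect_equal(res0$p.value, 1)
    tab <- rbind(c(50, 40, 10), c(10, 40, 50))
    res <- chiSquareDistribution(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(res$df, 2)
    # doubling all counts doubles the statistic at fixed proportions
    res2 <- chiSquareDistribution(2 * tab)
    expect_equal(res2$statistic, 2 * res$statistic, tolerance = 1e-12)
    # zero-margin column dropped with warning
    w <- capture_warnings(res3 <- chiSquareDistribution(
        rbind(c(5, 0, 7), c(3, 0, 9))))
    expect_true(any(grepl("zero-margin", w)))
    expect_equal(res3$df, 1)
})

test_that("Sholl profile comparison finds no signal under the null", {
    spec <- cohortSpec(ageGroups = 3L, micePerGroup = 2L,
                       subregions = "Sub", cellsPerMouseSubregion = 10L,
                       mixtures = list(WT.3 = c(0, 1, 0),
                                       TAU.3 = c(0, 1, 0)), seed = 55L)
    sim <- simulateCohort(spec)
    curves <- lapply(sim$skeletons, shollCurve)
    res <- suppressMessages(
        shollProfileCompare(curves, sim$metadata$genotype))
    expect_length(res$significantRadii, 0)
    expect_equal(res$perRadius$adjusted.p,
                 pmin(1, res$perRadius$p.value *
                          max(res$perRadius$radius, na.rm = TRUE)),
                 tolerance = 1e-12)
})

test_that("an injected genotype effect is detected only where planted", {
    # synthetic curves: WT flat 6 everywhere, TAU elevated at radii 14-19
    set.seed(56)
    mk <- function(bump) {
        counts <- pmax(0L, as.integer(round(rnorm(25, 6, 1))))
        if (bump) counts[14:19] <- counts[14:19] + 8L
        counts[25] <- max(counts[25], 1L)
        new("ShollCurve", radii = as.numeric(1:25), counts = counts,
            cellId = "s")
    }
    curves <- c(lapply(1:40, function(i) mk(FALSE)),
                lapply(1:40, function(i) mk(TRUE)))
    res <- shollProfileCompare(curves, rep(c("WT", "TAU"), each = 40))
    expect_true(all(res$significantRadii %in% 14:19))
    expect_gte(length(res$significantRadii), 5)
    expect_lt(res$anova$genotype$p.value, 0.01)
})

test_that("complexity scoring ranks clusters by the three z-features", {
    set.seed(57)
    n <- 60
    labels <- rep(1:2, each = n / 2)
    base <- matrix(rnorm(n * 3, sd = 0.2), n)
    base[labels == 2, ] <- base[labels == 2, ] + 1
    z <- scale(base)
    colnames(z) <- c("n_branching_points", "n_branches",
                     "ramification_index")
    cx <- complexityScore(z, labels)
    expect_equal(cx$label[cx$cluster == 2], "high")
    expect_equal(cx$label[cx$cluster == 1], "low")
    # permuting cluster ids permutes ranks consistently
    cx2 <- complexityScore(z, 3L - labels)
    expect_equal(cx2$label[cx2$cluster == 1], "high")
})

test_that("cluster proportions sum to 100 and track the generating mixture", {
    labels <- c(rep(1L, 95), rep(2L, 3), rep(3L, 2))
    md <- data.frame(genotype = rep("WT", 100))
    pr <- clusterProportions(labels, md)
    expect_equal(pr$percent, c(95, 3, 2))
    expect_equal(sum(pr$percent), 100, tolerance = 1e-9)
    # binomial check against a known mixture
    set.seed(58)
    mix <- c(0.75, 0.18, 0.07)
    lab2 <- sample(1:3, 400, TRUE, prob = mix)
    pr2 <- clusterProportions(lab2, data.frame(genotype = rep("WT", 400)))
    for (c in 1:3) {
        ci <- qbinom(c(0.025, 0.975), 400, mix[c]) / 400 * 100
        expect_gte(pr2$percent[pr2$cluster == c], ci[1])
        expect_lte(pr2$percent[pr2$cluster == c], ci[2])
    }
})
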