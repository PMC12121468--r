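# Group-comparison statistics: Kruskal-Wallis + Dunn/BH cluster
# characterization, nested ANOVA with mouse in genotype, Pearson chi-square
# on morphotype distributions, Sholl-profile two-way ANOVA with Bonferroni
# contrasts, complexity scoring and proportion tables.

.statResult <- function(test, statistic, df = NA, p = NA_real_,
                        adjusted = NA_real_, descriptives = NULL) {
    out <- list(test = test, statistic = statistic, df = df,
                p.value = p, adjusted.p = adjusted,
                descriptives = descriptives)
    class(out) <- "astroStatTest"
    out
}

#' @export
print.astroStatTest <- function(x, ...) {
    cat(x$test, ": statistic = ", format(x$statistic, digits = 5), sep = "")
    if (!all(is.na(x$df))) cat(", df = ", paste(x$df, collapse = ", "), sep = "")
    cat(", p = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
    invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1
#' degrees of freedom. When all values are identical, H = 0 and p = 1.
#'
#' @param groups list of numeric vectors (one per group), or a numeric
#'   vector with `g` giving the grouping.
#' @param g optional grouping factor when `groups` is a vector.
#' @return an `astroStatTest` with group medians as descriptives.
#' @export
kruskalWallis <- function(groups, g = NULL) {
    if (!is.null(g)) groups <- split(as.numeric(groups), g)
    stopifnot(length(groups) >= 2, sum(lengths(groups)) >= 3)
    x <- unlist(groups)
    if (length(unique(x)) == 1L)
        return(.statResult("Kruskal-Wallis", 0, df = length(groups) - 1L,
                           p = 1))
    f <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- stats::kruskal.test(x, f)
    .statResult("Kruskal-Wallis", unname(kt$statistic),
                df = unname(kt$parameter), p = kt$p.value,
                descriptives = data.frame(
                    group = seq_along(groups), n = lengths(groups),
                    median = vapply(groups, stats::median, 0)))
}

#' Dunn's post hoc test with Benjamini-Hochberg correction
#'
#' Pairwise Dunn z statistics on the pooled ranks with tie correction,
#' two-sided p-values, and BH (FDR) adjustment across all pairs of one
#' Kruskal-Wallis family.
#'
#' @inheritParams kruskalWallis
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p.value`, `adjusted.p`.
#' @export
dunnBH <- function(groups, g = NULL) {
    if (!is.null(g)) groups <- split(as.numeric(groups), g)
    k <- length(groups)
    stopifnot(k >= 2)
    x <- unlist(groups)
    f <- rep(seq_len(k), lengths(groups))
    N <- length(x)
    r <- rank(x)
    meanRank <- vapply(seq_len(k), function(i) mean(r[f == i]), 0)
    n <- lengths(groups)
    ties <- table(x)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    pairs <- utils::combn(k, 2)
    z <- apply(pairs, 2L, function(pr) {
        i <- pr[1]; j <- pr[2]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
        (meanRank[i] - meanRank[j]) / se
    })
    p <- 2 * stats::pnorm(-abs(z))
    nm <- names(groups)
    if (is.null(nm)) nm <- as.character(seq_len(k))
    data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
               z = z, p.value = p,
               adjusted.p = stats::p.adjust(p, "BH"))
}

#' Nested ANOVA with animal as the nesting factor
#'
#' Two-level nested ANOVA for cell-level measurements: genotype is a fixed
#' factor and mouse a random factor nested in genotype, so that cells are
#' not treated as independent replicates of genotype. Sums of squares are
#' partitioned genotype / mouse-within-genotype / residual (sequential SS
#' under unbalance), and the genotype F is tested against the
#' mouse-within-genotype mean square on (g - 1, m - g) degrees of freedom,
#' computed via `aov` with a mouse error stratum.
#'
#' @param values numeric cell-level measurements.
#' @param genotype factor (or character) of length `length(values)`.
#' @param mouse mouse identifier per cell; each mouse must belong to
#'   exactly one genotype, with at least 2 mice per genotype.
#' @param log10Transform apply a log10 transform first (values must be
#'   positive).
#' @return an `astroStatTest`; `statistic` is the genotype F, `df` its two
#'   degrees of freedom; descriptives give per-genotype n, mean and SEM.
#'   When all values are equal the F is reported as `NA` with p = `NA`.
#' @export
nestedAnova <- function(values, genotype, mouse, log10Transform = FALSE) {
    genotype <- factor(genotype)
    mouse <- factor(mouse)
    if (log10Transform) {
        stopifnot(all(values > 0))
        values <- log10(values)
    }
    gOf <- tapply(as.character(genotype), mouse,
                  function(g) length(unique(g)))
    if (any(gOf > 1)) stop("a mouse appears in more than one genotype")
    micePer <- table(unique(data.frame(genotype, mouse))$genotype)
    if (any(micePer < 2))
        stop("need >= 2 mice per genotype to test genotype")
    if (length(unique(values)) == 1L)
        return(.statResult("nested ANOVA", NA_real_, df = c(NA, NA),
                           p = NA_real_))
    fit <- stats::aov(values ~ genotype + Error(mouse))
    s <- summary(fit)
    strat <- s[["Error: mouse"]][[1L]]
    rownames(strat) <- trimws(rownames(strat))
    Fg <- strat["genotype", "F value"]
    dfs <- c(strat["genotype", "Df"], strat["Residuals", "Df"])
    p <- strat["genotype", "Pr(>F)"]
    desc <- do.call(rbind, lapply(split(values, genotype), function(v)
        data.frame(n = length(v), mean = mean(v),
                   sem = stats::sd(v) / sqrt(length(v)))))
    desc <- data.frame(genotype = rownames(desc), desc, row.names = NULL)
    .statResult("nested ANOVA", unname(Fg), df = unname(dfs),
                p = unname(p), descriptives = desc)
}

#' Pearson chi-square on a genotype x cluster table
#'
#' Pearson chi-square test of homogeneity with (r-1)(c-1) degrees of
#' freedom and no continuity correction. Zero-margin rows/columns are
#' dropped with a warning; a warning is also raised when any expected
#' count is below 5.
#'
#' @param table a contingency matrix (e.g. genotypes x clusters) of
#'   non-negative counts.
#' @return an `astroStatTest`; descriptives carry the expected counts.
#' @export
chiSquareDistribution <- function(table) {
    table <- as.matrix(table)
    stopifnot(all(table >= 0))
    keepR <- rowSums(table) > 0; keepC <- colSums(table) > 0
    if (!all(keepR) || !all(keepC)) {
        warning("dropping zero-margin row(s)/column(s)")
        table <- table[keepR, keepC, drop = FALSE]
    }
    stopifnot(nrow(table) >= 2, ncol(table) >= 2)
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    if (any(ct$expected < 5))
        warning("expected count(s) below 5; chi-square approximation weak")
    .statResult("Pearson chi-square", unname(ct$statistic),
                df = unname(ct$parameter), p = ct$p.value,
                descriptives = ct$expected)
}

#' Compare Sholl profiles between genotypes
#'
#' Aligns per-cell Sholl curves on common radii (zero-padding beyond each
#' cell's maximal radius: absent processes are true zero intersections),
#' runs a two-way ANOVA (genotype x radius, cells as replicates), then
#' per-radius genotype contrasts (two-sample t tests) with Bonferroni
#' correction across radii. Radii with fewer than 2 cells per genotype are
#' excluded with a message.
#'
#' @param curves list of [ShollCurve-class], one per cell.
#' @param genotype genotype per cell.
#' @param alpha corrected significance threshold (default 0.01, the
#'   convention used for profile plots).
#' @return list with `anova` (genotype, radius, interaction
#'   `astroStatTest`s), `perRadius` (data.frame radius, meanA, meanB, t,
#'   p.value, adjusted.p), `significantRadii`.
#' @export
shollProfileCompare <- function(curves, genotype, alpha = 0.01) {
    genotype <- factor(genotype)
    stopifnot(nlevels(genotype) == 2, length(curves) == length(genotype))
    rmax <- max(vapply(curves, function(s) {
        n <- length(s@radii); if (n) s@radii[n] else 0 }, 0))
    if (rmax < 1) stop("all cells are soma-only")
    radii <- seq_len(rmax)
    mat <- t(vapply(curves, function(s) {
        v <- numeric(rmax)
        if (length(s@counts)) v[seq_along(s@counts)] <- s@counts
        v
    }, numeric(rmax)))
    long <- data.frame(
        count = as.vector(mat),
        genotype = rep(genotype, times = rmax),
        radius = factor(rep(radii, each = length(curves))))
    fit <- stats::aov(count ~ genotype * radius, data = long)
    tab <- summary(fit)[[1L]]
    rownames(tab) <- trimws(rownames(tab))
    anovaRes <- list(
        genotype = .statResult("two-way ANOVA: genotype",
                               tab["genotype", "F value"],
                               df = c(tab["genotype", "Df"],
                                      tab["Residuals", "Df"]),
                               p = tab["genotype", "Pr(>F)"]),
        radius = .statResult("two-way ANOVA: radius",
                             tab["radius", "F value"],
                             df = c(tab["radius", "Df"],
                                    tab["Residuals", "Df"]),
                             p = tab["radius", "Pr(>F)"]),
        interaction = .statResult("two-way ANOVA: genotype x radius",
                                  tab["genotype:radius", "F value"],
                                  df = c(tab["genotype:radius", "Df"],
                                         tab["Residuals", "Df"]),
                                  p = tab["genotype:radius", "Pr(>F)"]))
    lv <- levels(genotype)
    ok <- logical(rmax)
    res <- vector("list", rmax)
    for (r in radii) {
        a <- mat[genotype == lv[1], r]; b <- mat[genotype == lv[2], r]
        if (length(a) < 2 || length(b) < 2 ||
            (stats::sd(a) == 0 && stats::sd(b) == 0)) next
        tt <- stats::t.test(a, b)
        ok[r] <- TRUE
        res[[r]] <- data.frame(radius = r, meanA = mean(a), meanB = mean(b),
                               t = unname(tt$statistic), p.value = tt$p.value)
    }
    if (!all(ok))
        message("excluded ", sum(!ok), " radius/radii with degenerate data")
    perRadius <- do.call(rbind, res[ok])
    perRadius$adjusted.p <- pmin(1, perRadius$p.value * rmax)
    list(anova = anovaRes, perRadius = perRadius,
         significantRadii = perRadius$radius[perRadius$adjusted.p < alpha])
}

#' Complexity score and ordering of clusters
#'
#' Scores each cluster by the mean z-score of the three complexity
#' features (number of branching points, total number of branches,
#' ramification index) and ranks clusters from low to high complexity.
#'
#' @param zTable cells x features z-scaled matrix containing columns
#'   `n_branching_points`, `n_branches`, `ramification_index`.
#' @param labels integer cluster labels.
#' @return data.frame `cluster`, `score`, `rank` (1 = lowest complexity),
#'   `label` (`"low"`/`"medium"`/.../`"high"`).
#' @export
complexityScore <- function(zTable, labels) {
    zTable <- as.matrix(zTable)
    labels <- as.integer(labels)
    k <- max(labels)
    stopifnot(k >= 2)
    feats <- c("n_branching_points", "n_branches", "ramification_index")
    stopifnot(all(feats %in% colnames(zTable)))
    score <- vapply(seq_len(k), function(c)
        mean(zTable[labels == c, feats], na.rm = TRUE), 0)
    rk <- rank(score, ties.method = "first")
    names <- if (k == 2) c("low", "high")
             else c("low", rep("medium", k - 2), "high")
    data.frame(cluster = seq_len(k), score = score, rank = rk,
               label = names[rk])
}

#' Cluster proportions per genotype
#'
#' Percentage of cells belonging to each cluster within each genotype (and
#' optionally each age group), with the underlying counts.
#'
#' @param labels integer cluster labels.
#' @param metadata data.frame with a `genotype` column (and optionally
#'   `age_group`) aligned to `labels`.
#' @return data.frame `genotype` (, `age_group`), `cluster`, `n`,
#'   `percent`; percentages sum to 100 within each genotype (x age) group.
#' @export
clusterProportions <- function(labels, metadata) {
    stopifnot(length(labels) == nrow(metadata))
    byAge <- "age_group" %in% names(metadata)
    grp <- if (byAge) interaction(metadata$genotype, metadata$age_group,
                                  drop = TRUE)
           else factor(metadata$genotype)
    out <- do.call(rbind, lapply(levels(grp), function(g) {
        sel <- grp == g
        tab <- table(factor(labels[sel], levels = sort(unique(labels))))
        d <- data.frame(cluster = as.integer(names(tab)),
                        n = as.integer(tab),
                        percent = 100 * as.integer(tab) / sum(tab))
        d$genotype <- unique(metadata$genotype[sel])[1]
        if (byAge) d$age_group <- unique(metadata$age_group[sel])[1]
        d
    }))
    cols <- c("genotype", if (byAge) "age_group", "cluster", "n", "percent")
    out[, cols]
}
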