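# End-to-end orchestration: per age group, features -> scaling -> PCA ->
# Kaiser & Horn retention -> clustering with k and algorithm selection ->
# variable filter -> DAPC refinement -> group statistics.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; supplied values
#' override them. Unknown keys are rejected.
#'
#' @param ... overrides, e.g. `cluster = list(kRange = 2:6)`.
#' @return nested named list with blocks `features`, `pca`, `cluster`,
#'   `dapc`, `stats`.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        features = list(log10 = c("total_process_length", "n_branches",
                                  "n_branching_points", "sholl_peak_count",
                                  "sholl_median", "n_primary_branches",
                                  "ramification_index")),
        pca = list(nIter = 1000L, quantile = 0.95, minComponents = 2L),
        cluster = list(kRange = 2:8, linkage = "ward",
                       algorithms = c("hierarchical", "kmeans", "pam",
                                      "som"),
                       selectionAlgorithm = "hierarchical", nRefs = 50L),
        dapc = list(contributionThreshold = 0.7, alpha = 0.05,
                    refineRounds = 1L),
        stats = list(shollAlpha = 0.01))
    over <- list(...)
    for (blk in names(over)) {
        if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
        for (key in names(over[[blk]])) {
            if (!key %in% names(cfg[[blk]]))
                stop("unknown config key: ", blk, ".", key)
            cfg[[blk]][[key]] <- over[[blk]][[key]]
        }
    }
    cfg
}

#' Run the full morphotype pipeline
#'
#' For each age group independently (clusterings are never pooled across
#' ages, so cluster identities are age-specific): extract the ten-feature
#' profiles, optionally log10-transform skewed features, z-scale, run
#' correlation-matrix PCA with Kaiser-and-Horn component retention,
#' select the number of clusters by the eight-index vote and the
#' algorithm by standardized internal-validation score, filter variables
#' by cluster contribution, refine the partition by DAPC on the PC scores
#' of the retained variables, and compute the group statistics: cluster
#' proportions per genotype with a Pearson chi-square, Kruskal-Wallis +
#' Dunn/BH cluster characterization per retained feature, the cluster
#' complexity ranking, nested-ANOVA genotype contrasts per feature and
#' subregion, and the per-subregion Sholl-profile comparison.
#'
#' @param cohort list with `skeletons` and `metadata` ([loadCohort()] /
#'   [simulateCohort()] output), or an already profiled
#'   `SummarizedExperiment` from [extractProfiles()].
#' @param config configuration list from [pipelineConfig()].
#' @param seed master seed; all stage seeds are derived from it.
#' @param verbose emit per-stage messages.
#' @return list of class `astroPipelineReport`: per age group a list with
#'   `features`, `retention`, `kSelection`, `algorithmSelection`,
#'   `retainedVariables`, `dapc`, `labels` (refined, named by cell),
#'   `proportions`, `chiSquare`, `characterization`, `complexity`,
#'   `nestedAnova`, `shollComparison`; plus `config` and `seed`.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), seed = 1L,
                        verbose = TRUE) {
    say <- if (verbose) message else function(...) invisible()
    se <- if (is(cohort, "SummarizedExperiment")) cohort
          else { say("extracting morphometric profiles"); extractProfiles(cohort) }
    md <- as.data.frame(SummarizedExperiment::colData(se))
    ages <- sort(unique(md$age_group))
    report <- list(ageGroups = list(), config = config, seed = seed)
    for (age in ages) {
        say("== age group ", age, " months ==")
        sub <- se[, md$age_group == age]
        report$ageGroups[[as.character(age)]] <-
            .runAgeGroup(sub, config, subSeed(seed, paste0("age.", age)),
                         say)
    }
    class(report) <- "astroPipelineReport"
    report
}

.runAgeGroup <- function(se, cfg, seed, say) {
    md <- as.data.frame(SummarizedExperiment::colData(se))
    feats <- featureTable(se)
    md <- md[rownames(feats), , drop = FALSE]
    # log10(1 + x): branching counts and lengths are strongly right-skewed
    for (f in cfg$features$log10) {
        stopifnot(all(feats[, f] > -1))
        feats[, f] <- log10(1 + feats[, f])
    }
    scaled <- scaleFeatures(feats)
    pcaOut <- runPCA(scaled)
    horn <- hornParallel(scaled, nIter = cfg$pca$nIter,
                         quantile = cfg$pca$quantile,
                         seed = subSeed(seed, "horn"))
    ret <- retainComponents(pcaOut, horn,
                            minComponents = cfg$pca$minComponents)
    say("retained ", ret$retainedK, " PC(s) (Kaiser ", ret$kaiserK,
        ", Horn ", ret$hornK, ")")
    ks <- selectK(ret$scores, kRange = cfg$cluster$kRange,
                  algorithm = cfg$cluster$selectionAlgorithm,
                  nRefs = cfg$cluster$nRefs, seed = subSeed(seed, "selectk"),
                  linkage = cfg$cluster$linkage)
    say("index vote chose k = ", ks$chosenK)
    alg <- selectAlgorithm(ret$scores, ks$chosenK,
                           candidates = cfg$cluster$algorithms,
                           seed = subSeed(seed, "selectalg"),
                           linkage = cfg$cluster$linkage)
    labels <- alg$best@labels
    say("best algorithm: ", alg$best@algorithm)
    retained <- variableContributionFilter(
        scaled$values, labels,
        threshold = cfg$dapc$contributionThreshold, alpha = cfg$dapc$alpha)
    # DAPC on the PC scores of the retained variables, same retained
    # dimensionality as upstream where possible
    dapcVars <- if (length(retained) >= 2) retained else colnames(feats)
    zr <- scaled$values[, dapcVars, drop = FALSE]
    pcaR <- runPCA(list(values = zr))
    nPC <- min(ret$retainedK, ncol(zr))
    dapcScores <- pcaR$scores[, seq_len(nPC), drop = FALSE]
    model <- fitDAPC(dapcScores, labels, k = alg$best@k)
    refined <- refinePartition(model, labels, scores = dapcScores,
                               rounds = cfg$dapc$refineRounds)
    names(refined) <- rownames(feats)
    props <- clusterProportions(refined, md[, "genotype", drop = FALSE])
    tab <- table(md$genotype, refined)
    chi <- if (nrow(tab) >= 2 && ncol(tab) >= 2)
        tryCatch(chiSquareDistribution(tab), error = function(e) NULL)
    else NULL
    characterization <- lapply(stats::setNames(retained, retained),
        function(f) {
            grps <- split(feats[, f], refined)
            list(kw = kruskalWallis(grps), dunn = dunnBH(grps))
        })
    complexity <- complexityScore(scaled$values, refined)
    nested <- .nestedByFeatureSubregion(feats, md)
    sholl <- .shollBySubregion(se, md, cfg$stats$shollAlpha)
    list(features = feats, scaled = scaled, retention = ret,
         kSelection = ks, algorithmSelection = alg$report,
         chosenAlgorithm = alg$best@algorithm,
         initialLabels = labels, retainedVariables = retained,
         dapc = model, labels = refined, proportions = props,
         chiSquare = chi, characterization = characterization,
         complexity = complexity, nestedAnova = nested,
         shollComparison = sholl)
}

.nestedByFeatureSubregion <- function(feats, md) {
    out <- list()
    for (s in unique(md$subregion)) {
        sel <- md$subregion == s
        if (length(unique(md$genotype[sel])) < 2) next
        for (f in colnames(feats)) {
            res <- tryCatch(
                nestedAnova(feats[sel, f], md$genotype[sel],
                            md$mouse_id[sel]),
                error = function(e) NULL)
            if (!is.null(res))
                out[[paste(s, f, sep = ".")]] <- res
        }
    }
    out
}

.shollBySubregion <- function(se, md, alpha) {
    sholl <- S4Vectors::metadata(se)$sholl
    if (is.null(sholl)) return(NULL)
    sholl <- sholl[rownames(md)]
    out <- list()
    for (s in unique(md$subregion)) {
        sel <- md$subregion == s
        if (length(unique(md$genotype[sel])) < 2) next
        out[[s]] <- tryCatch(
            shollProfileCompare(sholl[sel], md$genotype[sel], alpha = alpha),
            error = function(e) NULL)
    }
    out
}

#' @export
print.astroPipelineReport <- function(x, ...) {
    cat("astromorph pipeline report (seed ", x$seed, ")\n", sep = "")
    for (age in names(x$ageGroups)) {
        ag <- x$ageGroups[[age]]
        cat("  age ", age, " mo: n = ", length(ag$labels), ", retained ",
            ag$retention$retainedK, " PC(s), k = ", ag$dapc@k,
            " (", ag$chosenAlgorithm, ")\n", sep = "")
    }
    invisible(x)
}

#' Render a pipeline report to markdown
#'
#' Writes a human-readable markdown summary of a pipeline run: per age
#' group the eigenvalue / retention table, the index-vote table, cluster
#' proportions per genotype with the chi-square test, the complexity
#' ranking, the retained-variable characterization (or a note when no
#' variable was retained), and the significant Sholl radii per subregion.
#'
#' @param report an `astroPipelineReport` from [runPipeline()].
#' @param path output file path (`.md`).
#' @return invisibly, the path.
#' @export
renderReport <- function(report, path) {
    ln <- character(0)
    add <- function(...) ln <<- c(ln, paste0(...))
    add("# Astrocyte morphotype pipeline report")
    add("")
    add("Master seed: ", report$seed)
    for (age in names(report$ageGroups)) {
        ag <- report$ageGroups[[age]]
        add("", paste0("## Age group ", age, " months"), "")
        add("Cells analysed: ", length(ag$labels))
        ev <- ag$retention$eigenvalues
        add("", "### Component retention", "")
        add("| rank | eigenvalue | retained |", "|---|---|---|")
        for (i in seq_along(ev))
            add("| ", i, " | ", sprintf("%.3f", ev[i]), " | ",
                ifelse(i <= ag$retention$retainedK, "yes", "no"), " |")
        add("", "Kaiser k = ", ag$retention$kaiserK, "; Horn k = ",
            ag$retention$hornK, "; retained = ", ag$retention$retainedK)
        add("", "### k selection (index votes)", "")
        v <- ag$kSelection$votes
        add("| k | votes |", "|---|---|")
        for (k in names(v)) add("| ", k, " | ", v[[k]], " |")
        add("", "Chosen k = ", ag$kSelection$chosenK, "; algorithm: ",
            ag$chosenAlgorithm)
        add("", "### Cluster proportions by genotype", "")
        add("| genotype | cluster | n | percent |", "|---|---|---|---|")
        pr <- ag$proportions
        for (i in seq_len(nrow(pr)))
            add("| ", pr$genotype[i], " | ", pr$cluster[i], " | ", pr$n[i],
                " | ", sprintf("%.1f%%", pr$percent[i]), " |")
        if (!is.null(ag$chiSquare))
            add("", "Pearson chi-square = ",
                sprintf("%.2f", ag$chiSquare$statistic), ", df = ",
                ag$chiSquare$df, ", p = ",
                format.pval(ag$chiSquare$p.value, digits = 3))
        add("", "### Cluster complexity ranking", "")
        cx <- ag$complexity
        for (i in order(cx$rank))
            add("- cluster ", cx$cluster[i], ": score ",
                sprintf("%.2f", cx$score[i]), " (", cx$label[i], ")")
        add("", "### Cluster characterization", "")
        if (length(ag$retainedVariables) == 0) {
            add("no retained variables")
        } else {
            for (f in ag$retainedVariables) {
                kw <- ag$characterization[[f]]$kw
                add("- ", f, ": Kruskal-Wallis H = ",
                    sprintf("%.2f", kw$statistic), ", p = ",
                    format.pval(kw$p.value, digits = 3))
            }
        }
        if (length(ag$shollComparison)) {
            add("", "### Sholl-profile comparison (per subregion)", "")
            for (s in names(ag$shollComparison)) {
                sc <- ag$shollComparison[[s]]
                if (is.null(sc)) next
                sig <- sc$significantRadii
                add("- ", s, ": significant radii ",
                    if (length(sig)) paste(sig, collapse = ", ") else "none")
            }
        }
    }
    writeLines(ln, path)
    invisible(path)
}
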