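#' Read an SWC skeleton file
#'
#' Parses a classic 7-column SWC file (id, type, x, y, z, radius, parent;
#' space- or tab-delimited, `#` comment lines ignored) into a validated
#' [AstrocyteSkeleton-class]. Nodes are returned in topological order
#' (parent before child) regardless of file order. Coordinates and radii
#' are taken as micrometres; no unit conversion is attempted.
#'
#' @param path path to an SWC text file.
#' @param cellId cell identifier; defaults to the file name without
#'   extension.
#' @return an [AstrocyteSkeleton-class].
#' @examples
#' sk <- simulateSkeleton(morphotypeParams("simple"), seed = 1)
#' f <- tempfile(fileext = ".swc")
#' writeSWC(sk, f)
#' readSWC(f)
#' @export
readSWC <- function(path, cellId = sub("\\.[sS][wW][cC]$", "", basename(path))) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) stop("no data lines in ", path)
    fields <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(fields) != 7L)
    if (length(bad))
        stop("malformed line ", lineNo[bad[1L]], " in ", path,
             ": expected 7 fields, got ", lengths(fields)[bad[1L]])
    m <- suppressWarnings(
        matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
    if (anyNA(m)) {
        bad <- which(apply(is.na(m), 1L, any))[1L]
        stop("malformed line ", lineNo[bad], " in ", path,
             ": non-numeric field")
    }
    nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                        x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                        parent = as.integer(m[, 7]))
    AstrocyteSkeleton(nodes, cellId = cellId)
}

#' Write a skeleton to an SWC file
#'
#' Emits standard 7-column whitespace-separated SWC with a `#` header
#' comment carrying the cell id. Node ids are renumbered 1..N in
#' topological order, so write -> read -> write is byte-stable.
#'
#' @param skeleton an [AstrocyteSkeleton-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSWC <- function(skeleton, path) {
    stopifnot(is(skeleton, "AstrocyteSkeleton"))
    validObject(skeleton)
    nd <- skeleton@nodes
    newId <- seq_len(nrow(nd))
    newParent <- ifelse(nd$parent == -1L, -1L, match(nd$parent, nd$id))
    body <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                    newId, nd$type, nd$x, nd$y, nd$z, nd$radius, newParent)
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write ", path, ": ",
                                             conditionMessage(e)))
    on.exit(close(con))
    writeLines(c(paste0("# cell_id: ", skeleton@cellId), body), con)
    invisible(path)
}

.GENOTYPES <- c("WT", "TAU")
.AGE_GROUPS <- c(3L, 9L, 23L)
.SUBREGIONS <- c("CA1so", "CA1sr", "Sub")

#' Load a cohort of skeletons from a manifest
#'
#' Reads a CSV manifest with columns
#' `cell_id,swc_path,mouse_id,genotype,age_group,subregion`, loads every SWC
#' file, validates tokens (genotype in WT/TAU, age group in 3/9/23,
#' subregion in CA1so/CA1sr/Sub), and returns the skeletons with their
#' metadata. Relative SWC paths are resolved against the manifest's
#' directory. Cells are never pooled: one SWC file is one astrocyte.
#'
#' @param manifestPath path to the manifest CSV.
#' @param verbose log the genotype x age x subregion breakdown.
#' @return a list with elements `skeletons` (named list of
#'   [AstrocyteSkeleton-class]) and `metadata` (data.frame, one row per
#'   cell, in manifest order).
#' @export
loadCohort <- function(manifestPath, verbose = TRUE) {
    man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
    need <- c("cell_id", "swc_path", "mouse_id", "genotype", "age_group",
              "subregion")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ","))
    if (anyDuplicated(man$cell_id))
        stop("duplicate cell_id in manifest")
    if (!all(man$genotype %in% .GENOTYPES))
        stop("unknown genotype token: ",
             paste(unique(setdiff(man$genotype, .GENOTYPES)), collapse = ", "))
    if (!all(man$age_group %in% .AGE_GROUPS))
        stop("unknown age_group token: ",
             paste(unique(setdiff(man$age_group, .AGE_GROUPS)), collapse = ", "))
    if (!all(man$subregion %in% .SUBREGIONS))
        stop("unknown subregion token: ",
             paste(unique(setdiff(man$subregion, .SUBREGIONS)), collapse = ", "))
    base <- dirname(manifestPath)
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$swc_path), man$swc_path,
                    file.path(base, man$swc_path))
    skeletons <- vector("list", nrow(man))
    names(skeletons) <- man$cell_id
    failures <- character(0)
    for (i in seq_len(nrow(man))) {
        res <- tryCatch(readSWC(paths[i], cellId = man$cell_id[i]),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
            failures <- c(failures, sprintf("%s: %s", man$cell_id[i], res))
        } else {
            skeletons[[i]] <- res
        }
    }
    if (length(failures))
        stop("failed to load ", length(failures), " cell(s):\n  ",
             paste(failures, collapse = "\n  "))
    if (verbose) {
        tab <- table(genotype = man$genotype, age = man$age_group,
                     subregion = man$subregion)
        message("loaded ", nrow(man), " cells")
        for (g in dimnames(tab)$genotype) for (a in dimnames(tab)$age)
            for (s in dimnames(tab)$subregion)
                if (tab[g, a, s] > 0)
                    message("  ", g, " / ", a, " mo / ", s, ": ", tab[g, a, s])
    }
    list(skeletons = skeletons, metadata = man)
}
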