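#' Read an RPKM expression matrix and its sample-to-tissue-group map
#'
#' The matrix TSV has gene identifiers in the first column and one column per
#' sample (header row). The group map is a 2-column TSV (`sample`,
#' `tissue_group`, header row). Every sample must have a group, every group
#' at least one sample, and all values must be non-negative.
#'
#' @param matrixPath RPKM matrix TSV.
#' @param groupsPath sample-to-group TSV.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `rpkm`
#'   and colData column `tissue_group`.
#' @export
readExpressionMatrix <- function(matrixPath, groupsPath) {
    if (!file.exists(matrixPath))
        stop(sprintf("expression matrix not found: %s", matrixPath))
    if (!file.exists(groupsPath))
        stop(sprintf("sample group map not found: %s", groupsPath))
    df <- utils::read.table(matrixPath, sep = "\t", header = TRUE,
        row.names = 1, check.names = FALSE, quote = "", comment.char = "")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    gm <- utils::read.table(groupsPath, sep = "\t", header = TRUE,
        colClasses = "character", quote = "", comment.char = "")
    if (!all(c("sample", "tissue_group") %in% names(gm)))
        stop("group map must have columns sample, tissue_group")
    groups <- stats::setNames(gm$tissue_group, gm$sample)
    missing <- setdiff(colnames(m), names(groups))
    if (length(missing))
        stop(sprintf("sample(s) without tissue group: %s",
            paste(missing, collapse = ", ")))
    if (any(m < 0) || anyNA(m))
        stop("RPKM values must be non-negative and non-missing")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(rpkm = m),
        colData = S4Vectors::DataFrame(
            tissue_group = unname(groups[colnames(m)]),
            row.names = colnames(m)))
}

# extract (matrix, groups) from a SummarizedExperiment or a plain matrix
.rpkmAndGroups <- function(x, groups = NULL) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "rpkm")
        cd <- SummarizedExperiment::colData(x)
        if (!"tissue_group" %in% names(cd))
            stop("colData must contain a tissue_group column")
        groups <- stats::setNames(as.character(cd$tissue_group), colnames(m))
    } else {
        m <- as.matrix(x)
        if (is.null(groups))
            stop("groups must be supplied with a plain matrix")
        groups <- stats::setNames(as.character(groups[colnames(m)]), colnames(m))
    }
    if (anyNA(groups) || any(!nzchar(groups)))
        stop("every sample must have a tissue group")
    if (any(m < 0)) stop("RPKM values must be non-negative")
    list(m = m, groups = groups)
}

#' Per-tissue-group mean RPKM
#'
#' Groups the samples by tissue and returns the arithmetic mean RPKM of each
#' gene in each tissue group.
#'
#' @param x a `SummarizedExperiment` from [readExpressionMatrix()], or a
#'   numeric gene x sample matrix.
#' @param groups named character vector sample -> group (only for a plain
#'   matrix).
#' @return Numeric gene x tissue-group matrix.
#' @export
groupMeans <- function(x, groups = NULL) {
    d <- .rpkmAndGroups(x, groups)
    gs <- split(seq_len(ncol(d$m)), d$groups[colnames(d$m)])
    out <- vapply(gs, function(idx)
        rowMeans(d$m[, idx, drop = FALSE]), numeric(nrow(d$m)))
    if (is.null(dim(out)))
        out <- matrix(out, nrow = nrow(d$m), dimnames = list(rownames(d$m), names(gs)))
    out
}

#' Classify genes as preferentially expressed in one tissue group
#'
#' A gene is assigned to group `g` iff its mean RPKM in `g` is at least
#' `foldThreshold` times its mean in every other group ("three-fold or
#' higher" read inclusively, so the default is `>= 3`), and the expression
#' floor passes (`minRpkm`, default 10, guarding against calling a
#' barely-expressed gene "preferential"). With `foldThreshold > 1` at most
#' one group can dominate, so the map is a partial function: genes failing
#' either condition (including ties at the maximum) are absent.
#'
#' @param means gene x group matrix from [groupMeans()] (at least 2 groups).
#' @param foldThreshold dominance ratio, > 1; default 3.
#' @param minRpkm expression floor in RPKM; default 10.
#' @param floorOn whether the floor applies to the focal (candidate) group's
#'   mean (default) or to the gene's overall mean across groups.
#' @return Named character vector: gene -> assigned tissue group.
#' @export
classifyPreferential <- function(means, foldThreshold = 3, minRpkm = 10,
                                 floorOn = c("focal", "overall")) {
    floorOn <- match.arg(floorOn)
    means <- as.matrix(means)
    if (ncol(means) < 2L)
        stop("at least 2 tissue groups are required")
    if (!(foldThreshold > 1)) stop("foldThreshold must be > 1")
    if (minRpkm < 0) stop("minRpkm must be >= 0")
    if (nrow(means) == 0L)
        return(stats::setNames(character(0), character(0)))
    top <- apply(means, 1L, max)
    arg <- apply(means, 1L, which.max)
    second <- vapply(seq_len(nrow(means)), function(i)
        max(means[i, -arg[i]]), numeric(1))
    floorVal <- switch(floorOn, focal = top, overall = rowMeans(means))
    ok <- top > 0 & top >= foldThreshold * second & floorVal >= minRpkm
    stats::setNames(colnames(means)[arg[ok]], rownames(means)[ok])
}

#' Build the tissue-preferential-expression gene-set collection
#'
#' Runs [groupMeans()] then [classifyPreferential()] and assembles one gene
#' set per tissue group with at least one assigned gene. Each gene appears in
#' at most one set (dominance is mutually exclusive).
#'
#' @inheritParams groupMeans
#' @inheritParams classifyPreferential
#' @param categoryId,organism,idSpace,source collection metadata.
#' @return A [GeneSetCollection-class].
#' @export
buildTissueCollection <- function(x, groups = NULL, foldThreshold = 3,
                                  minRpkm = 10, floorOn = c("focal", "overall"),
                                  categoryId = "tissue-preferential",
                                  organism = "dm", idSpace = "mod_primary",
                                  source = "tissue-expression") {
    means <- groupMeans(x, groups)
    calls <- classifyPreferential(means, foldThreshold, minRpkm, floorOn)
    byGroup <- split(names(calls), unname(calls))
    sets <- lapply(names(byGroup), function(g)
        GeneSet(g, byGroup[[g]], categoryId = categoryId))
    GeneSetCollection(sets, categoryId = categoryId, organism = organism,
        idSpace = idSpace, source = source)
}
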