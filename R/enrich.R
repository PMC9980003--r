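#' Upper-tail hypergeometric probability
#'
#' The over-representation p-value: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` — drawing `n` genes without replacement
#' from a background of `N` genes of which `K` belong to the set, the
#' probability of seeing `k` or more set members. Computed as an explicit
#' tail sum of binomial-coefficient ratios on the log scale.
#'
#' @param k observed overlap (input genes in the set).
#' @param K set size within the background.
#' @param n analysed input size.
#' @param N background population size.
#' @return Probability in `[0, 1]`. Arguments are recycled to the longest
#'   length.
#' @examples
#' hypergeomUpperTail(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    args <- cbind(k = k, K = K, n = n, N = N)
    if (anyNA(args) || any(args != floor(args)))
        stop("k, K, n, N must be non-missing integers")
    k <- args[, "k"]; K <- args[, "K"]; n <- args[, "n"]; N <- args[, "N"]
    if (any(k < 0)) stop("constraint violated: k >= 0")
    if (any(K > N)) stop("constraint violated: K <= N")
    if (any(n > N)) stop("constraint violated: n <= N")
    if (any(k > pmin(n, K))) stop("constraint violated: k <= min(n, K)")
    vapply(seq_along(k), function(j) {
        if (k[j] <= 0L) return(1)
        i <- k[j]:min(n[j], K[j])
        p <- sum(exp(lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) -
            lchoose(N[j], n[j])))
        min(1, max(0, p))
    }, numeric(1))
}

#' Fold enrichment
#'
#' `(k/n) / (K/N)`: the observed fraction of input genes in the set over the
#' fraction expected under uniform sampling from the background.
#'
#' @inheritParams hypergeomUpperTail
#' @return Numeric ratio (vectorised).
#' @examples
#' foldEnrichment(3, 5, 5, 20)  # 2.4
#' @export
foldEnrichment <- function(k, K, n, N) {
    if (any(K == 0)) stop("fold enrichment undefined: K = 0")
    if (any(n == 0)) stop("fold enrichment undefined: n = 0")
    (k / n) / (K / N)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni family-wise correction and the Benjamini-Hochberg and
#' Benjamini-Yekutieli step-up false-discovery-rate procedures, via
#' [stats::p.adjust()]. Output order matches input order.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @param method one of `bonferroni`, `bh`, `by`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh", "by")) {
    method <- match.arg(method)
    if (length(p) == 0L) return(numeric(0))
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must be in [0, 1]")
    stats::p.adjust(p, method = switch(method,
        bonferroni = "bonferroni", bh = "BH", by = "BY"))
}

#' Hypergeometric over-representation test of a gene list against a collection
#'
#' For each gene set with at least one background member, tests whether the
#' input list shares more genes with the set than expected when drawing the
#' list uniformly from the background universe.
#'
#' The background defaults to the union of all genes in the collection plus
#' the analysed genes. With a user-supplied background (e.g. a kinase
#' sub-library for a focused screen), `N` is the background size, set
#' memberships are intersected with the background, and input genes outside
#' the background are dropped from the analysis and reported.
#'
#' All three adjustments are computed over the sets actually tested (`K > 0`)
#' within this collection. Results are ordered by raw p ascending, ties
#' broken by fold enrichment descending, then set id.
#'
#' @param genes a [GeneList-class] (or character vector).
#' @param collection a [GeneSetCollection-class].
#' @param background optional [GeneList-class] or character vector defining
#'   the universe.
#' @return An [EnrichmentRun-class].
#' @export
enrich <- function(genes, collection, background = NULL) {
    stopifnot(is(collection, "GeneSetCollection"))
    if (is(genes, "GeneList")) {
        if (!is.na(genes@organism) && genes@organism != collection@organism)
            stop(sprintf("organism mismatch: list is '%s', collection is '%s'",
                genes@organism, collection@organism))
        listId <- genes@listId
        g <- genes@genes
    } else {
        listId <- "gene_list"
        g <- unique(as.character(genes))
    }
    mem <- members(collection)
    dropped <- character(0)
    if (!is.null(background)) {
        bg <- if (is(background, "GeneList")) background@genes else
            unique(as.character(background))
        dropped <- setdiff(g, bg)
        g <- g[g %in% bg]
        mem <- lapply(mem, function(m) m[m %in% bg])
    } else {
        bg <- unique(c(unlist(mem, use.names = FALSE), g))
    }
    if (length(g) == 0L)
        stop("empty effective input: no analysed genes within the background")
    N <- length(bg)
    n <- length(g)
    Ks <- lengths(mem)
    keep <- Ks > 0L
    mem <- mem[keep]
    Ks <- Ks[keep]
    ov <- lapply(mem, function(m) g[g %in% m])
    ks <- lengths(ov)
    pRaw <- hypergeomUpperTail(ks, Ks, rep(n, length(ks)), rep(N, length(ks)))
    nameOf <- vapply(collection@sets[keep], function(s) s@name, character(1),
        USE.NAMES = FALSE)
    res <- data.frame(
        set_id = names(mem),
        name = nameOf,
        N = N, K = as.integer(Ks), n = n, k = as.integer(ks),
        p_raw = pRaw,
        p_bonferroni = adjustPvalues(pRaw, "bonferroni"),
        p_bh = adjustPvalues(pRaw, "bh"),
        p_by = adjustPvalues(pRaw, "by"),
        fold = foldEnrichment(ks, Ks, n, N),
        stringsAsFactors = FALSE)
    res$overlap_genes <- unname(ov)
    ord <- order(res$p_raw, -res$fold, res$set_id)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    covered <- unique(unlist(mem, use.names = FALSE))
    new("EnrichmentRun",
        results = res,
        backgroundSize = as.integer(N),
        inputSize = as.integer(n),
        droppedGenes = dropped,
        uncoveredGenes = g[!g %in% covered],
        categoryId = collection@categoryId,
        listId = listId)
}

#' Filter enrichment results at a p-value cutoff
#'
#' Retains results whose chosen column is strictly below the cutoff (so a
#' result with `p_raw = 1` is dropped even at cutoff 1.0). Ordering is
#' preserved.
#'
#' @param run an [EnrichmentRun-class].
#' @param column one of `p_raw`, `p_bonferroni`, `p_bh`, `p_by`.
#' @param cutoff probability threshold.
#' @return A filtered [EnrichmentRun-class].
#' @export
filterResults <- function(run, column = c("p_raw", "p_bonferroni", "p_bh", "p_by"),
                          cutoff = 0.05) {
    column <- match.arg(column)
    stopifnot(is(run, "EnrichmentRun"))
    keep <- run@results[[column]] < cutoff
    run@results <- run@results[keep, , drop = FALSE]
    rownames(run@results) <- NULL
    run
}

#' Write enrichment results as TSV
#'
#' Columns: set_id, name, N, K, n, k, p_raw, p_bonferroni, p_bh, p_by, fold,
#' overlap (`;`-joined genes).
#'
#' @param run an [EnrichmentRun-class].
#' @param path output file.
#' @param uncoveredPath optional file for the uncovered-gene report (analysed
#'   genes in no set of the collection), one id per line.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(run, path, uncoveredPath = NULL) {
    df <- run@results
    df$overlap <- vapply(df$overlap_genes, function(x)
        paste(sort(x), collapse = ";"), character(1))
    df$overlap_genes <- NULL
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(uncoveredPath))
        writeLines(run@uncoveredGenes, uncoveredPath)
    invisible(path)
}
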