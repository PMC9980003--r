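#' Enrich several gene lists against the same collection
#'
#' Each list is analysed independently with the identical collection and
#' background; run order matches input order. Any single-list failure aborts
#' with the offending list named.
#'
#' @param lists list of [GeneList-class] objects.
#' @param collection a [GeneSetCollection-class].
#' @param background optional shared background.
#' @return List of [EnrichmentRun-class], named by list id.
#' @export
enrichMulti <- function(lists, collection, background = NULL) {
    stopifnot(length(lists) >= 1L)
    orgs <- unique(vapply(lists, function(l)
        if (is(l, "GeneList")) l@organism else NA_character_, character(1)))
    orgs <- orgs[!is.na(orgs)]
    if (length(orgs) > 1L)
        stop(sprintf("lists mix organisms: %s", paste(orgs, collapse = ", ")))
    runs <- lapply(lists, function(l) {
        id <- if (is(l, "GeneList")) l@listId else "gene_list"
        tryCatch(enrich(l, collection, background),
            error = function(e) stop(sprintf("list '%s': %s", id,
                conditionMessage(e)), call. = FALSE))
    })
    names(runs) <- vapply(runs, function(r) r@listId, character(1))
    runs
}

#' Build a multi-list comparison matrix for heatmap/dot-plot display
#'
#' Rows are the gene sets passing the cutoff (strictly below, on the chosen
#' p column) in at least one run; columns are the input lists. Cells carry
#' the chosen display value; cells that were untestable for a run (the set
#' had no background member there) are `NA`, distinct from "tested, not
#' significant" cells, which keep their true value flagged
#' `significant = FALSE`.
#'
#' @param runs list of [EnrichmentRun-class] sharing one collection.
#' @param cutoffColumn p column used for row selection
#'   (`p_raw|p_bonferroni|p_bh|p_by`).
#' @param cutoff significance threshold (strict `<`).
#' @param value display value: `neglog10p` (-log10 of the cutoff column;
#'   default, common heatmap practice), `p`, or `fold`.
#' @return A [ComparisonMatrix-class].
#' @export
comparisonMatrix <- function(runs, cutoffColumn = c("p_raw", "p_bonferroni",
                             "p_bh", "p_by"), cutoff = 0.05,
                             value = c("neglog10p", "p", "fold")) {
    cutoffColumn <- match.arg(cutoffColumn)
    value <- match.arg(value)
    stopifnot(length(runs) >= 1L)
    cats <- unique(vapply(runs, function(r) r@categoryId, character(1)))
    if (length(cats) > 1L)
        stop(sprintf("runs span several collections: %s",
            paste(cats, collapse = ", ")))
    listIds <- vapply(runs, function(r) r@listId, character(1), USE.NAMES = FALSE)
    if (anyDuplicated(listIds))
        listIds <- make.unique(listIds)
    sig <- lapply(runs, function(r)
        r@results$set_id[r@results[[cutoffColumn]] < cutoff])
    rows <- sort(unique(unlist(sig, use.names = FALSE)))
    if (length(rows) == 0L)
        stop("nothing passes cutoff")
    nr <- length(rows); nc <- length(runs)
    mk <- function(init) matrix(init, nr, nc, dimnames = list(rows, listIds))
    p <- mk(NA_real_); fold <- mk(NA_real_); k <- mk(NA_real_)
    tested <- mk(FALSE); signif <- mk(FALSE); val <- mk(NA_real_)
    setNames_ <- stats::setNames(rep(NA_character_, nr), rows)
    for (j in seq_len(nc)) {
        res <- runs[[j]]@results
        hit <- match(rows, res$set_id)
        has <- !is.na(hit)
        tested[has, j] <- TRUE
        p[has, j] <- res[[cutoffColumn]][hit[has]]
        fold[has, j] <- res$fold[hit[has]]
        k[has, j] <- res$k[hit[has]]
        signif[has, j] <- res[[cutoffColumn]][hit[has]] < cutoff
        setNames_[rows[has]] <- res$name[hit[has]]
    }
    val <- switch(value,
        p = p,
        fold = fold,
        neglog10p = -log10(p))
    new("ComparisonMatrix",
        setIds = rows, setNames = unname(setNames_), listIds = listIds,
        value = val, p = p, fold = fold, k = k,
        tested = tested, significant = signif,
        valueType = value, cutoffColumn = cutoffColumn, cutoff = cutoff)
}

#' Write a comparison matrix as TSV
#'
#' Wide plot-ready table: one row per gene set, one column per list with the
#' display value, plus companion `<list>.significant` flag columns. `NA`
#' marks untestable cells.
#'
#' @param cm a [ComparisonMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComparisonMatrix <- function(cm, path) {
    df <- data.frame(set_id = cm@setIds, name = cm@setNames,
        stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(cm@listIds)) {
        df[[cm@listIds[j]]] <- cm@value[, j]
        df[[paste0(cm@listIds[j], ".significant")]] <- cm@significant[, j]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Build the bipartite gene/gene-set overlap graph
#'
#' One `gene_set` node per selected set and one `gene` node per gene in the
#' union of their overlap genes; an edge links a set to each of its overlap
#' genes. Genes shared by several selected sets get degree > 1, which is what
#' the network view is for. Gene nodes are restricted to overlap genes (input
#' genes found in the set), not full set membership. Selected sets with an
#' empty overlap are dropped with a warning (the graph carries no isolated
#' set nodes).
#'
#' @param run an [EnrichmentRun-class].
#' @param selectedSets character vector of set ids present in the run.
#' @return A [BipartiteGraph-class].
#' @export
buildBipartiteGraph <- function(run, selectedSets) {
    res <- run@results
    unknown <- setdiff(selectedSets, res$set_id)
    if (length(unknown))
        stop(sprintf("unknown set id(s): %s", paste(unknown, collapse = ", ")))
    idx <- match(selectedSets, res$set_id)
    ov <- res$overlap_genes[idx]
    empty <- lengths(ov) == 0L
    if (any(empty)) {
        warning(sprintf("set(s) with empty overlap dropped: %s",
            paste(selectedSets[empty], collapse = ", ")))
        idx <- idx[!empty]; ov <- ov[!empty]; selectedSets <- selectedSets[!empty]
    }
    genes <- sort(unique(unlist(ov, use.names = FALSE)))
    nodes <- rbind(
        data.frame(id = selectedSets, node_type = "gene_set",
            label = res$name[idx], stringsAsFactors = FALSE),
        data.frame(id = genes, node_type = "gene", label = genes,
            stringsAsFactors = FALSE))
    edges <- data.frame(
        set = rep(selectedSets, lengths(ov)),
        gene = unlist(ov, use.names = FALSE),
        stringsAsFactors = FALSE)
    new("BipartiteGraph", nodes = nodes, edges = edges)
}

.asIgraph <- function(g) {
    vert <- g@nodes
    names(vert)[1] <- "name"
    igraph::graph_from_data_frame(g@edges, directed = FALSE, vertices = vert)
}

#' Export a bipartite graph to GraphML or sectioned TSV
#'
#' GraphML (via igraph) carries `node_type` and `label` as node attributes
#' and is accepted by Cytoscape/Gephi. The TSV format is a single file whose
#' `record` column distinguishes node rows (`id`, `node_type`, `label`) from
#' edge rows (`source`, `target`); both formats round-trip through
#' [importGraph()].
#'
#' @param g a [BipartiteGraph-class].
#' @param path output file.
#' @param format `graphml` or `tsv`.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(g, path, format = c("graphml", "tsv")) {
    format <- match.arg(format)
    stopifnot(is(g, "BipartiteGraph"))
    if (format == "graphml") {
        igraph::write_graph(.asIgraph(g), path, format = "graphml")
    } else {
        nd <- g@nodes
        df <- rbind(
            data.frame(record = "node", id = nd$id, node_type = nd$node_type,
                label = nd$label, source = "", target = "",
                stringsAsFactors = FALSE),
            data.frame(record = "edge", id = "", node_type = "", label = "",
                source = g@edges$set, target = g@edges$gene,
                stringsAsFactors = FALSE))
        utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Re-import a graph written by [exportGraph()]
#'
#' @param path file written by [exportGraph()].
#' @param format `graphml` or `tsv`.
#' @return A [BipartiteGraph-class].
#' @export
importGraph <- function(path, format = c("graphml", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("graph file not found: %s", path))
    if (format == "graphml") {
        ig <- igraph::read_graph(path, format = "graphml")
        nodes <- data.frame(
            id = igraph::vertex_attr(ig, "name"),
            node_type = igraph::vertex_attr(ig, "node_type"),
            label = igraph::vertex_attr(ig, "label"),
            stringsAsFactors = FALSE)
        el <- igraph::as_edgelist(ig, names = TRUE)
        typeOf <- stats::setNames(nodes$node_type, nodes$id)
        edges <- data.frame(set = character(nrow(el)), gene = character(nrow(el)),
            stringsAsFactors = FALSE)
        if (nrow(el)) {
            swap <- typeOf[el[, 1]] != "gene_set"
            edges$set <- ifelse(swap, el[, 2], el[, 1])
            edges$gene <- ifelse(swap, el[, 1], el[, 2])
        }
    } else {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
            colClasses = "character", quote = "", comment.char = "")
        nd <- df[df$record == "node", c("id", "node_type", "label")]
        ed <- df[df$record == "edge", c("source", "target")]
        nodes <- data.frame(id = nd$id, node_type = nd$node_type,
            label = nd$label, stringsAsFactors = FALSE)
        edges <- data.frame(set = ed$source, gene = ed$target,
            stringsAsFactors = FALSE)
    }
    rownames(nodes) <- rownames(edges) <- NULL
    new("BipartiteGraph", nodes = nodes, edges = edges)
}

#' Top-n bar-graph table
#'
#' The `topN` sets by raw p (the run is already sorted) with a `bar_value`
#' column holding the chosen bar height, alongside the raw statistics —
#' plot-ready for a bar graph of the strongest enrichments.
#'
#' @param run an [EnrichmentRun-class].
#' @param topN number of rows to keep (clamped to the result count).
#' @param value bar height: `neglog10p` or `fold`.
#' @return data.frame.
#' @export
barTable <- function(run, topN = 10L, value = c("neglog10p", "fold")) {
    value <- match.arg(value)
    stopifnot(topN >= 1L)
    df <- utils::head(run@results, topN)
    df$bar_value <- switch(value,
        neglog10p = -log10(df$p_raw),
        fold = df$fold)
    df$overlap <- vapply(df$overlap_genes, function(x)
        paste(sort(x), collapse = ";"), character(1))
    df$overlap_genes <- NULL
    rownames(df) <- NULL
    df
}
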