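#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname accessors
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname accessors
#' @export
setGeneric("results", function(x) standardGeneric("results"))

#' Accessors for setora classes
#'
#' `setIds` returns the set identifiers of a collection; `members` the member
#' genes of a set (or a named list over a collection); `geneUniverse` the
#' union of all member genes; `nSets` the number of sets; `results` the
#' result table of an [EnrichmentRun-class].
#'
#' @name accessors
#' @return See individual descriptions.
NULL

setMethod("setIds", "GeneSetCollection", function(x)
    vapply(x@sets, function(s) s@setId, character(1), USE.NAMES = FALSE))

setMethod("members", "GeneSet", function(x) x@members)

setMethod("members", "GeneSetCollection", function(x) {
    out <- lapply(x@sets, function(s) s@members)
    names(out) <- setIds(x)
    out
})

setMethod("geneUniverse", "GeneSetCollection", function(x)
    unique(unlist(lapply(x@sets, function(s) s@members), use.names = FALSE)))

setMethod("nSets", "GeneSetCollection", function(x) length(x@sets))

setMethod("results", "EnrichmentRun", function(x) x@results)

#' Subset a collection by set id
#'
#' @param x a [GeneSetCollection-class].
#' @param i character set id(s) or numeric index.
#' @param j,drop,... ignored.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i, j, ...) x@sets[[i]])

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet %s (%s): %d gene(s)\n",
        object@setId, object@name, length(object@members)))
})

setMethod("show", "GeneSetCollection", function(object) {
    sizes <- lengths(members(object))
    cat(sprintf("GeneSetCollection '%s' [%s, %s, id space %s]: %d set(s)\n",
        object@categoryId, object@organism, object@source, object@idSpace,
        nSets(object)))
    if (length(sizes))
        cat(sprintf("  set sizes: min %d / median %g / max %d; universe %d gene(s)\n",
            min(sizes), stats::median(sizes), max(sizes),
            length(geneUniverse(object))))
})

setMethod("show", "GeneList", function(object) {
    cat(sprintf("GeneList '%s' [%s]: %d gene(s)\n",
        object@listId, object@organism, length(object@genes)))
})

setMethod("show", "Ontology", function(object) {
    cat(sprintf("Ontology: %d term(s) (%d obsolete), relations: %s, %d root(s)\n",
        nrow(object@terms), sum(object@terms$is_obsolete),
        paste(object@relations, collapse = "+"),
        length(ontologyRoots(object))))
})

setMethod("show", "IDMapTable", function(object) {
    cat(sprintf("IDMapTable [%s]: %d entrie(s), %d alias(es)\n",
        object@organism, nrow(object@entries),
        length(unique(object@entries$alias))))
})

setMethod("show", "MappingReport", function(object) {
    cat(sprintf(
        "MappingReport: %d mapped, %d updated, %d ambiguous, %d unmapped, %d collapsed\n",
        nrow(object@mapped), nrow(object@updated), length(object@ambiguous),
        length(object@unmapped), nrow(object@collapsed)))
})

setMethod("show", "EnrichmentRun", function(object) {
    cat(sprintf(
        "EnrichmentRun '%s' vs '%s': %d set(s) tested, N = %d, n = %d\n",
        object@listId, object@categoryId, nrow(object@results),
        object@backgroundSize, object@inputSize))
    cat(sprintf("  %d dropped gene(s), %d uncovered gene(s)\n",
        length(object@droppedGenes), length(object@uncoveredGenes)))
    if (nrow(object@results)) {
        top <- utils::head(object@results, 3L)
        cat("  top sets:\n")
        for (i in seq_len(nrow(top)))
            cat(sprintf("    %s  p_raw = %.3g  fold = %.2f  k = %d\n",
                top$set_id[i], top$p_raw[i], top$fold[i], top$k[i]))
    }
})

setMethod("show", "ComparisonMatrix", function(object) {
    cat(sprintf(
        "ComparisonMatrix: %d set(s) x %d list(s), value = %s (cutoff: %s < %g)\n",
        length(object@setIds), length(object@listIds), object@valueType,
        object@cutoffColumn, object@cutoff))
})

setMethod("show", "BipartiteGraph", function(object) {
    cat(sprintf("BipartiteGraph: %d gene-set node(s), %d gene node(s), %d edge(s)\n",
        sum(object@nodes$node_type == "gene_set"),
        sum(object@nodes$node_type == "gene"),
        nrow(object@edges)))
})
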