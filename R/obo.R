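#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas of an OBO 1.2 file, keeping only the requested
#' parent relations (GO roll-up convention: `is_a` and `part_of`;
#' regulates-type edges are not traversed). Obsolete terms are loaded but
#' contribute no edges to traversal. `alt_id`s are recorded for resolution of
#' annotations made against secondary identifiers.
#'
#' The retained graph is validated at load: every parent reference must
#' resolve to a loaded term and the graph must be acyclic (an error reports
#' one offending cycle).
#'
#' @param path OBO file.
#' @param relations relations to retain, a subset of `c("is_a", "part_of")`.
#' @return An [Ontology-class].
#' @export
readObo <- function(path, relations = c("is_a", "part_of")) {
    if (!file.exists(path))
        stop(sprintf("OBO file not found: %s", path))
    relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
    lines <- readLines(path)

    termIds <- character(0)
    names_ <- character(0)
    namespaces <- character(0)
    obsolete <- logical(0)
    parents <- list()
    altIds <- character(0)

    inTerm <- FALSE
    cur <- NULL
    flush <- function(cur) {
        if (is.null(cur) || is.null(cur$id)) return()
        termIds[[length(termIds) + 1L]] <<- cur$id
        names_[[length(names_) + 1L]] <<- if (is.null(cur$name)) cur$id else cur$name
        namespaces[[length(namespaces) + 1L]] <<-
            if (is.null(cur$namespace)) NA_character_ else cur$namespace
        obsolete[[length(obsolete) + 1L]] <<- isTRUE(cur$obsolete)
        parents[[cur$id]] <<- if (isTRUE(cur$obsolete)) character(0) else
            unique(cur$parents)
        if (length(cur$alt)) {
            a <- stats::setNames(rep(cur$id, length(cur$alt)), cur$alt)
            altIds <<- c(altIds, a)
        }
    }
    for (ln in lines) {
        ln <- sub("\\s*!.*$", "", ln)   # strip trailing comments
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush(cur)
            inTerm <- TRUE
            cur <- list(parents = character(0), alt = character(0))
            next
        }
        if (grepl("^\\[", ln)) {        # [Typedef] etc.
            flush(cur)
            inTerm <- FALSE
            cur <- NULL
            next
        }
        if (!inTerm || !nzchar(ln)) next
        kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
        if (length(kv) != 3L) next
        key <- kv[2]; val <- trimws(kv[3])
        if (key == "id") cur$id <- val
        else if (key == "name") cur$name <- val
        else if (key == "namespace") cur$namespace <- val
        else if (key == "alt_id") cur$alt <- c(cur$alt, val)
        else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
        else if (key == "is_a" && "is_a" %in% relations)
            cur$parents <- c(cur$parents, strsplit(val, "\\s+")[[1]][1])
        else if (key == "relationship") {
            parts <- strsplit(val, "\\s+")[[1]]
            if (length(parts) >= 2L && parts[1] %in% relations)
                cur$parents <- c(cur$parents, parts[2])
        }
    }
    flush(cur)

    if (length(termIds) == 0L)
        stop(sprintf("no [Term] stanzas found in %s", path))
    if (anyDuplicated(termIds))
        stop(sprintf("duplicate term id(s): %s",
            paste(unique(termIds[duplicated(termIds)]), collapse = ", ")))
    clash <- intersect(names(altIds), termIds)
    if (length(clash))
        stop(sprintf("alt_id(s) collide with primary term id(s): %s",
            paste(clash, collapse = ", ")))

    # drop edges into obsolete parents: obsolete terms take no part in traversal
    obsSet <- termIds[obsolete]
    parents <- lapply(parents, function(p) setdiff(p, obsSet))

    dangling <- setdiff(unique(unlist(parents, use.names = FALSE)), termIds)
    if (length(dangling))
        stop(sprintf("dangling parent reference(s): %s",
            paste(dangling, collapse = ", ")))

    ont <- new("Ontology",
        terms = data.frame(term_id = termIds, name = names_,
            namespace = namespaces, is_obsolete = obsolete,
            stringsAsFactors = FALSE),
        parents = parents,
        altIds = altIds,
        relations = relations)
    cyc <- .findCycle(parents)
    if (!is.null(cyc))
        stop(sprintf("ontology graph is cyclic; one cycle: %s",
            paste(cyc, collapse = " -> ")))
    ont
}

# one cycle (as a term path) in the parent graph, or NULL if acyclic
.findCycle <- function(parents) {
    state <- new.env(parent = emptyenv())   # 1 = in stack, 2 = done
    found <- NULL
    visit <- function(id, path) {
        if (!is.null(found)) return()
        s <- state[[id]]
        if (!is.null(s)) {
            if (s == 1L) {
                i <- match(id, path)
                found <<- c(path[i:length(path)], id)
            }
            return()
        }
        state[[id]] <- 1L
        for (p in parents[[id]]) visit(p, c(path, id))
        state[[id]] <- 2L
    }
    for (id in names(parents)) {
        visit(id, character(0))
        if (!is.null(found)) return(found)
    }
    NULL
}

#' Root terms of an ontology
#'
#' Non-obsolete terms with no retained parents.
#'
#' @param ont an [Ontology-class].
#' @return Character vector of term ids.
#' @export
ontologyRoots <- function(ont) {
    ids <- ont@terms$term_id[!ont@terms$is_obsolete]
    ids[lengths(ont@parents[ids]) == 0L]
}

#' Resolve a (possibly secondary) term id to its primary id
#'
#' @param ont an [Ontology-class].
#' @param termId term id or alt id.
#' @return Primary term id; errors on an unknown id.
#' @export
resolveTermId <- function(ont, termId) {
    out <- termId
    isAlt <- termId %in% names(ont@altIds)
    out[isAlt] <- ont@altIds[termId[isAlt]]
    unknown <- setdiff(out, ont@terms$term_id)
    if (length(unknown))
        stop(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")))
    out
}

#' Ancestors of a term (reflexive-transitive closure)
#'
#' The closure over the retained relations, including the term itself (the
#' true-path rule: a gene annotated to a term is implicitly annotated to
#' every ancestor).
#'
#' @param ont an [Ontology-class].
#' @param termId a single term id (alt ids resolved first).
#' @return Character vector of term ids (the term itself included).
#' @export
termAncestors <- function(ont, termId) {
    stopifnot(length(termId) == 1L)
    id <- resolveTermId(ont, termId)
    seen <- new.env(parent = emptyenv())
    stack <- id
    out <- character(0)
    while (length(stack)) {
        t <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        if (!is.null(seen[[t]])) next
        seen[[t]] <- TRUE
        out <- c(out, t)
        stack <- c(stack, ont@parents[[t]])
    }
    out
}

# ancestor closure for a set of term ids, memoised bottom-up; returns a
# named list term -> ancestors (reflexive)
.ancestorClosure <- function(ont, termIds) {
    memo <- new.env(parent = emptyenv())
    anc <- function(t) {
        got <- memo[[t]]
        if (!is.null(got)) return(got)
        ps <- ont@parents[[t]]
        out <- t
        for (p in ps) out <- c(out, anc(p))
        out <- unique(out)
        memo[[t]] <- out
        out
    }
    stats::setNames(lapply(termIds, anc), termIds)
}

# shared preparation for set builders: resolve alt ids, drop obsolete-term
# annotations (warning with count), optional namespace restriction
.prepareAnnotations <- function(ont, annotations, namespace = NULL) {
    stopifnot(is.data.frame(annotations),
        all(c("gene_id", "term_id") %in% names(annotations)))
    ann <- annotations[, c("gene_id", "term_id")]
    ann$term_id <- resolveTermId(ont, ann$term_id)
    obs <- ont@terms$term_id[ont@terms$is_obsolete]
    isObs <- ann$term_id %in% obs
    if (any(isObs)) {
        warning(sprintf("%d annotation(s) to obsolete term(s) dropped", sum(isObs)))
        ann <- ann[!isObs, , drop = FALSE]
    }
    if (!is.null(namespace)) {
        keepTerms <- ont@terms$term_id[!is.na(ont@terms$namespace) &
            ont@terms$namespace == namespace]
        ann <- ann[ann$term_id %in% keepTerms, , drop = FALSE]
    }
    unique(ann)
}

# assemble a GeneSetCollection from (gene_id, term_id) pairs
.pairsToCollection <- function(ont, pairs, categoryId, organism, idSpace, source) {
    if (nrow(pairs) == 0L)
        return(GeneSetCollection(list(), categoryId = categoryId,
            organism = organism, idSpace = idSpace, source = source))
    byTerm <- split(pairs$gene_id, pairs$term_id)
    nameOf <- stats::setNames(ont@terms$name, ont@terms$term_id)
    sets <- lapply(names(byTerm), function(t)
        GeneSet(t, byTerm[[t]], name = unname(nameOf[t]), categoryId = categoryId))
    GeneSetCollection(sets, categoryId = categoryId, organism = organism,
        idSpace = idSpace, source = source)
}

#' Build direct (unpropagated) term gene sets
#'
#' One set per term with at least one directly annotated gene; no ancestor
#' propagation. Useful to inspect annotation depth; for enrichment the
#' propagated assembly is recommended.
#'
#' @param ont an [Ontology-class].
#' @param annotations data.frame with columns `gene_id`, `term_id` (e.g. from
#'   [readGaf()]).
#' @param categoryId,organism,idSpace,source collection metadata.
#' @param namespace optional ontology namespace (e.g.
#'   `"biological_process"`); when given, one namespace per collection.
#' @return A [GeneSetCollection-class].
#' @export
buildDirectSets <- function(ont, annotations, categoryId = "direct",
                            organism = "dm", idSpace = "mod_primary",
                            source = "ontology-direct", namespace = NULL) {
    ann <- .prepareAnnotations(ont, annotations, namespace)
    .pairsToCollection(ont, ann, categoryId, organism, idSpace, source)
}

#' Build ancestor-propagated ("flattened") term gene sets
#'
#' Each gene annotated to a term contributes to that term and to every
#' ancestor over the retained relations; equivalently, a term's set is the
#' union of directly annotated genes over the term and all its descendants.
#'
#' @inheritParams buildDirectSets
#' @return A [GeneSetCollection-class].
#' @export
buildPropagatedSets <- function(ont, annotations, categoryId = "propagated",
                                organism = "dm", idSpace = "mod_primary",
                                source = "ontology-propagated",
                                namespace = NULL) {
    ann <- .prepareAnnotations(ont, annotations, namespace)
    if (nrow(ann) == 0L)
        return(.pairsToCollection(ont, ann, categoryId, organism, idSpace, source))
    clo <- .ancestorClosure(ont, unique(ann$term_id))
    reps <- lengths(clo[ann$term_id])
    pairs <- unique(data.frame(
        gene_id = rep(ann$gene_id, reps),
        term_id = unlist(clo[ann$term_id], use.names = FALSE),
        stringsAsFactors = FALSE))
    if (!is.null(namespace)) {
        keepTerms <- ont@terms$term_id[!is.na(ont@terms$namespace) &
            ont@terms$namespace == namespace]
        pairs <- pairs[pairs$term_id %in% keepTerms, , drop = FALSE]
    }
    .pairsToCollection(ont, pairs, categoryId, organism, idSpace, source)
}

#' Roll annotations up onto a slim (reduced ontology subset)
#'
#' A gene belongs to slim set `s` iff `s` is an ancestor (reflexive) of some
#' term the gene is directly annotated to. Genes whose annotations reach no
#' slim term are omitted.
#'
#' @inheritParams buildDirectSets
#' @param slimTerms character vector of slim term ids (must all exist in the
#'   ontology).
#' @return A [GeneSetCollection-class] with one set per slim term hit.
#' @export
mapToSlim <- function(ont, annotations, slimTerms, categoryId = "slim",
                      organism = "dm", idSpace = "mod_primary",
                      source = "ontology-slim") {
    if (length(slimTerms) == 0L)
        stop("slimTerms must be non-empty")
    slimTerms <- unique(resolveTermId(ont, slimTerms))
    ann <- .prepareAnnotations(ont, annotations)
    if (nrow(ann) == 0L)
        return(.pairsToCollection(ont, ann, categoryId, organism, idSpace, source))
    clo <- .ancestorClosure(ont, unique(ann$term_id))
    hits <- lapply(seq_len(nrow(ann)), function(i)
        intersect(clo[[ann$term_id[i]]], slimTerms))
    reps <- lengths(hits)
    pairs <- unique(data.frame(
        gene_id = rep(ann$gene_id, reps),
        term_id = unlist(hits, use.names = FALSE),
        stringsAsFactors = FALSE))
    .pairsToCollection(ont, pairs, categoryId, organism, idSpace, source)
}

#' Read a slim term list (one CURIE per line)
#'
#' @param path text file with one term id per line; blank lines and lines
#'   starting with `#` or `!` are skipped.
#' @return Character vector of term ids.
#' @export
readSlimTerms <- function(path) {
    if (!file.exists(path))
        stop(sprintf("slim term file not found: %s", path))
    x <- trimws(readLines(path))
    x <- x[nzchar(x) & !grepl("^[#!]", x)]
    if (length(x) == 0L)
        stop("no slim terms in file")
    unique(x)
}
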