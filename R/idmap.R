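#' Load an identifier-synchronisation table
#'
#' Reads a TSV with header and columns `alias`, `canonical`, `id_type`
#' (type of the canonical id: `entrez|symbol|mod_primary`) and `status`
#' (status of the alias: `current|secondary`). An optional `organism` column
#' is filtered to the requested organism. Reflexive rows (`canonical` ->
#' itself, status `current`) are added automatically for every canonical id,
#' so already-canonical lists map to themselves.
#'
#' An alias mapping to more than one canonical id within one id type is kept
#' as ambiguous and is never silently resolved by [mapIds()].
#'
#' @param path TSV file.
#' @param organism species code of the table.
#' @return An [IDMapTable-class].
#' @export
readIdMap <- function(path, organism) {
    if (!file.exists(path))
        stop(sprintf("id map file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("alias", "canonical", "id_type", "status")
    if (!all(need %in% header))
        stop(sprintf("id map header must contain columns: %s",
            paste(need, collapse = ", ")))
    rows <- vector("list", length(lines) - 1L)
    for (i in seq_along(rows)) {
        f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
        if (length(f) != length(header))
            stop(sprintf("id map parse error at line %d: expected %d columns, got %d",
                i + 1L, length(header), length(f)))
        rows[[i]] <- f
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- header
    if ("organism" %in% header)
        df <- df[df$organism == organism, , drop = FALSE]
    df <- df[, need]
    bad <- which(!df$id_type %in% .ID_SPACES)
    if (length(bad))
        stop(sprintf("id map parse error at line %d: bad id_type '%s'",
            bad[1] + 1L, df$id_type[bad[1]]))
    bad <- which(!df$status %in% c("current", "secondary"))
    if (length(bad))
        stop(sprintf("id map parse error at line %d: bad status '%s'",
            bad[1] + 1L, df$status[bad[1]]))
    # reflexive closure: every canonical resolves to itself, status current
    canon <- unique(df[, c("canonical", "id_type")])
    selfRows <- data.frame(alias = canon$canonical, canonical = canon$canonical,
        id_type = canon$id_type, status = "current", stringsAsFactors = FALSE)
    df <- unique(rbind(df, selfRows))
    rownames(df) <- NULL
    new("IDMapTable", organism = as.character(organism), entries = df)
}

#' Aliases with more than one candidate canonical id
#'
#' @param table an [IDMapTable-class].
#' @param idType target identifier space.
#' @return Named list: alias -> candidate canonical ids.
#' @export
ambiguousAliases <- function(table, idType) {
    e <- table@entries[table@entries$id_type == idType, , drop = FALSE]
    cand <- lapply(split(e$canonical, e$alias), unique)
    cand[lengths(cand) > 1L]
}

#' Synchronise a gene list to canonical identifiers
#'
#' Reproduces the standalone "gene id mapping" step: each input identifier is
#' looked up in the table against the target identifier space. Current
#' aliases with a unique canonical are `mapped`; secondary (withdrawn)
#' aliases are `updated` to their current canonical; aliases with several
#' candidates are `ambiguous` and excluded from the output (silent
#' misassignment is worse than exclusion — the report surfaces them);
#' unknown identifiers are `unmapped`. The four categories partition the
#' input.
#'
#' Output genes keep input order; two inputs resolving to the same canonical
#' collapse to one output gene, recorded in the report.
#'
#' @param table an [IDMapTable-class].
#' @param genes a [GeneList-class] (or character vector).
#' @param targetSpace target identifier space (`entrez|symbol|mod_primary`).
#' @return A list with elements `genes` (a [GeneList-class] of canonical ids)
#'   and `report` (a [MappingReport-class]).
#' @export
mapIds <- function(table, genes, targetSpace = c("mod_primary", "symbol", "entrez")) {
    targetSpace <- match.arg(targetSpace)
    if (is(genes, "GeneList")) {
        if (!is.na(genes@organism) && genes@organism != table@organism)
            stop(sprintf("organism mismatch: list is '%s', table is '%s'",
                genes@organism, table@organism))
        listId <- genes@listId
        input <- genes@genes
    } else {
        listId <- "gene_list"
        input <- as.character(genes)
    }
    e <- table@entries[table@entries$id_type == targetSpace, , drop = FALSE]

    mapped <- list(); updated <- list(); ambiguous <- list(); unmapped <- character(0)
    outGenes <- character(0)
    collapsed <- list()
    for (g in input) {
        hit <- e[e$alias == g, , drop = FALSE]
        cands <- unique(hit$canonical)
        if (length(cands) == 0L) {
            unmapped <- c(unmapped, g)
        } else if (length(cands) > 1L) {
            ambiguous[[g]] <- cands
        } else {
            entry <- data.frame(input = g, canonical = cands,
                stringsAsFactors = FALSE)
            if (any(hit$status == "current"))
                mapped[[length(mapped) + 1L]] <- entry
            else
                updated[[length(updated) + 1L]] <- entry
            if (cands %in% outGenes)
                collapsed[[length(collapsed) + 1L]] <- entry
            else
                outGenes <- c(outGenes, cands)
        }
    }
    emptyDf <- data.frame(input = character(0), canonical = character(0),
        stringsAsFactors = FALSE)
    report <- new("MappingReport",
        mapped = if (length(mapped)) do.call(rbind, mapped) else emptyDf,
        updated = if (length(updated)) do.call(rbind, updated) else emptyDf,
        ambiguous = ambiguous,
        unmapped = unmapped,
        collapsed = if (length(collapsed)) do.call(rbind, collapsed) else emptyDf)
    if (length(outGenes) == 0L)
        stop("no genes mapped")
    list(genes = GeneList(outGenes, organism = table@organism, listId = listId),
         report = report)
}

#' Write a mapping report as TSV
#'
#' One row per input identifier with its category and resolution.
#'
#' @param report a [MappingReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMappingReport <- function(report, path) {
    rows <- rbind(
        if (nrow(report@mapped)) data.frame(input = report@mapped$input,
            category = "mapped", resolution = report@mapped$canonical),
        if (nrow(report@updated)) data.frame(input = report@updated$input,
            category = "updated", resolution = report@updated$canonical),
        if (length(report@ambiguous)) data.frame(
            input = names(report@ambiguous), category = "ambiguous",
            resolution = vapply(report@ambiguous, paste, character(1),
                collapse = ";")),
        if (length(report@unmapped)) data.frame(input = report@unmapped,
            category = "unmapped", resolution = ""))
    if (is.null(rows))
        rows <- data.frame(input = character(0), category = character(0),
            resolution = character(0))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
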