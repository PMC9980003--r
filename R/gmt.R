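#' Read a gene-set collection from a GMT file
#'
#' GMT (Gene Matrix Transposed) holds one gene set per line:
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`. Blank member
#' tokens are dropped and duplicate members within a line are collapsed.
#'
#' @param path GMT file.
#' @param categoryId collection category identifier.
#' @param organism species code (`dm, hs, mm, ce, dr, rn`).
#' @param idSpace member identifier space (`entrez|symbol|mod_primary`).
#' @param source provenance label.
#' @return A [GeneSetCollection-class].
#' @seealso [writeGmt()], [writeSetTable()]
#' @export
readGmt <- function(path, categoryId, organism, idSpace, source = categoryId) {
    if (!file.exists(path))
        stop(sprintf("GMT file not found: %s", path))
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    sets <- vector("list", sum(keep))
    seen <- character(0)
    j <- 0L
    for (i in which(keep)) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3L)
            stop(sprintf(
                "GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                i, length(fields)))
        id <- trimws(fields[1])
        if (id %in% seen)
            stop(sprintf("GMT parse error at line %d: duplicate set_id '%s'", i, id))
        mem <- trimws(fields[-(1:2)])
        mem <- unique(mem[nzchar(mem)])
        if (length(mem) == 0L)
            stop(sprintf("GMT parse error at line %d: set '%s' has no members", i, id))
        seen <- c(seen, id)
        j <- j + 1L
        sets[[j]] <- GeneSet(id, mem, name = trimws(fields[2]), categoryId = categoryId)
    }
    GeneSetCollection(sets[seq_len(j)], categoryId = categoryId,
        organism = organism, idSpace = idSpace, source = source)
}

#' Write a gene-set collection to a GMT file
#'
#' Members are emitted sorted so that output is deterministic and
#' `readGmt(writeGmt(x))` reproduces the collection (round-trip identity up
#' to member ordering).
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    lines <- vapply(collection@sets, function(s)
        paste(c(s@setId, s@name, sort(s@members)), collapse = "\t"),
        character(1), USE.NAMES = FALSE)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Export a collection as a 2-column TSV (set_id, gene_id)
#'
#' Long-format export suitable for loading into a relational database.
#'
#' @inheritParams writeGmt
#' @return `path`, invisibly.
#' @export
writeSetTable <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    mem <- members(collection)
    df <- data.frame(
        set_id = rep(names(mem), lengths(mem)),
        gene_id = unlist(lapply(mem, sort), use.names = FALSE),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Normalise raw gene-list text into a GeneList
#'
#' Trims whitespace, drops blank lines and removes duplicates keeping the
#' first occurrence. Identifiers are case-sensitive: `G1` and `g1` are kept
#' as two genes (symbol case is significant in fly nomenclature).
#'
#' @param raw character vector of input lines (one identifier per line).
#' @param organism species code.
#' @param listId label for the resulting list.
#' @return A [GeneList-class].
#' @export
normaliseGeneList <- function(raw, organism = NA_character_, listId = "gene_list") {
    genes <- trimws(as.character(raw))
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L)
        stop("no genes after normalisation")
    GeneList(genes, organism = organism, listId = listId)
}

#' Read a one-identifier-per-line gene list file
#'
#' @param path text file, one identifier per line.
#' @inheritParams normaliseGeneList
#' @return A [GeneList-class].
#' @export
readGeneList <- function(path, organism = NA_character_,
                         listId = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop(sprintf("gene list file not found: %s", path))
    normaliseGeneList(readLines(path), organism = organism, listId = listId)
}
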