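# In-code builders for tiny ontology/annotation fixtures.

# write an OBO file from a term table; edges: data.frame(child, parent,
# relation); obsolete/alt: named by term id
writeOboFixture <- function(terms, edges = NULL, obsolete = character(0),
                            altIds = list(), path = tempfile(fileext = ".obo"),
                            namespace = "biological_process") {
    lines <- c("format-version: 1.2", "")
    for (t in terms) {
        lines <- c(lines, "[Term]", sprintf("id: %s", t),
            sprintf("name: term %s", t), sprintf("namespace: %s", namespace))
        for (a in altIds[[t]])
            lines <- c(lines, sprintf("alt_id: %s", a))
        if (t %in% obsolete)
            lines <- c(lines, "is_obsolete: true")
        if (!is.null(edges)) {
            e <- edges[edges$child == t, , drop = FALSE]
            for (j in seq_len(nrow(e)))
                lines <- c(lines, if (e$relation[j] == "is_a")
                    sprintf("is_a: %s ! parent", e$parent[j])
                else sprintf("relationship: %s %s", e$relation[j], e$parent[j]))
        }
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    path
}

# chain C -> B -> A (is_a)
chainOntology <- function() {
    readObo(writeOboFixture(c("A", "B", "C"),
        data.frame(child = c("B", "C"), parent = c("A", "B"),
            relation = "is_a")))
}

# diamond D -> {B, C} -> A
diamondOntology <- function() {
    readObo(writeOboFixture(c("A", "B", "C", "D"),
        data.frame(child = c("B", "C", "D", "D"),
            parent = c("A", "A", "B", "C"), relation = "is_a")))
}

annotationDf <- function(genes, terms, codes = "IDA", qualifier = "") {
    data.frame(gene_id = genes, term_id = terms, evidence_code = codes,
        qualifier = qualifier, source_ref = "TEST:1", stringsAsFactors = FALSE)
}

# GAF 2.2 row with the given payload columns
gafRow <- function(gene, term, code, qualifier = "involved_in") {
    paste(c("FB", gene, gene, qualifier, term, "REF:1", code, "", "P",
        "name", "", "gene", "taxon:7227", "20260101", "TEST", "", ""),
        collapse = "\t")
}

writeGafFixture <- function(rows, path = tempfile(fileext = ".gaf")) {
    writeLines(c("!gaf-version: 2.2", rows), path)
    path
}

randomCollection <- function(nSets, maxMembers, seed,
                             universe = sprintf("g%03d", 1:200)) {
    set.seed(seed)
    sets <- lapply(seq_len(nSets), function(i)
        GeneSet(sprintf("S%03d", i),
            sample(universe, sample.int(maxMembers, 1))))
    GeneSetCollection(sets, categoryId = "rand", organism = "dm",
        idSpace = "symbol")
}

# random DAG ontology + annotations through the package's own generators
randomDagFixture <- function(seed, nTerms = 50, nAnnotations = 200) {
    d <- tempfile()
    spec <- fixtureSpec(seed = seed, nTerms = nTerms,
        nAnnotations = nAnnotations)
    f <- makeOntologyFixture(spec, d)
    ont <- readObo(f$obo)
    g <- makeGafFixture(spec, ont, d)
    list(ont = ont, ann = readGaf(g$gaf))
}
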