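#' @import methods
NULL

.ORGANISM_CODES <- c("dm", "hs", "mm", "ce", "dr", "rn")
.ID_SPACES <- c("entrez", "symbol", "mod_primary")

#' GeneSet: a named set of genes
#'
#' A gene set is a finite, non-empty set of canonical gene identifiers grouped
#' under an opaque identifier (a GO term, a phenotype CV term, a pathway id, a
#' tissue label, ...) and owned by a classification category (collection).
#'
#' @slot setId single identifier, unique within its collection.
#' @slot name human-readable label.
#' @slot members character vector of unique gene identifiers (set semantics;
#'   empty sets are rejected at construction since they can never be enriched
#'   and break fold-enrichment denominators).
#' @slot categoryId identifier of the owning collection (may be `NA` for a
#'   free-standing set).
#' @exportClass GeneSet
setClass("GeneSet",
    slots = c(
        setId = "character",
        name = "character",
        members = "character",
        categoryId = "character"
    )
)

setValidity("GeneSet", function(object) {
    msg <- character(0)
    if (length(object@setId) != 1L || is.na(object@setId) || !nzchar(object@setId))
        msg <- c(msg, "setId must be a single non-empty string")
    if (length(object@members) == 0L)
        msg <- c(msg, "members must be non-empty")
    if (anyNA(object@members) || any(!nzchar(object@members)))
        msg <- c(msg, "members must not contain NA or empty identifiers")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must not contain duplicates")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param setId set identifier (e.g. `"GO:0016071"`).
#' @param members character vector of gene identifiers; duplicates are
#'   collapsed, blanks and `NA` are rejected.
#' @param name human-readable label; defaults to `setId`.
#' @param categoryId owning collection id, or `NA`.
#' @return A [GeneSet-class] object.
#' @examples
#' GeneSet("S1", c("g1", "g2", "g2"))
#' @export
GeneSet <- function(setId, members, name = setId, categoryId = NA_character_) {
    new("GeneSet",
        setId = as.character(setId),
        name = as.character(name),
        members = unique(as.character(members)),
        categoryId = as.character(categoryId))
}

#' GeneSetCollection: all gene sets of one classification category
#'
#' A collection groups gene sets that share an organism, a provenance label
#' and an identifier space. Identifiers are case-sensitive throughout (fly
#' symbol case is significant).
#'
#' @slot categoryId opaque category identifier.
#' @slot organism one of the six species codes `dm, hs, mm, ce, dr, rn`.
#' @slot source provenance label (e.g. `"GO-BP"`, `"FlyBase-phenotype"`).
#' @slot idSpace one of `entrez`, `symbol`, `mod_primary`.
#' @slot sets list of [GeneSet-class] objects with unique `setId`s.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    slots = c(
        categoryId = "character",
        organism = "character",
        source = "character",
        idSpace = "character",
        sets = "list"
    )
)

#' Validate a gene-set collection, reporting every violation
#'
#' Machine-checks the collection invariants and returns all violations, not
#' just the first: unique set ids, valid organism code and id space, and the
#' per-set invariants (non-empty, duplicate-free members).
#'
#' @param collection a [GeneSetCollection-class].
#' @return Character vector of violation messages; empty when valid.
#' @export
validateCollection <- function(collection) {
    msg <- character(0)
    if (!collection@organism %in% .ORGANISM_CODES)
        msg <- c(msg, sprintf("organism '%s' is not one of: %s",
            collection@organism, paste(.ORGANISM_CODES, collapse = ", ")))
    if (!collection@idSpace %in% .ID_SPACES)
        msg <- c(msg, sprintf("idSpace '%s' is not one of: %s",
            collection@idSpace, paste(.ID_SPACES, collapse = ", ")))
    ids <- vapply(collection@sets, function(s) s@setId, character(1))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        msg <- c(msg, sprintf("duplicate set_id: %s", paste(dup, collapse = ", ")))
    for (s in collection@sets) {
        v <- validObject(s, test = TRUE)
        if (!isTRUE(v))
            msg <- c(msg, sprintf("set '%s': %s", s@setId, paste(v, collapse = "; ")))
    }
    msg
}

setValidity("GeneSetCollection", function(object) {
    bad <- vapply(object@sets, function(s) !is(s, "GeneSet"), logical(1))
    if (any(bad)) return("all elements of sets must be GeneSet objects")
    msg <- validateCollection(object)
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets list of [GeneSet-class] objects.
#' @param categoryId category identifier.
#' @param organism species code (`dm, hs, mm, ce, dr, rn`).
#' @param idSpace identifier space of the members
#'   (`entrez`, `symbol`, `mod_primary`).
#' @param source provenance label.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, categoryId, organism, idSpace,
                              source = categoryId) {
    sets <- lapply(sets, function(s) {
        s@categoryId <- as.character(categoryId)
        s
    })
    names(sets) <- vapply(sets, function(s) s@setId, character(1))
    new("GeneSetCollection",
        categoryId = as.character(categoryId),
        organism = as.character(organism),
        source = as.character(source),
        idSpace = as.character(idSpace),
        sets = sets)
}

#' GeneList: an ordered, duplicate-free user gene list
#'
#' @slot listId label used in reports and comparison matrices.
#' @slot genes character vector, unique, input order preserved.
#' @slot organism species code.
#' @exportClass GeneList
setClass("GeneList",
    slots = c(
        listId = "character",
        genes = "character",
        organism = "character"
    )
)

setValidity("GeneList", function(object) {
    msg <- character(0)
    if (length(object@genes) == 0L)
        msg <- c(msg, "genes must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "genes must not contain duplicates")
    if (!object@organism %in% c(.ORGANISM_CODES, NA_character_))
        msg <- c(msg, sprintf("unknown organism code '%s'", object@organism))
    if (length(msg)) msg else TRUE
})

#' Construct a GeneList
#'
#' @param genes character vector of gene identifiers (unique; order kept).
#' @param organism species code.
#' @param listId label for the list.
#' @return A [GeneList-class].
#' @export
GeneList <- function(genes, organism = NA_character_, listId = "gene_list") {
    new("GeneList",
        listId = as.character(listId),
        genes = as.character(genes),
        organism = as.character(organism))
}

#' Ontology: a term DAG restricted to the traversed relations
#'
#' Holds the `[Term]` stanzas of an OBO 1.2 file: primary terms, the parent
#' edges over the requested relations (default `is_a` and `part_of`), alt-id
#' resolution and obsolete flags. The retained graph is validated to be
#' acyclic with every parent reference resolving; obsolete terms carry no
#' edges used in traversal.
#'
#' @slot terms data.frame with columns `term_id`, `name`, `namespace`,
#'   `is_obsolete`.
#' @slot parents named list: `term_id` -> character vector of parent ids over
#'   the retained relations.
#' @slot altIds named character vector: alt id -> primary id.
#' @slot relations relations retained at load.
#' @exportClass Ontology
setClass("Ontology",
    slots = c(
        terms = "data.frame",
        parents = "list",
        altIds = "character",
        relations = "character"
    )
)

#' IDMapTable: alias -> canonical identifier synchronisation table
#'
#' @slot organism species code.
#' @slot entries data.frame with columns `alias`, `canonical`, `id_type`
#'   (`entrez|symbol|mod_primary`: the type of the canonical id) and `status`
#'   (`current|secondary`: the status of the alias). Canonical ids map to
#'   themselves with status `current` (reflexive closure added at load).
#' @exportClass IDMapTable
setClass("IDMapTable",
    slots = c(
        organism = "character",
        entries = "data.frame"
    )
)

#' MappingReport: full accounting of one id-mapping run
#'
#' The four categories partition the input list: `mapped` (current alias with
#' a unique canonical), `updated` (secondary/withdrawn alias resolved to its
#' current canonical), `ambiguous` (alias with more than one candidate
#' canonical in the target space; never silently resolved) and `unmapped`.
#'
#' @slot mapped data.frame (`input`, `canonical`).
#' @slot updated data.frame (`input`, `canonical`).
#' @slot ambiguous named list: input -> candidate canonical ids.
#' @slot unmapped character vector.
#' @slot collapsed data.frame (`input`, `canonical`) of mapped/updated inputs
#'   whose canonical id was already produced by an earlier input (enrichment
#'   must not double-count a gene).
#' @exportClass MappingReport
setClass("MappingReport",
    slots = c(
        mapped = "data.frame",
        updated = "data.frame",
        ambiguous = "list",
        unmapped = "character",
        collapsed = "data.frame"
    )
)

#' EnrichmentRun: per-set over-representation results for one gene list
#'
#' @slot results data.frame ordered by raw p ascending (ties: fold
#'   descending, then set id) with columns `set_id`, `name`, `N`, `K`, `n`,
#'   `k`, `p_raw`, `p_bonferroni`, `p_bh`, `p_by`, `fold` and a list column
#'   `overlap_genes`.
#' @slot backgroundSize N, the background universe size.
#' @slot inputSize n, the analysed (effective) input size.
#' @slot droppedGenes input genes outside the user background.
#' @slot uncoveredGenes analysed genes in no set of the collection.
#' @slot categoryId collection analysed.
#' @slot listId input list label.
#' @exportClass EnrichmentRun
setClass("EnrichmentRun",
    slots = c(
        results = "data.frame",
        backgroundSize = "integer",
        inputSize = "integer",
        droppedGenes = "character",
        uncoveredGenes = "character",
        categoryId = "character",
        listId = "character"
    )
)

#' ComparisonMatrix: gene sets x gene lists display matrix
#'
#' Rows are the union of sets passing the cutoff in at least one run; cells
#' that were untestable (K = 0 for that run) are `NA` and distinguished from
#' "tested, not significant" cells, which carry their true value with
#' `significant = FALSE`.
#'
#' @slot setIds,setNames row identity.
#' @slot listIds column identity.
#' @slot value matrix of the chosen display value.
#' @slot p,fold,k raw statistic matrices.
#' @slot tested,significant logical matrices.
#' @slot valueType one of `p`, `fold`, `neglog10p`.
#' @slot cutoffColumn,cutoff the row-selection rule used.
#' @exportClass ComparisonMatrix
setClass("ComparisonMatrix",
    slots = c(
        setIds = "character",
        setNames = "character",
        listIds = "character",
        value = "matrix",
        p = "matrix",
        fold = "matrix",
        k = "matrix",
        tested = "matrix",
        significant = "matrix",
        valueType = "character",
        cutoffColumn = "character",
        cutoff = "numeric"
    )
)

#' BipartiteGraph: gene-set nodes linked to gene nodes
#'
#' Strictly bipartite: edges only connect a `gene_set` node to a `gene`
#' node, and no gene-set node is isolated.
#'
#' @slot nodes data.frame (`id`, `node_type` in `gene_set|gene`, `label`).
#' @slot edges data.frame (`set`, `gene`).
#' @exportClass BipartiteGraph
setClass("BipartiteGraph",
    slots = c(
        nodes = "data.frame",
        edges = "data.frame"
    )
)

setValidity("BipartiteGraph", function(object) {
    msg <- character(0)
    nd <- object@nodes
    ed <- object@edges
    if (!all(c("id", "node_type", "label") %in% names(nd)))
        msg <- c(msg, "nodes must have columns id, node_type, label")
    if (!all(c("set", "gene") %in% names(ed)))
        msg <- c(msg, "edges must have columns set, gene")
    if (length(msg)) return(msg)
    if (anyDuplicated(nd$id))
        msg <- c(msg, "duplicate node ids")
    if (!all(nd$node_type %in% c("gene_set", "gene")))
        msg <- c(msg, "node_type must be gene_set or gene")
    setIds <- nd$id[nd$node_type == "gene_set"]
    geneIds <- nd$id[nd$node_type == "gene"]
    if (nrow(ed)) {
        if (!all(ed$set %in% setIds) || !all(ed$gene %in% geneIds))
            msg <- c(msg, "edges must connect a gene_set node to a gene node")
    }
    if (length(setIds) && !all(setIds %in% ed$set))
        msg <- c(msg, "isolated gene_set node(s) present")
    if (length(msg)) msg else TRUE
})
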