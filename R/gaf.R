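.COMPUTATIONAL_CODES <- c("IEA", "IBA", "IBD", "IKR", "IRD", "ISS", "ISO",
    "ISA", "ISM", "IGC", "RCA")
.HTP_CODES <- c("HTP", "HDA", "HMP", "HGI", "HEP")

#' Read a GAF 2.x gene association file
#'
#' Parses the 17-column tab-separated Gene Association File format. Lines
#' starting with `!` are comments. Rows whose qualifier carries `NOT` are
#' dropped before any set building (a negative annotation must never create
#' set membership); the number dropped is recorded in the
#' `droppedNegated` attribute of the result.
#'
#' @param path GAF file.
#' @return data.frame with columns `gene_id` (DB object id), `term_id`
#'   (ontology CURIE), `evidence_code`, `qualifier` and `source_ref`, one row
#'   per retained annotation record, with attribute `droppedNegated`.
#' @export
readGaf <- function(path) {
    if (!file.exists(path))
        stop(sprintf("GAF file not found: %s", path))
    lines <- readLines(path)
    dataIdx <- which(!grepl("^!", lines) & nzchar(lines))
    recs <- vector("list", length(dataIdx))
    for (j in seq_along(dataIdx)) {
        i <- dataIdx[j]
        # sentinel keeps trailing empty fields (strsplit drops them)
        f <- strsplit(paste0(lines[i], "\tEND"), "\t", fixed = TRUE)[[1]]
        f <- f[-length(f)]
        if (length(f) != 17L)
            stop(sprintf("GAF parse error at line %d: expected 17 columns, got %d",
                i, length(f)))
        ev <- f[7]
        if (!grepl("^[A-Z]{2,4}$", ev))
            stop(sprintf("GAF parse error at line %d: bad evidence code '%s'", i, ev))
        recs[[j]] <- c(f[2], f[5], ev, f[4], f[6])
    }
    m <- do.call(rbind, recs)
    if (is.null(m))
        m <- matrix(character(0), ncol = 5)
    out <- data.frame(gene_id = m[, 1], term_id = m[, 2],
        evidence_code = m[, 3], qualifier = m[, 4], source_ref = m[, 5],
        stringsAsFactors = FALSE)
    negated <- vapply(strsplit(out$qualifier, "|", fixed = TRUE),
        function(q) "NOT" %in% q, logical(1))
    dropped <- sum(negated)
    out <- out[!negated, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "droppedNegated") <- dropped
    out
}

# pair-level "only supported by" filter: a (gene, term) pair survives iff at
# least one of its records carries a code outside `excluded`; surviving pairs
# keep all their records.
.filterPairsByCode <- function(records, excluded) {
    stopifnot(is.data.frame(records),
        all(c("gene_id", "term_id", "evidence_code") %in% names(records)))
    if (nrow(records) == 0L) return(records)
    key <- paste(records$gene_id, records$term_id, sep = "\r")
    ok <- !(records$evidence_code %in% excluded)
    keepKeys <- unique(key[ok])
    out <- records[key %in% keepKeys, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Restrict annotations to experimentally supported gene-term pairs
#'
#' Removes (gene, term) pairs supported only by phylogenetic, sequence or
#' structural similarity and other computational analyses (evidence codes
#' IEA, IBA, IBD, IKR, IRD, ISS, ISO, ISA, ISM, IGC, RCA). A pair with at
#' least one record outside this code list survives with all its records.
#'
#' @param records annotation data.frame (see [readGaf()]).
#' @return Filtered data.frame.
#' @export
filterExperimental <- function(records)
    .filterPairsByCode(records, .COMPUTATIONAL_CODES)

#' Remove gene-term pairs supported only by high-throughput evidence
#'
#' Removes (gene, term) pairs whose every record carries a high-throughput
#' evidence code (HTP, HDA, HMP, HGI, HEP). Excluding HTP-only support
#' avoids circularity when analysing gene lists derived from similar
#' high-throughput studies.
#'
#' @inheritParams filterExperimental
#' @return Filtered data.frame.
#' @export
filterNoHtp <- function(records)
    .filterPairsByCode(records, .HTP_CODES)

#' Read a genotype-phenotype TSV
#'
#' Expects a header line and four tab-separated columns mirroring the
#' information content of a model-organism genotype/phenotype download:
#' `genotype_alleles` (`;`-joined allele tokens), `gene_ids` (`;`-joined
#' genes the alleles belong to), `allele_class`
#' (`classical|insertional|other`) and `phenotype_id` (controlled-vocabulary
#' CURIE).
#'
#' @param path TSV file.
#' @return data.frame with those four character columns.
#' @export
readGenotypePhenotype <- function(path) {
    if (!file.exists(path))
        stop(sprintf("genotype-phenotype file not found: %s", path))
    df <- utils::read.table(path, sep = "\t", header = TRUE,
        colClasses = "character", quote = "", comment.char = "")
    need <- c("genotype_alleles", "gene_ids", "allele_class", "phenotype_id")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop(sprintf("genotype-phenotype file lacks column(s): %s",
            paste(missing, collapse = ", ")))
    df[, need]
}

#' Build phenotype gene sets from single-allele genotypes
#'
#' Only genotypes where the phenotype can be attributed with certainty to the
#' perturbation of a single gene contribute: exactly one allele, of class
#' `classical` or `insertional`, belonging to exactly one gene. All other
#' records are counted in the `excluded` attribute of the result.
#'
#' When a phenotype-CV [Ontology-class] is supplied the gene-phenotype pairs
#' are propagated up the CV hierarchy (via [buildPropagatedSets()]);
#' otherwise direct sets are built.
#'
#' @param records data.frame from [readGenotypePhenotype()].
#' @param ont optional phenotype CV [Ontology-class].
#' @param categoryId,organism,idSpace,source collection metadata.
#' @return A [GeneSetCollection-class]; attribute `excluded` counts the
#'   non-qualifying records.
#' @export
buildPhenotypeSets <- function(records, ont = NULL, categoryId = "phenotype",
                               organism = "dm", idSpace = "mod_primary",
                               source = "genotype-phenotype") {
    alleles <- strsplit(records$genotype_alleles, ";", fixed = TRUE)
    genes <- strsplit(records$gene_ids, ";", fixed = TRUE)
    qual <- lengths(alleles) == 1L & lengths(genes) == 1L &
        records$allele_class %in% c("classical", "insertional")
    nExcluded <- sum(!qual)
    pairs <- unique(data.frame(
        gene_id = unlist(genes[qual], use.names = FALSE),
        term_id = records$phenotype_id[qual],
        stringsAsFactors = FALSE))
    if (!is.null(ont)) {
        coll <- buildPropagatedSets(ont, pairs, categoryId = categoryId,
            organism = organism, idSpace = idSpace, source = source)
    } else {
        byTerm <- if (nrow(pairs)) split(pairs$gene_id, pairs$term_id) else list()
        sets <- lapply(names(byTerm), function(t)
            GeneSet(t, byTerm[[t]], categoryId = categoryId))
        coll <- GeneSetCollection(sets, categoryId = categoryId,
            organism = organism, idSpace = idSpace, source = source)
    }
    attr(coll, "excluded") <- nExcluded
    coll
}
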