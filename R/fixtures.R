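#' Parameters for the synthetic-data generators
#'
#' Bundles every knob of the fixture generators. Identical specs produce
#' byte-identical output files; each generator writes a JSON manifest beside
#' its files recording the planted ground truth, so recovery tests never
#' re-derive truth from generator internals.
#'
#' @param seed RNG seed (default 17).
#' @param nGenes size of the gene universe.
#' @param nTerms ontology size.
#' @param dagDensity probability of each extra (beyond the spanning) parent
#'   edge in the random DAG.
#' @param nAnnotations GAF rows to draw.
#' @param evidenceMix named probabilities over evidence classes
#'   `experimental`, `computational`, `htp`.
#' @param nSets,setSizeRange synthetic collection shape.
#' @param planted optional data.frame (`set_id`, `list_size`, `noise_genes`)
#'   describing planted screen lists; `NULL` lets [makeScreenFixture()] pick.
#' @param nLists number of screen lists when `planted` is `NULL`.
#' @param nTissues,nSamplesPerTissue expression-matrix shape (emulating a
#'   many-tissue dissection RPKM matrix).
#' @param nPlantedTissue tissue-preferential genes to plant.
#' @return A list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(seed = 17L, nGenes = 200L, nTerms = 30L,
                        dagDensity = 0.3, nAnnotations = 200L,
                        evidenceMix = c(experimental = 0.5,
                            computational = 0.3, htp = 0.2),
                        nSets = 50L, setSizeRange = c(10L, 40L),
                        planted = NULL, nLists = 5L,
                        nTissues = 5L, nSamplesPerTissue = 3L,
                        nPlantedTissue = 20L) {
    spec <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
        nTerms = as.integer(nTerms), dagDensity = dagDensity,
        nAnnotations = as.integer(nAnnotations), evidenceMix = evidenceMix,
        nSets = as.integer(nSets), setSizeRange = as.integer(setSizeRange),
        planted = planted, nLists = as.integer(nLists),
        nTissues = as.integer(nTissues),
        nSamplesPerTissue = as.integer(nSamplesPerTissue),
        nPlantedTissue = as.integer(nPlantedTissue))
    class(spec) <- "FixtureSpec"
    spec
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.geneIds <- function(n) sprintf("FBgn%07d", seq_len(n))
.termIds <- function(n) sprintf("FX:%07d", seq_len(n))

.writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
        null = "null", pretty = TRUE)
    invisible(path)
}

#' Generate a random acyclic OBO ontology
#'
#' Terms are indexed and every term after the first draws at least one parent
#' among earlier terms (plus extras with probability `dagDensity`), so the
#' graph is acyclic by construction and term 1 is the single root. About one
#' edge in five is `part_of`, the rest `is_a`. Output is valid OBO 1.2 and
#' loads with [readObo()] without warnings.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, list with `obo` and `manifest` paths.
#' @export
makeOntologyFixture <- function(spec, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ids <- .termIds(spec$nTerms)
    edges <- .withSeed(spec$seed, {
        out <- list()
        for (i in seq_len(spec$nTerms)[-1]) {
            np <- 1L + stats::rbinom(1L, min(i - 1L, 3L), spec$dagDensity)
            ps <- sample.int(i - 1L, min(np, i - 1L))
            rel <- ifelse(stats::runif(length(ps)) < 0.2, "part_of", "is_a")
            out[[i]] <- data.frame(child = ids[i], parent = ids[ps],
                relation = rel, stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
    lines <- c("format-version: 1.2", "ontology: fx", "")
    for (i in seq_len(spec$nTerms)) {
        e <- edges[edges$child == ids[i], , drop = FALSE]
        lines <- c(lines, "[Term]",
            sprintf("id: %s", ids[i]),
            sprintf("name: synthetic term %d", i),
            "namespace: biological_process",
            if (nrow(e)) unlist(lapply(seq_len(nrow(e)), function(j)
                if (e$relation[j] == "is_a")
                    sprintf("is_a: %s", e$parent[j])
                else
                    sprintf("relationship: part_of %s", e$parent[j]))),
            "")
    }
    oboPath <- file.path(dir, "ontology.obo")
    writeLines(lines, oboPath)
    manifestPath <- file.path(dir, "ontology.manifest.json")
    .writeManifest(list(seed = spec$seed, n_terms = spec$nTerms,
        root = ids[1], edges = edges), manifestPath)
    invisible(list(obo = oboPath, manifest = manifestPath))
}

.EVIDENCE_CLASSES <- list(
    experimental = c("IDA", "IMP", "IGI", "IPI", "EXP", "IEP"),
    computational = c("IEA", "IBA", "IBD", "IKR", "IRD", "ISS", "ISO",
        "ISA", "ISM", "IGC", "RCA"),
    htp = c("HTP", "HDA", "HMP", "HGI", "HEP"))

#' Generate a GAF annotation fixture over an ontology
#'
#' Draws `nAnnotations` (gene, term) annotations with terms biased towards
#' leaves (annotation practice annotates the most specific term) and evidence
#' codes sampled from the declared class mix. The manifest records the exact
#' per-code and per-class counts for verification.
#'
#' @param spec a [fixtureSpec()].
#' @param ont the [Ontology-class] the annotations target.
#' @param dir output directory.
#' @return Invisibly, list with `gaf` and `manifest` paths.
#' @export
makeGafFixture <- function(spec, ont, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genes <- .geneIds(spec$nGenes)
    terms <- ont@terms$term_id[!ont@terms$is_obsolete]
    hasChild <- unique(unlist(ont@parents, use.names = FALSE))
    leafW <- ifelse(terms %in% hasChild, 1, 3)   # leaf-biased
    mix <- spec$evidenceMix / sum(spec$evidenceMix)
    rows <- .withSeed(spec$seed, {
        g <- sample(genes, spec$nAnnotations, replace = TRUE)
        t <- sample(terms, spec$nAnnotations, replace = TRUE, prob = leafW)
        cls <- sample(names(mix), spec$nAnnotations, replace = TRUE, prob = mix)
        ev <- vapply(cls, function(cl)
            sample(.EVIDENCE_CLASSES[[cl]], 1L), character(1))
        data.frame(gene = g, term = t, class = unname(cls), code = unname(ev),
            stringsAsFactors = FALSE)
    })
    gafLines <- c("!gaf-version: 2.2",
        sprintf("FB\t%s\t%s\t\t%s\tSYNTH:0000001\t%s\t\tP\tsynthetic gene\t\tgene\ttaxon:7227\t20260101\tSYNTH\t\t",
            rows$gene, rows$gene, rows$term, rows$code))
    gafPath <- file.path(dir, "annotations.gaf")
    writeLines(gafLines, gafPath)
    manifestPath <- file.path(dir, "annotations.manifest.json")
    .writeManifest(list(seed = spec$seed, n_annotations = spec$nAnnotations,
        class_counts = as.list(table(rows$class)),
        code_counts = as.list(table(rows$code))), manifestPath)
    invisible(list(gaf = gafPath, manifest = manifestPath))
}

#' Generate an RPKM matrix fixture with planted tissue-preferential genes
#'
#' `nPlantedTissue` genes are constructed so that one tissue group's mean is
#' at least 3-fold above every other group and at least 10 RPKM; the
#' remaining genes each violate one condition (floor failure at preserved
#' fold dominance, fold failure above the floor, or flat expression).
#' Within-group sample noise is zero-sum, so empirical group means equal the
#' planned means exactly and the manifest is exact ground truth.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory.
#' @return Invisibly, list with `matrix`, `groups` and `manifest` paths.
#' @export
makeExpressionFixture <- function(spec, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stopifnot(spec$nTissues >= 2L)
    tissues <- sprintf("tissue%02d", seq_len(spec$nTissues))
    genes <- .geneIds(spec$nGenes)
    nP <- min(spec$nPlantedTissue, spec$nGenes)
    res <- .withSeed(spec$seed, {
        truth <- rep(NA_character_, spec$nGenes)
        means <- matrix(0, spec$nGenes, spec$nTissues,
            dimnames = list(genes, tissues))
        for (i in seq_len(spec$nGenes)) {
            if (i <= nP) {                       # planted: fold and floor pass
                focal <- sample.int(spec$nTissues, 1L)
                fm <- stats::runif(1, 12, 120)
                others <- stats::runif(spec$nTissues - 1L, 0.1,
                    fm / (3 * stats::runif(1, 1.05, 2)))
                means[i, focal] <- fm
                means[i, -focal] <- others
                truth[i] <- tissues[focal]
            } else {
                kind <- (i %% 3L)
                focal <- sample.int(spec$nTissues, 1L)
                if (kind == 0L) {                # floor fails, fold passes
                    fm <- stats::runif(1, 1, 9.5)
                    means[i, focal] <- fm
                    means[i, -focal] <- stats::runif(spec$nTissues - 1L,
                        0.01, fm / 3.5)
                } else if (kind == 1L) {         # fold fails, floor passes
                    fm <- stats::runif(1, 15, 100)
                    means[i, focal] <- fm
                    means[i, -focal] <- stats::runif(spec$nTissues - 1L,
                        fm / 2.9, fm)
                } else {                         # flat
                    means[i, ] <- stats::runif(1, 5, 50)
                }
            }
        }
        nS <- spec$nSamplesPerTissue
        samples <- unlist(lapply(tissues, function(t)
            sprintf("%s_rep%d", t, seq_len(nS))))
        vals <- matrix(0, spec$nGenes, length(samples),
            dimnames = list(genes, samples))
        for (j in seq_len(spec$nTissues)) {
            cols <- (j - 1L) * nS + seq_len(nS)
            mu <- means[, j]
            if (nS == 1L) {
                vals[, cols] <- mu
            } else {
                eps <- matrix(stats::runif(spec$nGenes * nS, -0.05, 0.05),
                    spec$nGenes, nS)
                eps <- eps - rowMeans(eps)       # zero-sum: group mean exact
                vals[, cols] <- pmax(0, mu * (1 + eps))
            }
        }
        list(means = means, vals = vals, truth = truth, samples = samples)
    })
    matPath <- file.path(dir, "rpkm.tsv")
    df <- data.frame(gene_id = genes, res$vals, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, matPath, sep = "\t", quote = FALSE, row.names = FALSE)
    groupsPath <- file.path(dir, "sample_groups.tsv")
    utils::write.table(data.frame(sample = res$samples,
        tissue_group = sub("_rep\\d+$", "", res$samples)),
        groupsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    manifestPath <- file.path(dir, "rpkm.manifest.json")
    .writeManifest(list(seed = spec$seed,
        planted = stats::setNames(as.list(res$truth), genes)), manifestPath)
    invisible(list(matrix = matPath, groups = groupsPath,
        manifest = manifestPath))
}

#' Generate a synthetic gene-set collection
#'
#' `nSets` sets with sizes uniform in `setSizeRange`, members drawn from the
#' `nGenes` universe. Used as the substrate for planted-screen fixtures and
#' recovery tests.
#'
#' @param spec a [fixtureSpec()].
#' @param organism,idSpace collection metadata.
#' @return A [GeneSetCollection-class].
#' @export
makeCollectionFixture <- function(spec, organism = "dm",
                                  idSpace = "mod_primary") {
    genes <- .geneIds(spec$nGenes)
    sets <- .withSeed(spec$seed, {
        lapply(seq_len(spec$nSets), function(i) {
            sz <- sample(seq(spec$setSizeRange[1], spec$setSizeRange[2]), 1L)
            GeneSet(sprintf("SET:%04d", i), sample(genes, min(sz, length(genes))),
                name = sprintf("synthetic set %d", i))
        })
    })
    GeneSetCollection(sets, categoryId = "synthetic", organism = organism,
        idSpace = idSpace, source = "fixture")
}

#' Generate planted screen-hit gene lists against a collection
#'
#' Emulates hit lists from several phenotypic screens, each planted on one
#' gene set: a list is `list_size` members sampled from its planted set plus
#' `noise_genes` genes drawn uniformly from the rest of the collection's
#' universe. The manifest records the list-to-set planting.
#'
#' @param spec a [fixtureSpec()]; `spec$planted` may name the planted sets,
#'   otherwise `nLists` sets are picked (most-disjoint first) with list size
#'   20 and 5 noise genes.
#' @param collection the substrate [GeneSetCollection-class].
#' @param dir output directory.
#' @return Invisibly, list with `lists` (paths) and `manifest`.
#' @export
makeScreenFixture <- function(spec, collection, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    universe <- geneUniverse(collection)
    planted <- spec$planted
    res <- .withSeed(spec$seed, {
        if (is.null(planted)) {
            pick <- sample(setIds(collection), spec$nLists)
            planted <- data.frame(set_id = pick, list_size = 20L,
                noise_genes = 5L, stringsAsFactors = FALSE)
        }
        lists <- lapply(seq_len(nrow(planted)), function(i) {
            mem <- members(collection[[planted$set_id[i]]])
            core <- sample(mem, min(planted$list_size[i], length(mem)))
            pool <- setdiff(universe, mem)
            noise <- if (planted$noise_genes[i] > 0L)
                sample(pool, min(planted$noise_genes[i], length(pool)))
            else character(0)
            unique(c(core, noise))
        })
        list(planted = planted, lists = lists)
    })
    paths <- character(nrow(res$planted))
    for (i in seq_along(paths)) {
        paths[i] <- file.path(dir, sprintf("screen%02d.txt", i))
        writeLines(res$lists[[i]], paths[i])
    }
    manifestPath <- file.path(dir, "screens.manifest.json")
    .writeManifest(list(seed = spec$seed,
        lists = lapply(seq_along(paths), function(i) list(
            file = basename(paths[i]),
            planted_set = res$planted$set_id[i],
            list_size = res$planted$list_size[i],
            noise_genes = res$planted$noise_genes[i]))), manifestPath)
    invisible(list(lists = paths, manifest = manifestPath))
}

#' Generate a synthetic id-mapping table fixture
#'
#' Canonical primary ids with symbol and entrez aliases, a share of
#' secondary (withdrawn) ids, one deliberately ambiguous alias and the
#' manifest recording each category — exercising every [mapIds()] path.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory.
#' @param organism species code.
#' @return Invisibly, list with `map` and `manifest` paths.
#' @export
makeIdMapFixture <- function(spec, dir, organism = "dm") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    n <- max(10L, min(spec$nGenes, 50L))
    canon <- .geneIds(n)
    sym <- sprintf("sym%03d", seq_len(n))
    entrez <- sprintf("%d", 100000L + seq_len(n))
    rows <- data.frame(
        alias = c(sym, entrez, canon, canon),
        canonical = c(canon, canon, sym, entrez),
        id_type = c(rep("mod_primary", 2L * n), rep("symbol", n),
            rep("entrez", n)),
        status = "current", stringsAsFactors = FALSE)
    nSec <- max(2L, n %/% 10L)
    secondary <- data.frame(
        alias = sprintf("FBgn9%06d", seq_len(nSec)),
        canonical = canon[seq_len(nSec)],
        id_type = "mod_primary", status = "secondary",
        stringsAsFactors = FALSE)
    ambiguous <- data.frame(
        alias = "ambig1", canonical = canon[1:2],
        id_type = "mod_primary", status = "current",
        stringsAsFactors = FALSE)
    tab <- rbind(rows, secondary, ambiguous)
    mapPath <- file.path(dir, "idmap.tsv")
    utils::write.table(tab, mapPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    manifestPath <- file.path(dir, "idmap.manifest.json")
    .writeManifest(list(seed = spec$seed, organism = organism,
        n_canonical = n, secondary = secondary$alias,
        ambiguous = "ambig1"), manifestPath)
    invisible(list(map = mapPath, manifest = manifestPath))
}
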