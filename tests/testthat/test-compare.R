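screenScenario <- function(seed = 21) {
    spec <- fixtureSpec(seed = seed, nGenes = 500, nSets = 20,
        setSizeRange = c(20, 30), nLists = 5)
    coll <- makeCollectionFixture(spec)
    fx <- makeScreenFixture(spec, coll, tempfile())
    man <- jsonlite::read_json(fx$manifest, simplifyVector = FALSE)
    lists <- lapply(seq_along(fx$lists), function(i)
        readGeneList(fx$lists[i], organism = "dm"))
    list(coll = coll, lists = lists, man = man)
}

test_that("enrichMulti runs each list independently and in order", {
    sc <- screenScenario()
    runs <- enrichMulti(sc$lists, sc$coll)
    expect_length(runs, 5L)
    expect_equal(names(runs), vapply(sc$lists, function(l) l@listId, ""))
    # two identical lists give identical results
    dup <- enrichMulti(list(sc$lists[[1]], sc$lists[[1]]), sc$coll)
    expect_equal(results(dup[[1]]), results(dup[[2]]))
    # the degenerate single-list case equals enrich
    one <- enrichMulti(sc$lists[1], sc$coll)
    expect_equal(results(one[[1]]), results(enrich(sc$lists[[1]], sc$coll)))
})

test_that("enrichMulti names the offending list on failure", {
    coll <- GeneSetCollection(list(GeneSet("S", c("a", "b"))),
        "toy", "dm", "symbol")
    bad <- GeneList("zz", "dm", listId = "badlist")
    ok <- GeneList("a", "dm")
    expect_error(enrichMulti(list(ok, bad), coll, background = c("a", "b")),
        "badlist")
    expect_error(enrichMulti(list(ok, GeneList("a", "hs")), coll),
        "mix organisms")
})

test_that("comparison matrix rows are the union of per-run significant sets", {
    sc <- screenScenario()
    runs <- enrichMulti(sc$lists, sc$coll)
    cutoff <- 1e-3
    cm <- comparisonMatrix(runs, "p_raw", cutoff, "neglog10p")
    perRun <- lapply(runs, function(r)
        results(filterResults(r, "p_raw", cutoff))$set_id)
    expect_setequal(cm@setIds, unique(unlist(perRun)))
    # diagonal dominance: each planted set is strongest in its own screen
    for (i in seq_along(runs)) {
        planted <- sc$man$lists[[i]]$planted_set
        expect_true(planted %in% cm@setIds)
        expect_equal(which.max(cm@value[planted, ]), c(i),
            ignore_attr = TRUE)
    }
})

test_that("comparison matrix distinguishes untestable from non-significant", {
    collA <- GeneSetCollection(list(GeneSet("S1", c("a", "b", "c")),
        GeneSet("S2", c("x", "y"))), "toy", "dm", "symbol")
    l1 <- GeneList(c("a", "b", "c"), "dm", listId = "L1")
    l2 <- GeneList(c("x", "q"), "dm", listId = "L2")
    runs <- enrichMulti(list(l1, l2), collA)
    cm <- comparisonMatrix(runs, "p_raw", 0.3, "p")
    # S1 significant only for L1; the L2 cell is tested and carries its value
    expect_true(cm@significant["S1", "L1"])
    expect_true(cm@tested["S1", "L2"])
    expect_false(cm@significant["S1", "L2"])
    expect_equal(cm@p["S1", "L2"],
        results(runs[[2]])$p_raw[results(runs[[2]])$set_id == "S1"])
    # neglog10p conversion: p = 1e-5 maps to 5
    cm2 <- comparisonMatrix(runs, "p_raw", 0.3, "neglog10p")
    expect_equal(cm2@value["S1", "L1"], -log10(cm@p["S1", "L1"]))
    expect_error(comparisonMatrix(runs, "p_raw", 1e-30), "nothing passes")
})

test_that("untestable cells are NA after background intersection empties a set", {
    coll <- GeneSetCollection(list(GeneSet("S1", c("a", "b")),
        GeneSet("S2", c("q", "r"))), "toy", "dm", "symbol")
    l1 <- GeneList(c("a", "b"), "dm", listId = "L1")
    l2 <- GeneList(c("a"), "dm", listId = "L2")
    r1 <- enrich(l1, coll)                                  # both sets tested
    r2 <- enrich(l2, coll, background = c("a", "b"))        # S2 untestable
    cm <- comparisonMatrix(list(r1, r2), "p_raw", 1.1, "p")
    expect_true(is.na(cm@p["S2", "L2"]))
    expect_false(cm@tested["S2", "L2"])
})

test_that("bipartite graphs count nodes, edges and degrees correctly", {
    coll <- GeneSetCollection(list(GeneSet("S1", c("g1", "g2")),
        GeneSet("S2", c("g2", "g3")), GeneSet("S3", c("z1", "z2"))),
        "toy", "dm", "symbol")
    run <- enrich(GeneList(c("g1", "g2", "g3"), "dm"), coll)
    g <- buildBipartiteGraph(run, c("S1", "S2"))
    expect_equal(nrow(g@nodes), 5L)
    expect_equal(nrow(g@edges), 4L)
    expect_equal(sum(g@edges$gene == "g2"), 2L)   # shared gene, degree 2
    # degree bookkeeping: gene degrees and set degrees both sum to edges
    expect_equal(sum(table(g@edges$set)), nrow(g@edges))
    expect_equal(sum(table(g@edges$gene)), nrow(g@edges))
    # single set -> star graph
    star <- buildBipartiteGraph(run, "S1")
    expect_equal(nrow(star@edges), 2L)
    expect_equal(sum(star@nodes$node_type == "gene_set"), 1L)
    expect_error(buildBipartiteGraph(run, "nope"), "unknown set id")
    # sets with empty overlap are dropped rather than left isolated
    expect_warning(g3 <- buildBipartiteGraph(run, c("S1", "S3")), "empty overlap")
    expect_false("S3" %in% g3@nodes$id)
})

test_that("two disjoint sets give two connected components", {
    coll <- GeneSetCollection(list(GeneSet("S1", c("a", "b")),
        GeneSet("S2", c("x", "y"))), "toy", "dm", "symbol")
    run <- enrich(GeneList(c("a", "b", "x", "y"), "dm"), coll)
    g <- buildBipartiteGraph(run, c("S1", "S2"))
    ig <- igraph::graph_from_data_frame(g@edges, directed = FALSE)
    expect_equal(igraph::components(ig)$no, 2L)
})

test_that("graph export round-trips through GraphML and TSV", {
    coll <- GeneSetCollection(list(GeneSet("S1", c("g1", "g2")),
        GeneSet("S2", c("g2", "g3"))), "toy", "dm", "symbol")
    run <- enrich(GeneList(c("g1", "g2", "g3"), "dm"), coll)
    g <- buildBipartiteGraph(run, c("S1", "S2"))
    for (fmt in c("graphml", "tsv")) {
        p <- tempfile(fileext = paste0(".", fmt))
        exportGraph(g, p, fmt)
        back <- importGraph(p, fmt)
        o1 <- g@nodes[order(g@nodes$id), ]
        o2 <- back@nodes[order(back@nodes$id), ]
        expect_equal(o2$id, o1$id)
        expect_equal(o2$node_type, o1$node_type)
        expect_equal(o2$label, o1$label)
        ek <- function(x) sort(paste(x@edges$set, x@edges$gene))
        expect_equal(ek(back), ek(g))
    }
    # graphml counts one <node> element per node
    p <- tempfile(fileext = ".graphml")
    exportGraph(g, p, "graphml")
    expect_equal(sum(grepl("<node ", readLines(p))), nrow(g@nodes))
    expect_error(exportGraph(g, tempfile(), "dot"), "should be one of")
})

test_that("barTable clamps, orders and computes bar heights", {
    sc <- screenScenario()
    run <- enrich(sc$lists[[1]], sc$coll)
    all <- barTable(run, topN = 10000L)
    expect_equal(nrow(all), nrow(results(run)))
    top1 <- barTable(run, topN = 1L)
    expect_equal(top1$set_id, results(run)$set_id[1])
    expect_equal(top1$bar_value, -log10(top1$p_raw))
    expect_false(is.unsorted(-all$bar_value))
    tf <- barTable(run, topN = 3L, value = "fold")
    expect_equal(tf$bar_value, tf$fold)
})

test_that("comparison matrices serialise to a wide TSV", {
    sc <- screenScenario()
    runs <- enrichMulti(sc$lists, sc$coll)
    cm <- comparisonMatrix(runs, "p_raw", 1e-3)
    p <- tempfile(fileext = ".tsv")
    writeComparisonMatrix(cm, p)
    df <- read.table(p, sep = "\t", header = TRUE, check.names = FALSE)
    expect_equal(nrow(df), length(cm@setIds))
    expect_true(all(cm@listIds %in% names(df)))
})
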