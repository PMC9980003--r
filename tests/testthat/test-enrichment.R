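test_that("hypergeomUpperTail matches hand-derived and boundary values", {
    expect_equal(hypergeomUpperTail(3, 5, 5, 20), 1126 / 15504,
        tolerance = 1e-12)
    expect_identical(hypergeomUpperTail(0, 5, 5, 20), 1)
    expect_identical(hypergeomUpperTail(7, 20, 7, 20), 1)   # set = population
    expect_error(hypergeomUpperTail(6, 5, 10, 20), "k <= min\\(n, K\\)")
    expect_error(hypergeomUpperTail(1, 25, 5, 20), "K <= N")
    expect_error(hypergeomUpperTail(1, 5, 25, 20), "n <= N")
    expect_error(hypergeomUpperTail(-1, 5, 5, 20), "k >= 0")
})

test_that("hypergeomUpperTail agrees with the survival function from stats", {
    set.seed(5)
    for (rep in 1:200) {
        N <- sample(2:500, 1)
        K <- sample.int(N, 1)
        n <- sample.int(N, 1)
        k <- sample.int(min(n, K) + 1L, 1) - 1L
        expect_equal(hypergeomUpperTail(k, K, n, N),
            phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            tolerance = 1e-12)
    }
})

test_that("fold enrichment is (k/n)/(K/N)", {
    expect_equal(foldEnrichment(3, 5, 5, 20), 2.4)
    expect_equal(foldEnrichment(0, 5, 5, 20), 0)
    expect_equal(foldEnrichment(7, 20, 7, 20), 1)
    expect_error(foldEnrichment(0, 0, 5, 20), "K = 0")
    expect_error(foldEnrichment(0, 5, 0, 20), "n = 0")
})

test_that("p-value adjustments reproduce the step-up formulas", {
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
        rep(0.04, 4))
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "by"),
        rep(0.04 * 25 / 12, 4))
    expect_equal(adjustPvalues(c(0.3, 0.4, 0.5, 0.6, 0.7), "bonferroni")[1], 1)
    set.seed(8)
    for (rep in 1:20) {
        p <- runif(sample.int(30, 1))
        expect_equal(adjustPvalues(p, "bonferroni"), oracleBonferroni(p))
        expect_equal(adjustPvalues(p, "bh"), oracleBH(p))
        expect_equal(adjustPvalues(p, "by"), oracleBY(p))
    }
    expect_error(adjustPvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

twoSetCollection <- function() {
    GeneSetCollection(list(
        GeneSet("S1", c("a", "b", "c")),
        GeneSet("S2", c("x", "y", "z", "w"))),
        "toy", "dm", "symbol")
}

test_that("a list equal to one set dominates the ranking", {
    run <- enrich(GeneList(c("a", "b", "c"), "dm"), twoSetCollection())
    res <- results(run)
    expect_equal(res$set_id[1], "S1")
    expect_equal(res$k[1], 3L)
    expect_equal(res$n[1], 3L)
    expect_equal(res$N[1], 7L)   # default background: collection union + input
    expect_setequal(res$overlap_genes[[1]], c("a", "b", "c"))
})

test_that("uncovered genes are the coverage complement", {
    coll <- GeneSetCollection(list(GeneSet("S1", "g1")), "toy", "dm", "symbol")
    run <- enrich(GeneList(c("g1", "g2", "g3"), "dm"), coll)
    expect_setequal(run@uncoveredGenes, c("g2", "g3"))
})

test_that("a user background redefines N and drops outside genes", {
    # focused-screen scenario: 50-gene sub-library background, list of 10,
    # set with 20 background members, 8 hits
    bg <- sprintf("k%02d", 1:50)
    set <- GeneSet("KIN", bg[1:20])
    coll <- GeneSetCollection(list(set), "kin", "dm", "symbol")
    lst <- GeneList(c(bg[1:8], bg[40:41], "outsider"), "dm")
    run <- enrich(lst, coll, background = bg)
    res <- results(run)
    expect_equal(run@droppedGenes, "outsider")
    expect_equal(res$N, 50L)
    expect_equal(res$n, 10L)
    expect_equal(res$k, 8L)
    expect_equal(res$p_raw, oracleHyper(8, 20, 10, 50), tolerance = 1e-12)
    expect_equal(res$fold, (8 / 10) / (20 / 50))
})

test_that("membership outside the background does not count", {
    coll <- GeneSetCollection(list(GeneSet("S", c("a", "b", "q"))),
        "toy", "dm", "symbol")
    run <- enrich(GeneList(c("a", "b"), "dm"), coll,
        background = c("a", "b", "c", "d"))
    expect_equal(results(run)$K, 2L)   # q is outside the background
})

test_that("shrinking the background to set + list never lowers p", {
    set.seed(13)
    for (rep in 1:20) {
        coll <- randomCollection(5, 30, seed = rep)
        lst <- GeneList(sample(sprintf("g%03d", 1:200), 25), "dm")
        runWide <- enrich(lst, coll, background = sprintf("g%03d", 1:200))
        for (sid in setIds(coll)) {
            tight <- unique(c(members(coll[[sid]]), lst@genes))
            runTight <- enrich(lst, coll, background = tight)
            pWide <- results(runWide)$p_raw[results(runWide)$set_id == sid]
            pTight <- results(runTight)$p_raw[results(runTight)$set_id == sid]
            expect_gte(pTight, pWide - 1e-12)
        }
    }
})

test_that("enrich rejects empty effective input and organism mismatch", {
    coll <- twoSetCollection()
    expect_error(enrich(GeneList("zz", "dm"), coll, background = c("a", "b")),
        "empty effective input")
    expect_error(enrich(GeneList("a", "hs"), coll), "organism mismatch")
})

test_that("filterResults uses strict inequality and preserves order", {
    coll <- twoSetCollection()
    run <- enrich(GeneList(c("a", "b", "c"), "dm"), coll)
    expect_equal(nrow(results(filterResults(run, "p_raw", 0))), 0L)
    # p_raw = 1 results are dropped even at cutoff 1.0
    kept <- filterResults(run, "p_raw", 1)
    expect_true(all(results(kept)$p_raw < 1))
    known <- results(run)$p_raw
    keep <- filterResults(run, "p_raw", known[1] + 1e-9)
    expect_equal(results(keep)$set_id, results(run)$set_id[known < known[1] + 1e-9])
})

test_that("the planted set is recovered at the top of the ranking", {
    hits <- 0L
    nRuns <- 30L
    for (seed in seq_len(nRuns)) {
        spec <- fixtureSpec(seed = seed, nGenes = 2000, nSets = 50,
            setSizeRange = c(20, 40), nLists = 1)
        coll <- makeCollectionFixture(spec)
        fx <- makeScreenFixture(spec, coll, tempfile())
        man <- jsonlite::read_json(fx$manifest)
        lst <- readGeneList(fx$lists[1], organism = "dm")
        run <- enrich(lst, coll, background = sprintf("FBgn%07d", 1:2000))
        if (results(run)$set_id[1] == man$lists[[1]]$planted_set)
            hits <- hits + 1L
    }
    expect_gte(hits / nRuns, 0.95)
})

test_that("enrichment TSV export carries the contingency and overlap columns", {
    run <- enrich(GeneList(c("a", "b", "c"), "dm"), twoSetCollection())
    p <- tempfile(fileext = ".tsv")
    u <- tempfile()
    writeEnrichment(run, p, uncoveredPath = u)
    df <- read.table(p, sep = "\t", header = TRUE)
    expect_equal(names(df), c("set_id", "name", "N", "K", "n", "k", "p_raw",
        "p_bonferroni", "p_bh", "p_by", "fold", "overlap"))
    expect_equal(df$overlap[df$set_id == "S1"], "a;b;c")
})
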