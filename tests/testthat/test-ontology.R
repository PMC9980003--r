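test_that("readObo parses chains, honours obsolete flags and relation filters", {
    ont <- chainOntology()
    expect_equal(ontologyRoots(ont), "A")
    expect_equal(ont@parents[["C"]], "B")

    # obsolete term loaded but excluded from traversal
    p <- writeOboFixture(c("A", "B"), data.frame(child = "B", parent = "A",
        relation = "is_a"), obsolete = "B")
    ont2 <- readObo(p)
    expect_true(ont2@terms$is_obsolete[ont2@terms$term_id == "B"])
    expect_equal(termAncestors(ont2, "B"), "B")

    # part_of edge dropped when only is_a is traversed
    p <- writeOboFixture(c("A", "B"), data.frame(child = "B", parent = "A",
        relation = "part_of"))
    expect_equal(termAncestors(readObo(p, relations = "is_a"), "B"), "B")
    expect_setequal(termAncestors(readObo(p), "B"), c("A", "B"))
})

test_that("readObo rejects cycles, dangling parents and alt collisions", {
    p <- writeOboFixture(c("A", "B"), data.frame(child = c("A", "B"),
        parent = c("B", "A"), relation = "is_a"))
    expect_error(readObo(p), "cycle")
    p <- writeOboFixture("A", data.frame(child = "A", parent = "ZZ",
        relation = "is_a"))
    expect_error(readObo(p), "dangling")
    p <- writeOboFixture(c("A", "B"), altIds = list(A = "B"))
    expect_error(readObo(p), "collide")
})

test_that("termAncestors is the reflexive-transitive closure", {
    chain <- chainOntology()
    expect_setequal(termAncestors(chain, "C"), c("A", "B", "C"))
    expect_equal(termAncestors(chain, "A"), "A")
    expect_setequal(termAncestors(diamondOntology(), "D"),
        c("A", "B", "C", "D"))
    expect_error(termAncestors(chain, "nope"), "unknown term")
})

test_that("buildDirectSets does not propagate and resolves alt ids", {
    chain <- chainOntology()
    coll <- buildDirectSets(chain, annotationDf("g", "C"))
    expect_equal(setIds(coll), "C")
    expect_equal(members(coll[["C"]]), "g")

    coll2 <- buildDirectSets(chain, annotationDf(c("g1", "g2"), "C"))
    expect_length(members(coll2[["C"]]), 2L)

    p <- writeOboFixture("A", altIds = list(A = "A_old"))
    ontAlt <- readObo(p)
    coll3 <- buildDirectSets(ontAlt, annotationDf("g", "A_old"))
    expect_equal(setIds(coll3), "A")

    pObs <- writeOboFixture(c("A", "B"), obsolete = "B")
    expect_warning(
        collObs <- buildDirectSets(readObo(pObs),
            annotationDf(c("g1", "g2"), c("A", "B"))),
        "obsolete")
    expect_equal(setIds(collObs), "A")
})

test_that("buildPropagatedSets unions genes up the DAG", {
    chain <- chainOntology()
    coll <- buildPropagatedSets(chain, annotationDf("g", "C"))
    expect_setequal(setIds(coll), c("A", "B", "C"))
    for (s in c("A", "B", "C")) expect_equal(members(coll[[s]]), "g")

    coll2 <- buildPropagatedSets(chain, annotationDf(c("g1", "g2"), c("C", "B")))
    expect_setequal(members(coll2[["A"]]), c("g1", "g2"))
    expect_setequal(members(coll2[["B"]]), c("g1", "g2"))
    expect_equal(members(coll2[["C"]]), "g1")

    coll3 <- buildPropagatedSets(chain, annotationDf("g", "A"))
    expect_equal(setIds(coll3), "A")
})

test_that("mapToSlim assigns genes via ancestor hits on direct annotations", {
    chain <- chainOntology()
    expect_equal(members(mapToSlim(chain, annotationDf("g", "C"), "A")[["A"]]),
        "g")
    # root annotation does not reach a slim term below it
    coll <- mapToSlim(chain, annotationDf("g", "A"), "B")
    expect_equal(nSets(coll), 0L)
    coll2 <- mapToSlim(chain, annotationDf("g", "C"), c("B", "A"))
    expect_setequal(setIds(coll2), c("A", "B"))
    expect_error(mapToSlim(chain, annotationDf("g", "C"), character(0)),
        "non-empty")
})

test_that("propagation matches the descendant-union oracle on random DAGs", {
    for (seed in 1:30) {
        fx <- randomDagFixture(seed, nTerms = sample(5:50, 1),
            nAnnotations = sample(20:200, 1))
        coll <- buildPropagatedSets(fx$ont, fx$ann)
        expected <- oracleDescendantUnion(fx$ont,
            unique(fx$ann[, c("gene_id", "term_id")]))
        got <- lapply(members(coll), sort)
        expect_equal(got[order(names(got))], expected[order(names(expected))])

        # monotonicity: parent set contains child set for every retained edge
        for (child in names(fx$ont@parents))
            for (par in fx$ont@parents[[child]])
                if (!is.null(got[[child]]))
                    expect_true(all(got[[child]] %in% got[[par]]))

        # direct sets are subsets of propagated sets
        direct <- members(buildDirectSets(fx$ont, fx$ann))
        for (t in names(direct))
            expect_true(all(direct[[t]] %in% got[[t]]))
    }
})

test_that("slim over all terms equals propagation restricted to annotated reach", {
    fx <- randomDagFixture(7)
    slim <- mapToSlim(fx$ont, fx$ann, fx$ont@terms$term_id)
    prop <- buildPropagatedSets(fx$ont, fx$ann)
    expect_equal(lapply(members(slim), sort)[sort(setIds(slim))],
        lapply(members(prop), sort)[sort(setIds(prop))])
})

test_that("namespace restriction splits collections at build time", {
    pA <- writeOboFixture(c("A", "B"), namespace = "molecular_function")
    ont <- readObo(pA)
    coll <- buildDirectSets(ont, annotationDf(c("g1", "g2"), c("A", "B")),
        namespace = "biological_process")
    expect_equal(nSets(coll), 0L)
})
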