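# Independent brute-force oracles, written from first principles so that the
# implementations they check share no code path with them.

# upper-tail hypergeometric by direct PMF enumeration with exact
# binomial coefficients
oracleHyper <- function(k, K, n, N) {
    if (k <= 0) return(1)
    i <- k:min(n, K)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# literal step-up definitions (quadratic; for tiny vectors only)
oracleBonferroni <- function(p) pmin(1, p * length(p))

oracleBH <- function(p) {
    m <- length(p)
    ps <- sort(p)
    r <- rank(p, ties.method = "first")
    vapply(r, function(ri) min(1, min(ps[ri:m] * m / (ri:m))), numeric(1))
}

oracleBY <- function(p) {
    cm <- sum(1 / seq_len(length(p)))
    pmin(1, oracleBH(p) * cm)
}

# descendant-union propagation: for each term DFS all descendants in the
# child graph and union their directly annotated genes
oracleDescendantUnion <- function(ont, annotations) {
    children <- list()
    for (child in names(ont@parents))
        for (par in ont@parents[[child]])
            children[[par]] <- c(children[[par]], child)
    direct <- split(annotations$gene_id, annotations$term_id)
    out <- list()
    for (t in ont@terms$term_id) {
        stack <- t
        seen <- character(0)
        while (length(stack)) {
            x <- stack[[1]]
            stack <- stack[-1]
            if (x %in% seen) next
            seen <- c(seen, x)
            stack <- c(stack, children[[x]])
        }
        genes <- unique(unlist(direct[seen], use.names = FALSE))
        if (length(genes)) out[[t]] <- sort(genes)
    }
    out
}

# per-gene loop re-statement of the tissue-preferential rule
oracleClassify <- function(means, fold = 3, minRpkm = 10) {
    out <- stats::setNames(character(0), character(0))
    for (g in rownames(means)) {
        for (grp in colnames(means)) {
            m <- means[g, grp]
            others <- means[g, setdiff(colnames(means), grp)]
            if (m > 0 && all(m >= fold * others) && m >= minRpkm)
                out[g] <- grp
        }
    }
    out
}
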