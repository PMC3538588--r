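test_that("hypergeometric tail matches enumeration on frozen examples", {
    expect_equal(hypergeometricTail(0, 5, 5, 10), 1)
    expect_equal(hypergeometricTail(2, 3, 3, 10), 11 / 60)
    expect_equal(hypergeometricTail(4, 5, 8, 20),
                 (5 * 1365 + 455) / 125970)
    expect_error(hypergeometricTail(4, 3, 3, 10), "min\\(K, n\\)")
    expect_error(hypergeometricTail(1, 11, 3, 10), "exceed N")
    expect_error(hypergeometricTail(0, 0, 0, 0), "N must be")
})

test_that("tail is symmetric in the two set sizes and monotone in k", {
    set.seed(1)
    for (i in 1:50) {
        N <- sample(5:200, 1)
        K <- sample.int(N, 1); n <- sample.int(N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeometricTail(k, K, n, N),
                     hypergeometricTail(k, n, K, N))
    }
    ks <- 0:8
    tails <- hypergeometricTail(ks, 10, 12, 40)
    expect_true(all(diff(tails) <= 0))
})

test_that("EASE score applies the k-1 rule and dominates the plain tail", {
    expect_equal(easeScore(0, 5, 5, 20), 1)
    expect_equal(easeScore(1, 7, 3, 50), 1)   # single-gene overlap: no evidence
    expect_equal(easeScore(3, 3, 3, 10), hypergeometricTail(2, 3, 3, 10))
    set.seed(2)
    for (i in 1:50) {
        N <- sample(5:100, 1)
        K <- sample.int(N, 1); n <- sample.int(N, 1)
        k <- sample(0:min(K, n), 1)
        expect_gte(easeScore(k, K, n, N), hypergeometricTail(k, K, n, N))
    }
})

test_that("BH adjustment matches the literal step-up reference", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(c(0.04, 0.01)), c(0.04, 0.02))
    expect_identical(bhAdjust(numeric()), numeric())
    expect_error(bhAdjust(c(0.1, 0)), "\\(0, 1\\]")

    set.seed(3)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bhReference(p))
        expect_true(all(adj >= p))          # adjustment never decreases
        expect_true(all(adj <= 1))
        # adjusted values respect the ordering of the raw values
        expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
})

test_that("Bonferroni adjustment multiplies and caps", {
    expect_equal(bonferroniAdjust(0.01, 5), 0.05)
    expect_equal(bonferroniAdjust(0.5, 4), 1)
    expect_equal(bonferroniAdjust(0.2, 1), 0.2)
    expect_error(bonferroniAdjust(0.1, 0), ">= 1")
})

test_that("pathway enrichment computes margins within the universe", {
    universe <- sprintf("U%02d", 1:20)
    pc <- PathwayCollection(list(PW = universe[1:5]))
    query <- c(universe[1:4], universe[10:13])
    res <- pathwayEnrichment(query, pc, universe,
                             method = "hypergeometric",
                             correction = "none")
    expect_equal(res$k, 4L)
    expect_equal(res$K, 5L)
    expect_equal(res$n, 8L)
    expect_equal(res$N, 20L)
    expect_equal(res$pRaw, bruteTail(4, 5, 8, 20))
    expect_setequal(res$genes[[1]], universe[1:4])

    # disjoint query: p = 1 everywhere
    resDisj <- pathwayEnrichment(universe[10:12], pc, universe,
                                 method = "hypergeometric",
                                 correction = "none")
    expect_equal(resDisj$pRaw, 1)

    # pathway equal to whole universe forces k = n, p = 1
    pcAll <- PathwayCollection(list(ALL = universe))
    resAll <- pathwayEnrichment(query, pcAll, universe,
                                method = "hypergeometric",
                                correction = "none")
    expect_equal(resAll$pRaw, 1)

    # empty query -> empty result; empty universe -> error
    expect_equal(nrow(pathwayEnrichment(character(), pc, universe)), 0L)
    expect_error(pathwayEnrichment(query, pc, character()), "empty universe")

    # query genes outside the universe are dropped with a message
    expect_message(
        pathwayEnrichment(c(query, "NOTINUNIVERSE"), pc, universe),
        "dropped 1")
})

test_that("enrichment results are sorted with deterministic tie-breaks", {
    universe <- sprintf("U%02d", 1:30)
    pc <- PathwayCollection(list(B = universe[1:5], A = universe[1:5],
                                 C = universe[21:25]))
    res <- pathwayEnrichment(universe[1:6], pc, universe,
                             method = "hypergeometric",
                             correction = "none")
    expect_identical(res$pathway[1:2], c("A", "B"))  # ties by name
    expect_true(all(diff(res$pAdj) >= 0))
})

test_that("overlap test is symmetric with exact margins and Bonferroni", {
    universe <- sprintf("U%02d", 1:20)
    A <- universe[1:5]; B <- c(universe[2:5], universe[6:9])
    r1 <- overlapTest(A, B, universe, m = 6)
    r2 <- overlapTest(B, A, universe, m = 6)
    expect_equal(r1$k, 4L)
    expect_equal(r1$pRaw, bruteTail(4, 5, 8, 20))
    expect_equal(r1$pAdj, min(1, 6 * r1$pRaw))
    expect_equal(r1$pRaw, r2$pRaw)

    disj <- overlapTest(universe[1:3], universe[4:6], universe)
    expect_equal(disj$k, 0L)
    expect_equal(disj$pRaw, 1)

    degenerate <- overlapTest(universe, universe, universe)
    expect_equal(degenerate$k, 20L)
    expect_equal(degenerate$pRaw, 1)

    expect_error(overlapTest(A, B, character()), "empty universe")
})

test_that("tail equals brute-force enumeration on random margins", {
    set.seed(4)
    worst <- 0
    for (i in 1:200) {
        N <- sample(1:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
        ks <- 0:min(K, n)
        got <- hypergeometricTail(ks, K, n, N)
        want <- vapply(ks, bruteTail, 0, K = K, n = n, N = N)
        worst <- max(worst, abs(got - want))
    }
    expect_lt(worst, 1e-12)
})
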