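test_that("drug screen filters below the minimum overlap before testing", {
    universe <- sprintf("U%02d", 1:20)
    target <- universe[1:8]
    drugs <- list(keep = c(universe[1:4], universe[15]),   # overlap 4
                  drop = c(universe[1:3], universe[16]))   # overlap 3
    res <- drugOverlapScreen(drugs, target, universe, minOverlap = 4)
    expect_identical(res$label, "keep")
    expect_equal(res$m, 1L)                 # excluded drug not counted
    expect_equal(res$pAdj, res$pRaw)        # single retained drug

    # frozen enumeration value: |drug|=5, target 8, overlap 4, N=20, m=6
    drugs6 <- c(list(main = c(universe[1:4], universe[15])),
                setNames(lapply(1:5, function(i)
                    universe[c(1:4, 14 + i)]), paste0("d", 1:5)))
    res6 <- drugOverlapScreen(drugs6, target, universe, minOverlap = 4)
    expect_equal(res6$m, rep(6L, 6))
    expect_equal(res6$pRaw[res6$label == "main"],
                 bruteTail(4, 5, 8, 20))
    expect_equal(res6$pAdj[res6$label == "main"],
                 min(1, 6 * bruteTail(4, 5, 8, 20)))

    expect_equal(nrow(drugOverlapScreen(list(), target, universe)), 0L)
    expect_error(drugOverlapScreen(drugs, target, universe, 0), ">= 1")
})

test_that("intersection testing matches the enumeration oracle", {
    universe <- sprintf("U%02d", 1:20)
    inter <- universe[1:5]
    trans <- c(universe[2:5], universe[6:9])
    it <- intersectAndTest(inter, trans, universe, m = 4, label = "c1")
    expect_setequal(it$intersection, universe[2:5])
    expect_equal(it$overlap$pRaw, bruteTail(4, 5, 8, 20))
    expect_equal(it$overlap$pAdj, min(1, 4 * bruteTail(4, 5, 8, 20)))

    disj <- intersectAndTest(universe[1:3], universe[4:6], universe)
    expect_length(disj$intersection, 0)
    expect_equal(disj$overlap$pRaw, 1)

    sup <- intersectAndTest(inter, universe, universe)
    expect_setequal(sup$intersection, inter)
})

test_that("common pathways require significance in every condition", {
    e1 <- data.frame(pathway = c("P1", "P2", "P3"),
                     pRaw = c(0.001, 0.02, 0.2),
                     pAdj = c(0.01, 0.2, 0.6))
    e2 <- data.frame(pathway = c("P1", "P2", "P3"),
                     pRaw = c(0.04, 0.3, 0.01),
                     pAdj = c(0.2, 0.7, 0.1))
    single <- commonPathways(list(a = e1), alpha = 0.05)
    expect_setequal(single$pathway, c("P1", "P2"))

    both <- commonPathways(list(a = e1, b = e2), alpha = 0.05)
    expect_identical(both$pathway, "P1")
    expect_equal(both$worstP, 0.04)

    none <- commonPathways(list(a = e1,
                                b = data.frame(pathway = "P9",
                                               pRaw = 0.9, pAdj = 0.9)),
                           alpha = 0.05)
    expect_equal(nrow(none), 0L)

    # adjusted-p membership is a subset of raw-p membership
    adj <- commonPathways(list(a = e1, b = e2), alpha = 0.05,
                          on = "adjusted")
    expect_true(all(adj$pathway %in% both$pathway))
})

test_that("ablation removes exactly the pathway genes and reports impact", {
    universe <- sprintf("U%02d", 1:40)
    pc <- PathwayCollection(list(TARGET = universe[1:8],
                                 OTHER = universe[5:14],
                                 FAR = universe[30:35]))
    inter <- universe[1:12]
    ab <- ablatePathway(inter, members(pc, "TARGET"), pc, universe,
                        method = "hypergeometric", correction = "none",
                        on = "raw")
    expect_setequal(ab$removed, universe[1:8])
    expect_equal(ab$remainingCount, 4L)
    # the ablated pathway itself: k = 0, p exactly 1 afterwards
    after <- ab$after
    expect_equal(after$k[after$pathway == "TARGET"], 0L)
    expect_equal(after$pRaw[after$pathway == "TARGET"], 1)
    # removing genes can only decrease every overlap count
    before <- ab$before
    shared <- intersect(before$pathway, after$pathway)
    expect_true(all(after$k[match(shared, after$pathway)] <=
                    before$k[match(shared, before$pathway)]))

    # disjoint pathway: nothing removed, p unchanged
    ab2 <- ablatePathway(inter, members(pc, "FAR"), pc, universe,
                         method = "hypergeometric", correction = "none",
                         on = "raw")
    expect_length(ab2$removed, 0)
    expect_equal(ab2$impact$pBefore, ab2$impact$pAfter)
    expect_equal(ab2$impactScore, 0)
})

test_that("pipeline handles an empty seed set and is deterministic", {
    p <- smallParams()
    b <- plantConvergentSignal(p, seed = 51)
    cfg <- pipelineConfig(seed = 51)

    # empty seeds: raise the cutoff impossible low via an empty table
    bEmpty <- b
    bEmpty@association <- data.frame(gene = character(), p = numeric())
    repEmpty <- runPipeline(bEmpty, cfg)
    expect_length(repEmpty@seeds, 0)
    expect_length(interactomeGenes(repEmpty@expansion), 0)
    expect_equal(nrow(repEmpty@commonPathways), 0L)

    rep1 <- runPipeline(b, cfg)
    rep2 <- runPipeline(b, cfg)
    expect_identical(reportToJson(rep1), reportToJson(rep2))

    # report self-consistency: serialized counts match member sets
    parsed <- jsonlite::fromJSON(reportToJson(rep1))
    cond <- names(rep1@conditions)[1]
    expect_equal(length(parsed$conditions[[cond]]$intersection),
                 parsed$conditions[[cond]]$overlap$k)
    expect_equal(length(parsed$interactome),
                 length(interactomeGenes(rep1@expansion)))
})

test_that("pipeline recovers the planted causal pathway", {
    b <- plantConvergentSignal(mediumParams(), seed = 61)
    rep <- runPipeline(b, pipelineConfig(seed = 61))
    expect_true(b@truth$causalPathway %in% rep@commonPathways$pathway)
    expect_identical(rep@ablation$pathway[1], b@truth$causalPathway)
})

test_that("ablating the causal pathway degrades companion pathways more
           than removing an equal-size random gene set", {
    set.seed(71)
    wins <- 0L; diffs <- numeric()
    nRep <- 20L
    for (r in seq_len(nRep)) {
        p <- mediumParams(overlapFraction = 0.35)
        b <- plantConvergentSignal(p, seed = 100 + r)
        causal <- b@truth$causalPathway
        causalGenes <- members(b@pathways, causal)
        rep <- runPipeline(b, pipelineConfig(seed = 100 + r))
        cond <- names(rep@conditions)[1]
        inter <- rep@conditions[[cond]]$intersection
        u <- geneUniverse(b@pathways)
        companions <- setdiff(
            pathwayNames(b@pathways)[vapply(b@pathways@sets, function(g)
                length(intersect(g, causalGenes)) > 0, TRUE)], causal)
        # mean adjusted-p degradation of the companion pathways
        delta <- function(genes) {
            ab <- ablatePathway(inter, genes, b@pathways, u)
            pb <- setNames(ab$before$pAdj, ab$before$pathway)
            pa <- setNames(ab$after$pAdj, ab$after$pathway)
            comm <- intersect(companions, intersect(names(pb), names(pa)))
            mean(log10(pa[comm] / pb[comm]))
        }
        dCausal <- delta(causalGenes)
        dRandom <- delta(sample(u, length(causalGenes)))
        diffs <- c(diffs, dCausal - dRandom)
        if (dCausal >= dRandom) wins <- wins + 1L
    }
    expect_gte(wins / nRep, 0.75)
    expect_gt(mean(diffs), 0)
})
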