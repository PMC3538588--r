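test_that("per-gene Welch test matches hand and t.test oracles", {
    # one biorep mean per sample: case (10,11,12) vs control (4,5,6)
    mat <- matrix(c(10, 11, 12, 4, 5, 6), nrow = 1,
                  dimnames = list("G1", paste0("s", 1:6)))
    meta <- data.frame(sample = paste0("s", 1:6),
                       group = rep(c("case", "control"), each = 3),
                       biorep = as.character(rep(1:3, 2)),
                       techrep = "1")
    res <- perGeneTest(makeExpressionSet(mat, meta))
    expect_equal(res$meanCase - res$meanControl, 6)
    expect_equal(res$pRaw, 0.001826261, tolerance = 1e-6)

    # vectorized statistics agree with stats::t.test per gene
    set.seed(10)
    se <- makeToyExpression(values = 8, shift = c(0, 0.5, 1, 2, 0),
                            nBio = 4, nTech = 1, seed = 10)
    res2 <- perGeneTest(se)
    m <- SummarizedExperiment::assay(se)
    grp <- SummarizedExperiment::colData(se)$group
    for (i in seq_len(nrow(m))) {
        tt <- t.test(m[i, grp == "case"], m[i, grp == "control"])
        expect_equal(res2$pRaw[i], tt$p.value)
    }
})

test_that("technical replicates are pre-averaged; order does not matter", {
    set.seed(11)
    se <- makeToyExpression(values = 8, shift = c(1, 0), nBio = 3,
                            nTech = 4, seed = 11)
    res <- perGeneTest(se)
    perm <- sample(ncol(se))
    res2 <- perGeneTest(se[, perm])
    expect_equal(res, res2)

    # averaging matters: collapsing techreps by hand gives the same p
    m <- SummarizedExperiment::assay(se)
    cd <- SummarizedExperiment::colData(se)
    key <- paste(cd$group, cd$biorep)
    bm <- vapply(unique(key), function(k)
        rowMeans(m[, key == k, drop = FALSE]), numeric(nrow(m)))
    grp <- vapply(strsplit(unique(key), " "), `[[`, "", 1)
    tt <- t.test(bm[1, grp == "case"], bm[1, grp == "control"])
    expect_equal(res$pRaw[1], tt$p.value)
})

test_that("degenerate variance and replicate-count rules hold", {
    mat <- matrix(5, nrow = 1, ncol = 6,
                  dimnames = list("G1", paste0("s", 1:6)))
    meta <- data.frame(sample = paste0("s", 1:6),
                       group = rep(c("case", "control"), each = 3),
                       biorep = as.character(rep(1:3, 2)), techrep = "1")
    res <- perGeneTest(makeExpressionSet(mat, meta))
    expect_equal(res$pRaw, 1)

    meta1 <- meta; meta1$biorep[1:3] <- "1"   # one case biorep only
    expect_error(perGeneTest(makeExpressionSet(mat, meta1)),
                 ">= 2 biological replicates")
})

test_that("Diff score transform honors the p = 0.05 <-> 13 convention", {
    expect_equal(diffScore(1, +1), 0)
    expect_equal(diffScore(0.05, +1), 13.0103, tolerance = 1e-5)
    expect_equal(round(abs(diffScore(0.05, +1))), 13)
    expect_equal(diffScore(0.01, -1), -20)
    expect_error(diffScore(0.5, 2), "sign")
    expect_warning(s0 <- diffScore(0, +1), "clamped")
    expect_true(is.finite(s0) && s0 > 0)
    # strictly decreasing magnitude in p
    ps <- sort(runif(20, 1e-6, 1))
    expect_true(all(diff(abs(diffScore(ps, +1))) < 0))
})

test_that("DE calling is a p-threshold in disguise and BH only shrinks", {
    set.seed(12)
    se <- makeToyExpression(values = 8,
                            shift = c(rep(0, 40), rep(1.5, 10)),
                            nBio = 3, nTech = 2, seed = 12)
    de <- callDE(se, threshold = 13, condition = "toy")
    tab <- deTable(de)
    called <- tab$gene[tab$direction != "none"]
    expect_setequal(called, tab$gene[tab$pRaw <= 10^(-1.3)])
    expect_length(intersect(upGenes(de), downGenes(de)), 0)
    # direction matches the sign of the mean difference
    up <- tab[tab$direction == "up", ]
    expect_true(all(up$meanCase > up$meanControl))

    deBH <- callDE(se, threshold = 13, adjust = "bh", condition = "toy")
    expect_lte(length(calledGenes(deBH)), length(calledGenes(de)))
    expect_true(all(calledGenes(deBH) %in% calledGenes(de)))
})

test_that("null type-I rate at threshold 13 is near the nominal level", {
    level <- 10^(-1.3)   # the p cutoff a |13| Diff score corresponds to
    nGenes <- 800
    # with enough biological replicates the Welch-Satterthwaite
    # approximation is accurate and the call rate sits at the level
    se <- makeToyExpression(values = 8, shift = rep(0, nGenes),
                            nBio = 8, nTech = 2, seed = 13)
    nCalled <- length(calledGenes(callDE(se, threshold = 13)))
    bounds <- qbinom(c(0.005, 0.995), nGenes, level)
    expect_gte(nCalled, bounds[1])
    expect_lte(nCalled, bounds[2])

    # at the 3-biological-replicate study design the approximation is
    # conservative: never anti-conservative
    se3 <- makeToyExpression(values = 8, shift = rep(0, nGenes),
                             nBio = 3, nTech = 4, seed = 14)
    nCalled3 <- length(calledGenes(callDE(se3, threshold = 13)))
    expect_lte(nCalled3, bounds[2])
})

test_that("power increases with planted effect size", {
    powerAt <- function(delta, seed) {
        se <- makeToyExpression(values = 8, shift = rep(delta, 300),
                                nBio = 3, nTech = 2, seed = seed)
        length(calledGenes(callDE(se))) / 300
    }
    p1 <- powerAt(0.3, 21); p2 <- powerAt(0.8, 21); p3 <- powerAt(1.6, 21)
    expect_lt(p1, p2)
    expect_lt(p2, p3)
})

test_that("comparative Ct fold changes follow 2^-ddCt", {
    ct <- data.frame(gene = rep("INS", 4),
                     sample = paste0("s", 1:4),
                     ctTarget = c(24, 24, 26, 26),
                     ctReference = c(18, 18, 18, 18),
                     group = rep(c("case", "control"), each = 2))
    fc <- deltaDeltaCt(ct)
    expect_equal(fc$ddCt, -2)
    expect_equal(fc$fold, 4)

    # ddCt = 0 -> fold 1; ddCt = -1 -> fold 2
    ct2 <- ct; ct2$ctTarget <- c(26, 26, 26, 26)
    expect_equal(deltaDeltaCt(ct2)$fold, 1)
    ct3 <- ct; ct3$ctTarget <- c(25, 25, 26, 26)
    expect_equal(deltaDeltaCt(ct3)$fold, 2)

    # undetected rows are excluded; losing a whole group is an error
    ct4 <- ct; ct4$undetected <- c(FALSE, FALSE, TRUE, TRUE)
    expect_error(deltaDeltaCt(ct4), "not present")

    # replicate averaging within group
    ct5 <- ct; ct5$ctTarget <- c(23, 25, 26, 26)
    expect_equal(deltaDeltaCt(ct5)$ddCt, -2)
})
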