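# Independent reference implementations used as oracles.

# Upper-tail hypergeometric by direct enumeration of the pmf:
# P(X >= k) = sum_{x >= k} C(K, x) C(N-K, n-x) / C(N, n)
bruteTail <- function(k, K, n, N) {
    xs <- max(k, 0, n - (N - K)):min(K, n)
    if (length(xs) == 0L || min(K, n) < k) return(0)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: sort ascending, p(i) * m / i,
# enforce monotonicity from the largest rank down, cap at 1, restore
# input order.
bhReference <- function(p) {
    m <- length(p)
    if (m == 0L) return(numeric())
    ord <- order(p)
    scaled <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(scaled)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[ord] <- adj
    out
}

# Small expression SummarizedExperiment: genes x (2 groups, nBio bioreps,
# nTech techreps), optional per-gene case shift.
makeToyExpression <- function(values, nBio = 3L, nTech = 2L, shift = 0,
                              seed = 1L, sigma = 0.3) {
    set.seed(seed)
    nGenes <- length(shift)
    groups <- rep(c("case", "control"), each = nBio * nTech)
    bioreps <- rep(rep(seq_len(nBio), each = nTech), 2L)
    techreps <- rep(seq_len(nTech), 2L * nBio)
    ids <- paste0("s", seq_along(groups))
    mat <- matrix(rnorm(nGenes * length(groups), mean = values,
                        sd = sigma),
                  nrow = nGenes,
                  dimnames = list(sprintf("G%04d", seq_len(nGenes)), ids))
    mat[, groups == "case"] <- mat[, groups == "case"] + shift
    meta <- data.frame(sample = ids, group = groups,
                       biorep = as.character(bioreps),
                       techrep = as.character(techreps))
    makeExpressionSet(mat, meta)
}

# Reduced-scale generator parameters for fast synthetic tests.
smallParams <- function(...) {
    p <- syntheticDefaults()
    p$nGenes <- 600L; p$nEdges <- 1800L; p$nPathways <- 20L
    p$sizeRange <- c(8L, 20L); p$nSeeds <- 25L
    p$drugSizeRange <- c(10L, 40L)
    p$conditions <- c("cond_a", "cond_b"); p$nTechreps <- 2L
    utils::modifyList(p, list(...))
}

# Mid-scale parameters keeping the study's proportions (interactome a
# small fraction of the universe) so the planted signal is recoverable.
mediumParams <- function(...) {
    p <- syntheticDefaults()
    p$nGenes <- 2000L; p$nEdges <- 6000L; p$nPathways <- 40L
    p$sizeRange <- c(10L, 40L); p$nSeeds <- 40L
    p$drugSizeRange <- c(15L, 70L)
    p$conditions <- c("cond_a", "cond_b"); p$nTechreps <- 2L
    utils::modifyList(p, list(...))
}

# Null-signal version of smallParams: nothing planted anywhere.
nullParams <- function(...) {
    smallParams(delta = 0, piInteractome = 0, piBackground = 0,
                enrichmentFactor = 1, causalFraction = 0, ...)
}
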