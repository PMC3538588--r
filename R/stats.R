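#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing at least \code{k} successes when drawing
#' \code{n} items without replacement from a universe of \code{N} items of
#' which \code{K} are successes: \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}. Computed exactly through
#' the log-gamma machinery of \code{stats::phyper}; no normal
#' approximation. The tail is inclusive: \code{k} itself counts as
#' success, so \code{k = 0} always yields 1.
#'
#' @param k overlap count.
#' @param K number of successes in the universe (e.g. pathway size).
#' @param n draw size (e.g. query size).
#' @param N universe size.
#' @return upper-tail probability in (0, 1]. Vectorized over all
#'   arguments.
#' @examples
#' hypergeometricTail(2, 3, 3, 10)  # 11/60
#' @export
hypergeometricTail <- function(k, K, n, N) {
    if (any(N < 1)) stop("universe size N must be >= 1")
    if (any(K > N) || any(n > N)) stop("margins K and n must not exceed N")
    if (any(k < 0) || any(k > pmin(K, n)))
        stop("overlap k must satisfy 0 <= k <= min(K, n)")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (conservative modified Fisher exact p-value)
#'
#' The EASE score removes one overlapping gene before computing the
#' hypergeometric upper tail: \code{hypergeometricTail(max(k - 1, 0), K,
#' n, N)}. Single-gene overlaps therefore carry no evidence (p = 1), and
#' the EASE score is always at least as large as the plain Fisher upper
#' tail for the same margins.
#'
#' @inheritParams hypergeometricTail
#' @return probability in (0, 1].
#' @export
easeScore <- function(k, K, n, N) {
    if (any(k < 0) || any(k > pmin(K, n)))
        stop("overlap k must satisfy 0 <= k <= min(K, n)")
    hypergeometricTail(pmax(k - 1, 0), K, n, N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment returning adjusted values in input order:
#' sort ascending, multiply p(i) by m/i, enforce monotonicity from the
#' largest rank down, cap at 1.
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(is.na(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment for a fixed number of simultaneous tests
#'
#' @param p raw p-value(s).
#' @param m number of simultaneous tests, >= 1.
#' @return \code{min(1, m * p)}.
#' @export
bonferroniAdjust <- function(p, m) {
    if (any(m < 1)) stop("number of tests m must be >= 1")
    pmin(1, m * p)
}

#' Pathway enrichment of a query gene set
#'
#' For every pathway with at least one member inside the universe, tests
#' over-representation of the query among the pathway's genes. Margins
#' (k, K, n) are always computed within the universe; query genes outside
#' the universe are dropped with a message. The default method is the
#' EASE score with Benjamini-Hochberg correction (DAVID-like); plain
#' Fisher upper tail and raw hypergeometric are also available.
#'
#' @param query character vector of gene symbols.
#' @param pathways a \linkS4class{PathwayCollection}.
#' @param universe background gene set; default the union of all pathway
#'   genes.
#' @param method \code{"ease"}, \code{"fisher"} or
#'   \code{"hypergeometric"} (the latter two are the same inclusive tail).
#' @param correction \code{"bh"}, \code{"bonferroni"} or \code{"none"}.
#' @param quiet suppress dropped-gene messages.
#' @return data.frame with columns pathway, k, K, n, N, pRaw, pAdj,
#'   method, genes (list column of overlapping genes), sorted by pAdj
#'   then pRaw then pathway name.
#' @export
pathwayEnrichment <- function(query, pathways,
                              universe = geneUniverse(pathways),
                              method = c("ease", "fisher",
                                         "hypergeometric"),
                              correction = c("bh", "bonferroni", "none"),
                              quiet = FALSE) {
    method <- match.arg(method)
    correction <- match.arg(correction)
    stopifnot(is(pathways, "PathwayCollection"))
    universe <- unique(canonicalizeSymbol(universe))
    if (length(universe) == 0L) stop("empty universe")
    query <- unique(canonicalizeSymbol(query))
    dropped <- setdiff(query, universe)
    if (length(dropped) && !quiet)
        message("dropped ", length(dropped),
                " query gene(s) outside the universe")
    query <- intersect(query, universe)
    emptyRes <- data.frame(pathway = character(), k = integer(),
                           K = integer(), n = integer(), N = integer(),
                           pRaw = numeric(), pAdj = numeric(),
                           method = character())
    emptyRes$genes <- list()
    if (length(query) == 0L) return(emptyRes)

    sets <- lapply(pathways@sets, intersect, universe)
    keep <- vapply(sets, length, 0L) >= 1L
    sets <- sets[keep]
    if (length(sets) == 0L) return(emptyRes)

    N <- length(universe)
    n <- length(query)
    K <- vapply(sets, length, 0L)
    ov <- lapply(sets, intersect, query)
    k <- vapply(ov, length, 0L)
    pRaw <- if (method == "ease") easeScore(k, K, n, N)
            else hypergeometricTail(k, K, n, N)
    pAdj <- switch(correction,
                   bh = bhAdjust(pRaw),
                   bonferroni = bonferroniAdjust(pRaw, length(pRaw)),
                   none = pRaw)
    res <- data.frame(pathway = names(sets), k = k, K = K, n = n, N = N,
                      pRaw = pRaw, pAdj = pAdj, method = method,
                      stringsAsFactors = FALSE, row.names = NULL)
    res$genes <- unname(ov)
    res <- res[order(res$pAdj, res$pRaw, res$pathway), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Significance of the overlap between two gene sets
#'
#' Hypergeometric upper-tail probability of observing at least
#' \code{|A intersect B|} shared genes between two sets drawn from a
#' finite universe, Bonferroni-adjusted for \code{m} simultaneous
#' comparisons. Symmetric in A and B.
#'
#' @param A,B character vectors of gene symbols (restricted to the
#'   universe).
#' @param universe background gene set.
#' @param m number of simultaneous overlap tests (>= 1).
#' @param label comparison label carried into the result.
#' @return one-row data.frame: label, k, sizeA, sizeB, N, pRaw, pAdj, m,
#'   plus a list column \code{genes} of the shared symbols.
#' @export
overlapTest <- function(A, B, universe, m = 1L, label = "overlap") {
    universe <- unique(canonicalizeSymbol(universe))
    if (length(universe) == 0L) stop("empty universe")
    if (m < 1) stop("number of tests m must be >= 1")
    A <- intersect(unique(canonicalizeSymbol(A)), universe)
    B <- intersect(unique(canonicalizeSymbol(B)), universe)
    shared <- intersect(A, B)
    pRaw <- hypergeometricTail(length(shared), length(A), length(B),
                               length(universe))
    res <- data.frame(label = label, k = length(shared),
                      sizeA = length(A), sizeB = length(B),
                      N = length(universe), pRaw = pRaw,
                      pAdj = bonferroniAdjust(pRaw, m), m = as.integer(m),
                      stringsAsFactors = FALSE)
    res$genes <- list(sort(shared))
    res
}
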