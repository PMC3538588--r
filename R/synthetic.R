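#' Deterministic synthetic gene universe
#'
#' @param nGenes number of genes (>= 1).
#' @return character vector of symbols \code{G000001 ...}; collision-free
#'   and identical across calls.
#' @export
generateUniverse <- function(nGenes) {
    if (length(nGenes) != 1L || is.na(nGenes) || nGenes < 1)
        stop("nGenes must be >= 1")
    sprintf("G%06d", seq_len(nGenes))
}

#' Synthetic interaction network
#'
#' Generates a simple undirected graph over the universe with exactly
#' \code{nEdges} edges. The \code{preferential_attachment} model draws
#' edges with power-law node fitness (heavy-tailed degrees, emulating a
#' curated interactome); \code{uniform} draws Erdos-Renyi edges.
#'
#' @param universe character vector of gene symbols.
#' @param nEdges requested edge count.
#' @param model \code{"preferential_attachment"} or \code{"uniform"}.
#' @param seed integer seed.
#' @param kindFractions named numeric, proportions of edge kinds
#'   (default 80\% physical / 20\% genetic).
#' @return an \linkS4class{InteractionNetwork}.
#' @export
generateNetwork <- function(universe, nEdges,
                            model = c("preferential_attachment",
                                      "uniform"),
                            seed = 1L,
                            kindFractions = c(physical = 0.8,
                                              genetic = 0.2)) {
    model <- match.arg(model)
    n <- length(universe)
    if (nEdges < 1) stop("nEdges must be >= 1")
    if (nEdges > n * (n - 1) / 2)
        stop("nEdges exceeds simple-graph capacity")
    set.seed(seed)
    g <- if (model == "uniform") {
        igraph::sample_gnm(n, nEdges)
    } else {
        fitness <- (seq_len(n))^(-0.9)  # Zipf-like node fitness
        igraph::sample_fitness(nEdges, fitness, loops = FALSE,
                               multiple = FALSE)
    }
    # fitness sampling may fall short of the requested count after dedup;
    # top up with uniform retries
    el <- igraph::as_edgelist(g)
    edges <- unique(data.frame(from = pmin(el[, 1], el[, 2]),
                               to = pmax(el[, 1], el[, 2])))
    while (nrow(edges) < nEdges) {
        extra <- cbind(sample.int(n, nEdges - nrow(edges), replace = TRUE),
                       sample.int(n, nEdges - nrow(edges), replace = TRUE))
        extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
        edges <- unique(rbind(edges,
                              data.frame(from = pmin(extra[, 1],
                                                     extra[, 2]),
                                         to = pmax(extra[, 1],
                                                   extra[, 2]))))
    }
    edges <- edges[seq_len(nEdges), , drop = FALSE]
    kinds <- sample(names(kindFractions), nEdges, replace = TRUE,
                    prob = kindFractions)
    InteractionNetwork(data.frame(from = universe[edges$from],
                                  to = universe[edges$to], kind = kinds),
                       quiet = TRUE)
}

#' Synthetic pathway collection
#'
#' Draws \code{nPathways} gene sets with sizes uniform in
#' \code{sizeRange}. A fraction \code{overlapFraction} of each pathway
#' (after the first) is sampled from genes already used by earlier
#' pathways, so pairwise overlaps are controlled; 0 gives pairwise
#' disjoint pathways.
#'
#' @param universe character vector of gene symbols.
#' @param nPathways number of pathways.
#' @param sizeRange length-2 integer range of pathway sizes.
#' @param overlapFraction fraction in [0, 1] of members drawn from
#'   previously used genes.
#' @param seed integer seed.
#' @return a \linkS4class{PathwayCollection} with names \code{PW001 ...}
#' @export
generatePathways <- function(universe, nPathways = 66L,
                             sizeRange = c(10L, 60L),
                             overlapFraction = 0.1, seed = 1L) {
    stopifnot(nPathways >= 1, overlapFraction >= 0, overlapFraction <= 1)
    if (max(sizeRange) > length(universe))
        stop("pathway sizes infeasible within universe")
    if (overlapFraction == 0 &&
        nPathways * max(sizeRange) > length(universe))
        stop("disjoint pathways of this size exceed the universe")
    set.seed(seed)
    used <- character()
    sets <- vector("list", nPathways)
    free <- universe
    for (i in seq_len(nPathways)) {
        size <- sample(seq(sizeRange[1L], sizeRange[2L]), 1L)
        nOld <- if (i == 1L) 0L else
            min(round(size * overlapFraction), length(used))
        old <- if (nOld > 0L) sample(used, nOld) else character()
        pool <- if (overlapFraction == 0) free else setdiff(universe, used)
        nNew <- size - length(old)
        if (nNew > length(pool))
            stop("universe exhausted; pathway configuration infeasible")
        newg <- sample(pool, nNew)
        sets[[i]] <- sort(c(old, newg))
        used <- union(used, sets[[i]])
        free <- setdiff(free, sets[[i]])
    }
    names(sets) <- sprintf("PW%03d", seq_len(nPathways))
    PathwayCollection(sets)
}

#' Default planted-signal parameters
#'
#' The study conditions emulated by the generator: a universe of 5000
#' genes (about one third of a curated human interactome), 90 seed genes
#' of which 30\% come from the causal pathway, seed-neighborhood
#' enrichment factor 5 for causal-pathway genes, log2 effect size 1.5
#' with replicate noise sd 0.5, differential-expression probability 0.3
#' for interactome genes against a 0.02 background rate, 3 biological x 4
#' technical replicates per group, and 4 tissue-by-gender conditions.
#'
#' @return named list of generator parameters.
#' @export
syntheticDefaults <- function() {
    list(nGenes = 5000L, nEdges = 22000L, nPathways = 66L,
         sizeRange = c(10L, 60L), overlapFraction = 0.1,
         nSeeds = 90L, causalFraction = 0.3, enrichmentFactor = 5,
         gwasCutoff = 1e-5, nDrugs = 6L, drugSizeRange = c(20L, 170L),
         drugInteractomeWeight = 4, delta = 1.5, sigma = 0.5,
         piInteractome = 0.3, piBackground = 0.02, mu0 = 8, sigmaBase = 1,
         nBioreps = 3L, nTechreps = 4L,
         conditions = c("female_visceral_adipose",
                        "male_visceral_adipose",
                        "female_subcutaneous_adipose",
                        "male_skeletal_muscle"))
}

#' Generate a complete synthetic bundle with a planted convergent signal
#'
#' Builds an internally consistent input bundle in which one causal
#' pathway carries a convergent signal through every stage: (a) seed
#' genes over-sample the causal pathway and receive association p-values
#' log-uniform below the cutoff; (b) the network is augmented so
#' causal-pathway genes are adjacent to seeds at the configured
#' enrichment factor over the baseline adjacency rate; (c) drug gene
#' lists over-sample the seed neighborhood; (d) per-condition expression
#' matrices shift interactome genes by +/- delta (equal probability, so
#' up and down calls are both produced) with probability piInteractome,
#' background genes with probability piBackground, plus replicate noise.
#' All parameters are recorded verbatim in the truth slot. Setting
#' \code{delta = 0, piInteractome = piBackground = 0, enrichmentFactor =
#' 1, causalFraction = 0} yields a null bundle for calibration.
#'
#' @param params list as from \code{\link{syntheticDefaults}}; entries
#'   may be overridden.
#' @param seed master integer seed; the bundle is a deterministic
#'   function of (params, seed).
#' @return a \linkS4class{SyntheticBundle}.
#' @export
plantConvergentSignal <- function(params = syntheticDefaults(),
                                  seed = 1L) {
    p <- utils::modifyList(syntheticDefaults(), params)
    universe <- generateUniverse(p$nGenes)
    network <- generateNetwork(universe, p$nEdges, seed = seed)
    pathways <- generatePathways(universe, p$nPathways, p$sizeRange,
                                 p$overlapFraction, seed = seed + 1L)

    set.seed(seed + 2L)
    # causal pathway: the largest, so seed fraction f is feasible
    sizes <- vapply(pathways@sets, length, 0L)
    causal <- names(sizes)[which.max(sizes)]
    causalGenes <- members(pathways, causal)
    nCausalSeeds <- round(p$nSeeds * p$causalFraction)
    if (nCausalSeeds > length(causalGenes))
        stop("causal pathway too small for requested seed fraction")
    seeds <- c(sample(causalGenes, nCausalSeeds),
               sample(setdiff(universe, causalGenes),
                      p$nSeeds - nCausalSeeds))
    # association p-values are cosmetic: log-uniform below the cutoff
    assocP <- 10^stats::runif(p$nSeeds, -12, log10(p$gwasCutoff))
    association <- data.frame(gene = seeds, p = assocP,
                              stringsAsFactors = FALSE)

    # (b) rewire: causal genes adjacent to seeds at factor x baseline
    edges <- networkEdges(network)
    adjacentToSeed <- function(e) {
        unique(c(e$to[e$from %in% seeds], e$from[e$to %in% seeds]))
    }
    adj <- adjacentToSeed(edges)
    nonCausalBg <- setdiff(universe, union(causalGenes, seeds))
    baseline <- length(intersect(adj, nonCausalBg)) / length(nonCausalBg)
    targetRate <- min(1, p$enrichmentFactor * baseline)
    pool <- setdiff(causalGenes, seeds)
    current <- intersect(pool, adj)
    targetCount <- round(targetRate * length(pool))
    extra <- NULL
    if (p$enrichmentFactor > 1 && targetCount > length(current)) {
        toWire <- sample(setdiff(pool, current),
                         targetCount - length(current))
        extra <- data.frame(from = toWire,
                            to = sample(seeds, length(toWire),
                                        replace = TRUE),
                            kind = "physical")
    }
    if (!is.null(extra))
        network <- InteractionNetwork(rbind(edges, extra), quiet = TRUE)

    # interactome as the analysis will see it (seeds + one hop)
    interactome <- interactomeGenes(
        firstNeighborExpand(seeds, network, includeSeeds = TRUE))

    # (c) drug-gene lists over-sampling the seed neighborhood
    w <- ifelse(universe %in% interactome, p$drugInteractomeWeight, 1)
    drugs <- list()
    for (i in seq_len(p$nDrugs)) {
        sz <- sample(seq(p$drugSizeRange[1L], p$drugSizeRange[2L]), 1L)
        drugs[[sprintf("drug%02d", i)]] <-
            sort(sample(universe, sz, prob = w))
    }

    # (d) expression matrices per condition; the DE program (which genes
    # shift, and in which direction) is one disease signature shared by
    # all conditions - replicate noise is independent per condition
    isDE <- stats::runif(p$nGenes) <
        ifelse(universe %in% interactome, p$piInteractome,
               p$piBackground)
    effect <- ifelse(isDE, sample(c(-1, 1), p$nGenes,
                                  replace = TRUE) * p$delta, 0)
    expression <- list()
    for (cond in p$conditions) {
        nSamp <- 2L * p$nBioreps * p$nTechreps
        groups <- rep(c("case", "control"),
                      each = p$nBioreps * p$nTechreps)
        bioreps <- rep(rep(seq_len(p$nBioreps), each = p$nTechreps), 2L)
        techreps <- rep(seq_len(p$nTechreps), 2L * p$nBioreps)
        sampleIds <- paste(cond, groups, bioreps, techreps, sep = "_")
        base <- stats::rnorm(p$nGenes, p$mu0, p$sigmaBase)
        mat <- matrix(stats::rnorm(p$nGenes * nSamp, 0, p$sigma),
                      nrow = p$nGenes, ncol = nSamp,
                      dimnames = list(universe, sampleIds))
        mat <- mat + base
        mat[, groups == "case"] <- mat[, groups == "case"] + effect
        meta <- data.frame(sample = sampleIds, group = groups,
                           biorep = as.character(bioreps),
                           techrep = as.character(techreps),
                           stringsAsFactors = FALSE)
        expression[[cond]] <- makeExpressionSet(mat, meta,
                                                log2Scale = TRUE)
    }

    truth <- c(p[c("nGenes", "nEdges", "nPathways", "nSeeds",
                   "causalFraction", "enrichmentFactor", "delta",
                   "sigma", "piInteractome", "piBackground", "nBioreps",
                   "nTechreps")],
               list(causalPathway = causal, seeds = sort(seeds),
                    masterSeed = seed,
                    realizedBaselineAdjacency = baseline,
                    targetAdjacencyRate = targetRate))
    new("SyntheticBundle", association = association, network = network,
        pathways = pathways, drugs = drugs, expression = expression,
        truth = truth)
}

#' Write a SyntheticBundle to standard-format files
#'
#' Emits the association TSV, edge-list TSV, GMT, drug-gene TSV,
#' per-condition expression + metadata TSVs, and a \code{truth.json},
#' all readable back by the package readers.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    stopifnot(is(bundle, "SyntheticBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeAssociationTable(bundle@association,
                          file.path(dir, "association.tsv"))
    writeEdgeList(bundle@network, file.path(dir, "network.tsv"))
    writeGmt(bundle@pathways, file.path(dir, "pathways.gmt"))
    writeDrugGeneTable(bundle@drugs, file.path(dir, "drug_genes.tsv"))
    for (cond in names(bundle@expression))
        writeExpression(bundle@expression[[cond]],
                        file.path(dir, paste0("expr_", cond, ".tsv")),
                        file.path(dir, paste0("meta_", cond, ".tsv")))
    jsonlite::write_json(bundle@truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Synthetic GWAS-catalog extract with a known threshold profile
#'
#' Builds an association table emulating a catalog "reported genes"
#' extract whose composition is fixed by construction: \code{counts[1]}
#' genes with best p-value in each successive significance decade
#' starting at \code{10^-8} (the default profile 46/16/9/22 yields
#' cumulative counts 46, 62, 71 and 93 at cutoffs 1e-8 ... 1e-5). The
#' table carries per-SNP duplicate rows and a few multi-gene entries so
#' the reader's collapse and split rules are exercised. This is a
#' synthetic stand-in, not the published supplement.
#'
#' @param counts integer vector: new genes entering per decade from
#'   1e-8 upward.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{p} (pre-split,
#'   pre-collapse: write with \code{\link{writeAssociationTable}} and
#'   read back with \code{\link{readAssociationTable}}).
#' @export
syntheticGwasCatalog <- function(counts = c(46L, 16L, 9L, 22L),
                                 seed = 7L) {
    set.seed(seed)
    nGenes <- sum(counts)
    genes <- sprintf("T2DG%03d", seq_len(nGenes))
    lo <- c(-12, -8, -7, -6)   # decade lower bounds (log10 best p)
    hi <- c(-8, -7, -6, -5)
    band <- rep(seq_along(counts), counts)
    bestP <- 10^stats::runif(nGenes, lo[band], hi[band])
    # clamp away from decade boundaries so thresholds are unambiguous
    rows <- data.frame(gene = genes, p = bestP, stringsAsFactors = FALSE)
    # per-SNP duplicates: weaker extra records for a third of the genes
    dup <- sample(nGenes, floor(nGenes / 3))
    rows <- rbind(rows, data.frame(gene = genes[dup],
                                   p = pmin(1, bestP[dup] * 10^
                                        stats::runif(length(dup), 1, 3))))
    # multi-gene intergenic entries pairing existing genes; p above the
    # loosest cutoff so the genes' best records are untouched
    pair <- matrix(sample(genes, 6L), ncol = 2L)
    rows <- rbind(rows, data.frame(
        gene = paste(pair[, 1], "-", pair[, 2]),
        p = 10^stats::runif(3L, -4, -3)))
    rows[sample(nrow(rows)), , drop = FALSE]
}
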