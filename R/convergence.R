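#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the convergence pipeline. Defaults
#' follow the conventional analysis settings: association cutoff 1e-5,
#' Diff-score call threshold 13 (p = 0.05), enrichment alpha 0.05 on
#' unadjusted p for common-pathway membership, minimum drug overlap 5.
#'
#' @param gwasCutoff association p-value cutoff for seed genes.
#' @param deThreshold absolute Diff-score call threshold.
#' @param deAdjust \code{"none"} or \code{"bh"} for the DE calls; the
#'   unadjusted transcriptome is the default convergence input.
#' @param enrichmentAlpha significance level for common-pathway
#'   membership.
#' @param enrichmentOn \code{"raw"} or \code{"adjusted"}: which p-value
#'   decides common-pathway membership.
#' @param enrichmentMethod method for pathway enrichment
#'   (\code{"ease"}, \code{"fisher"}, \code{"hypergeometric"}).
#' @param enrichmentCorrection correction for pathway enrichment.
#' @param minDrugOverlap minimum shared genes for a drug to enter the
#'   screen.
#' @param includeSeeds whether the interactome includes the seeds.
#' @param edgeKinds edge kinds traversed in expansion.
#' @param seed integer seed governing any stochastic stage.
#' @return a named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(gwasCutoff = 1e-5, deThreshold = 13,
                           deAdjust = "none", enrichmentAlpha = 0.05,
                           enrichmentOn = c("raw", "adjusted"),
                           enrichmentMethod = "ease",
                           enrichmentCorrection = "bh",
                           minDrugOverlap = 5L, includeSeeds = TRUE,
                           edgeKinds = c("physical", "genetic",
                                         "unspecified"),
                           seed = 1L) {
    enrichmentOn <- match.arg(enrichmentOn)
    stopifnot(gwasCutoff > 0, gwasCutoff <= 1,
              enrichmentAlpha > 0, enrichmentAlpha <= 1,
              minDrugOverlap >= 1)
    structure(list(gwasCutoff = gwasCutoff, deThreshold = deThreshold,
                   deAdjust = deAdjust,
                   enrichmentAlpha = enrichmentAlpha,
                   enrichmentOn = enrichmentOn,
                   enrichmentMethod = enrichmentMethod,
                   enrichmentCorrection = enrichmentCorrection,
                   minDrugOverlap = as.integer(minDrugOverlap),
                   includeSeeds = includeSeeds, edgeKinds = edgeKinds,
                   seed = as.integer(seed)),
              class = "pipelineConfig")
}

#' Screen drug-gene sets for overlap with a target gene set
#'
#' Drugs sharing fewer than \code{minOverlap} genes with the target are
#' excluded before testing (and do not count toward the Bonferroni
#' family); each retained drug's gene set is tested for overlap with the
#' target by the hypergeometric upper tail, Bonferroni-adjusted for the
#' number of retained drugs.
#'
#' @param drugs named list: drug -> character vector of genes.
#' @param target character vector (e.g. the interactome).
#' @param universe background gene set (e.g. all network nodes).
#' @param minOverlap minimum shared-gene count to retain a drug.
#' @return data.frame of overlap results sorted by pAdj, then pRaw, then
#'   drug name; zero rows if no drug is retained.
#' @export
drugOverlapScreen <- function(drugs, target, universe, minOverlap = 5L) {
    if (minOverlap < 1) stop("minOverlap must be >= 1")
    universe <- unique(canonicalizeSymbol(universe))
    target <- intersect(unique(canonicalizeSymbol(target)), universe)
    sets <- lapply(drugs, function(g)
        intersect(unique(canonicalizeSymbol(g)), universe))
    k <- vapply(sets, function(g) length(intersect(g, target)), 0L)
    keep <- k >= minOverlap
    sets <- sets[keep]
    if (length(sets) == 0L) {
        out <- data.frame(label = character(), k = integer(),
                          sizeA = integer(), sizeB = integer(),
                          N = integer(), pRaw = numeric(),
                          pAdj = numeric(), m = integer())
        out$genes <- list()
        return(out)
    }
    m <- length(sets)
    res <- do.call(rbind, lapply(names(sets), function(d)
        overlapTest(sets[[d]], target, universe, m = m, label = d)))
    res <- res[order(res$pAdj, res$pRaw, res$label), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Intersect an interactome with a condition transcriptome and test it
#'
#' Computes the commonality set (interactome intersect transcriptome) and
#' its hypergeometric overlap significance within the universe,
#' Bonferroni-adjusted for the number of conditions analyzed together.
#'
#' @param interactome,transcriptome character vectors.
#' @param universe background gene set (network node set by default
#'   policy).
#' @param m number of simultaneous condition comparisons.
#' @param label condition label.
#' @return list with elements \code{intersection} (character) and
#'   \code{overlap} (one-row data.frame).
#' @export
intersectAndTest <- function(interactome, transcriptome, universe,
                             m = 1L, label = "condition") {
    ov <- overlapTest(interactome, transcriptome, universe, m = m,
                      label = label)
    list(intersection = ov$genes[[1L]], overlap = ov)
}

#' Pathways enriched in every condition
#'
#' Given per-condition enrichment tables, returns the pathways whose
#' selected p-value (raw or adjusted) is at or below alpha in every
#' condition, ordered by the worst (maximum) selected p across
#' conditions. With membership on the adjusted p the result is always a
#' subset of the raw-p result at the same alpha.
#'
#' @param perCondition named list of enrichment data.frames (from
#'   \code{\link{pathwayEnrichment}}; columns pathway, pRaw, pAdj).
#' @param alpha significance level for membership.
#' @param on \code{"raw"} or \code{"adjusted"}.
#' @return data.frame: pathway, worstP, plus one selected-p column per
#'   condition; zero rows if any condition has no significant pathway.
#' @export
commonPathways <- function(perCondition, alpha = 0.05,
                           on = c("raw", "adjusted")) {
    on <- match.arg(on)
    stopifnot(length(perCondition) >= 1L)
    col <- if (on == "raw") "pRaw" else "pAdj"
    sig <- lapply(perCondition, function(d)
        stats::setNames(d[[col]], d$pathway)[d[[col]] <= alpha])
    common <- Reduce(intersect, lapply(sig, names))
    if (length(common) == 0L) {
        out <- data.frame(pathway = character(), worstP = numeric())
        for (nm in names(perCondition)) out[[nm]] <- numeric()
        return(out)
    }
    pmatrix <- vapply(sig, function(s) s[common], numeric(length(common)))
    if (length(common) == 1L)
        pmatrix <- matrix(pmatrix, nrow = 1L,
                          dimnames = list(common, names(sig)))
    worst <- apply(pmatrix, 1L, max)
    ord <- order(worst, common)
    out <- data.frame(pathway = common[ord], worstP = worst[ord],
                      stringsAsFactors = FALSE, row.names = NULL)
    for (nm in colnames(pmatrix)) out[[nm]] <- pmatrix[ord, nm]
    out
}

#' Leave-pathway-out ablation of an intersection gene set
#'
#' Removes one pathway's genes from the intersection set, re-runs pathway
#' enrichment on the remainder, and quantifies the pathway's contribution
#' to the convergent signal. The impact metric is the sum of
#' log10(pAfter / pBefore) over pathways significant before ablation
#' (selected p at or below alpha), plus the count of significance flips;
#' it is a package-defined metric. The ablated pathway's own
#' post-ablation overlap is k = 0 and its raw p exactly 1.
#'
#' @param intersection character vector of commonality genes.
#' @param pathway character vector: the genes to remove.
#' @param pathways a \linkS4class{PathwayCollection} for the re-run.
#' @param universe enrichment background.
#' @param method,correction passed to \code{\link{pathwayEnrichment}}.
#' @param alpha significance level used by the impact metric.
#' @param on \code{"raw"} or \code{"adjusted"} p for the impact metric.
#' @return list: removed (genes actually removed), remainingCount,
#'   before, after (enrichment tables), impact (data.frame pathway,
#'   pBefore, pAfter, log10Ratio, flipped), impactScore (number),
#'   flips (count).
#' @export
ablatePathway <- function(intersection, pathway, pathways, universe,
                          method = "ease", correction = "bh",
                          alpha = 0.05, on = c("adjusted", "raw")) {
    on <- match.arg(on)
    intersection <- unique(canonicalizeSymbol(intersection))
    pathway <- unique(canonicalizeSymbol(pathway))
    removed <- sort(intersect(intersection, pathway))
    remaining <- sort(setdiff(intersection, pathway))
    before <- pathwayEnrichment(intersection, pathways, universe,
                                method = method, correction = correction,
                                quiet = TRUE)
    after <- pathwayEnrichment(remaining, pathways, universe,
                               method = method, correction = correction,
                               quiet = TRUE)
    col <- if (on == "raw") "pRaw" else "pAdj"
    pb <- stats::setNames(before[[col]], before$pathway)
    pa <- stats::setNames(after[[col]], after$pathway)
    # pathways may drop out entirely when the query empties: treat as p=1
    allp <- names(pb)
    paFull <- ifelse(allp %in% names(pa), pa[allp], 1)
    sigBefore <- allp[pb[allp] <= alpha]
    impact <- data.frame(pathway = sigBefore,
                         pBefore = pb[sigBefore],
                         pAfter = paFull[match(sigBefore, allp)],
                         stringsAsFactors = FALSE, row.names = NULL)
    impact$log10Ratio <- log10(impact$pAfter / impact$pBefore)
    impact$flipped <- impact$pAfter > alpha
    list(removed = removed, remainingCount = length(remaining),
         before = before, after = after, impact = impact,
         impactScore = sum(impact$log10Ratio), flips = sum(impact$flipped))
}

#' @describeIn runPipeline run on an in-memory input list with elements
#'   \code{association} (data.frame gene/p), \code{network}
#'   (\linkS4class{InteractionNetwork}), \code{pathways}
#'   (\linkS4class{PathwayCollection}), \code{drugs} (named list),
#'   \code{expression} (named list of \code{SummarizedExperiment}),
#'   and optionally \code{truth}.
#' @export
setMethod("runPipeline", "list", function(inputs, config) {
    stopifnot(inherits(config, "pipelineConfig"))
    need <- c("association", "network", "pathways", "drugs", "expression")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
        stop("pipeline inputs missing: ", paste(miss, collapse = ", "))
    net <- inputs$network
    pc <- inputs$pathways
    netUniverse <- networkNodes(net)
    pwUniverse <- geneUniverse(pc)

    seeds <- thresholdGenes(inputs$association, config$gwasCutoff)
    expansion <- firstNeighborExpand(seeds, net,
                                     includeSeeds = config$includeSeeds,
                                     kinds = config$edgeKinds)
    interactome <- interactomeGenes(expansion)

    interEnrich <- pathwayEnrichment(interactome, pc, pwUniverse,
                                     method = config$enrichmentMethod,
                                     correction =
                                         config$enrichmentCorrection,
                                     quiet = TRUE)
    drugScreen <- drugOverlapScreen(inputs$drugs, interactome,
                                    netUniverse,
                                    minOverlap = config$minDrugOverlap)

    nCond <- length(inputs$expression)
    conditions <- list()
    for (cond in names(inputs$expression)) {
        de <- callDE(inputs$expression[[cond]],
                     threshold = config$deThreshold,
                     adjust = config$deAdjust, condition = cond)
        transcriptome <- calledGenes(de)
        it <- intersectAndTest(interactome, transcriptome, netUniverse,
                               m = max(nCond, 1L), label = cond)
        enr <- pathwayEnrichment(it$intersection, pc, pwUniverse,
                                 method = config$enrichmentMethod,
                                 correction = config$enrichmentCorrection,
                                 quiet = TRUE)
        conditions[[cond]] <- list(de = de, transcriptome = transcriptome,
                                   intersection = it$intersection,
                                   overlap = it$overlap,
                                   enrichment = enr)
    }

    common <- commonPathways(lapply(conditions, `[[`, "enrichment"),
                             alpha = config$enrichmentAlpha,
                             on = config$enrichmentOn)

    # rank candidate convergent pathways by total ablation impact
    ablRows <- list()
    for (pw in common$pathway) {
        score <- 0; flips <- 0L; remaining <- integer()
        for (cond in names(conditions)) {
            ab <- ablatePathway(conditions[[cond]]$intersection,
                                members(pc, pw), pc, pwUniverse,
                                method = config$enrichmentMethod,
                                correction = config$enrichmentCorrection,
                                alpha = config$enrichmentAlpha,
                                on = if (config$enrichmentOn == "raw")
                                    "raw" else "adjusted")
            score <- score + ab$impactScore
            flips <- flips + ab$flips
            remaining[cond] <- ab$remainingCount
        }
        ablRows[[pw]] <- data.frame(pathway = pw, impactScore = score,
                                    flips = flips,
                                    stringsAsFactors = FALSE)
    }
    ablation <- if (length(ablRows)) {
        a <- do.call(rbind, ablRows)
        a <- a[order(-a$impactScore, -a$flips, a$pathway), , drop = FALSE]
        rownames(a) <- NULL
        a
    } else data.frame(pathway = character(), impactScore = numeric(),
                      flips = integer())

    truth <- if (!is.null(inputs$truth)) inputs$truth else list()
    new("ConvergenceReport", config = unclass(config), seeds = seeds,
        expansion = expansion, interactomeEnrichment = interEnrich,
        drugScreen = drugScreen, conditions = conditions,
        commonPathways = common, ablation = ablation, truth = truth)
})

#' @describeIn runPipeline run directly on a
#'   \linkS4class{SyntheticBundle}; the planted truth is carried into the
#'   report.
#' @export
setMethod("runPipeline", "SyntheticBundle", function(inputs, config) {
    runPipeline(list(association = inputs@association,
                     network = inputs@network,
                     pathways = inputs@pathways, drugs = inputs@drugs,
                     expression = inputs@expression,
                     truth = inputs@truth), config)
})

#' Serialize a ConvergenceReport to JSON
#'
#' Writes a deterministic JSON document: all gene sets sorted, every
#' count recomputable from its serialized member sets. Re-running the
#' pipeline with the same seed and config yields byte-identical output.
#'
#' @param report a \linkS4class{ConvergenceReport}.
#' @param path output path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
reportToJson <- function(report, path = NULL) {
    stopifnot(is(report, "ConvergenceReport"))
    stripGenes <- function(d) d[setdiff(names(d), "genes")]
    conds <- lapply(report@conditions, function(cnd) list(
        transcriptome = cnd$transcriptome,
        intersection = cnd$intersection,
        overlap = stripGenes(cnd$overlap),
        enrichment = stripGenes(cnd$enrichment)))
    obj <- list(
        config = report@config,
        seeds = report@seeds,
        interactome = report@expansion@interactome,
        missingSeeds = report@expansion@missingSeeds,
        interactomeEnrichment = stripGenes(report@interactomeEnrichment),
        drugScreen = stripGenes(report@drugScreen),
        conditions = conds,
        commonPathways = report@commonPathways,
        ablation = report@ablation,
        truth = report@truth)
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, dataframe = "columns")
    if (!is.null(path)) {
        writeLines(json, path)
        return(invisible(as.character(json)))
    }
    as.character(json)
}
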