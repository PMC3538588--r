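#' @import methods
#' @importFrom stats phyper p.adjust pt rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

#' PathwayCollection: named gene sets
#'
#' A collection of named pathways (gene sets), the currency of every
#' enrichment stage. Gene symbols are canonical (uppercase, trimmed);
#' pathway names are unique and no pathway is empty.
#'
#' @slot sets named list of character vectors of canonical gene symbols.
#' @export
setClass("PathwayCollection", representation(sets = "list"))

setValidity("PathwayCollection", function(object) {
    s <- object@sets
    if (length(s) == 0L) return(TRUE)
    nm <- names(s)
    if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
        return("every pathway must be named")
    if (anyDuplicated(nm)) return("pathway names must be unique")
    if (any(vapply(s, length, 0L) == 0L)) return("empty pathway not allowed")
    if (any(vapply(s, anyDuplicated, 0L) > 0L))
        return("pathway members must be unique")
    TRUE
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors; symbols are canonicalized
#'   and deduplicated.
#' @return a \linkS4class{PathwayCollection}.
#' @examples
#' pc <- PathwayCollection(list(TGF_BETA = c("smad3", "CDKN2B")))
#' pathwayNames(pc)
#' @export
PathwayCollection <- function(sets = list()) {
    sets <- lapply(sets, function(g) unique(canonicalizeSymbol(g)))
    new("PathwayCollection", sets = sets)
}

#' InteractionNetwork: undirected simple graph over gene symbols
#'
#' Edges are unordered symbol pairs tagged with an interaction kind
#' (\code{physical}, \code{genetic} or \code{unspecified}); at most one
#' edge per pair per kind, no self-loops. The node universe is exactly
#' the set of symbols appearing in at least one edge (interactors),
#' unless an explicit universe is supplied.
#'
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{kind};
#'   \code{from < to} lexicographically.
#' @slot nodes character vector of node symbols.
#' @export
setClass("InteractionNetwork",
         representation(edges = "data.frame", nodes = "character"))

setValidity("InteractionNetwork", function(object) {
    e <- object@edges
    if (!all(c("from", "to", "kind") %in% names(e)))
        return("edges must have columns from, to, kind")
    if (nrow(e)) {
        if (any(e$from == e$to)) return("self-loops not allowed")
        if (any(e$from > e$to)) return("edges must be stored with from < to")
        if (anyDuplicated(e[c("from", "to", "kind")]))
            return("duplicate edge (same pair, same kind)")
        if (!all(e$kind %in% c("physical", "genetic", "unspecified")))
            return("kind must be physical, genetic or unspecified")
        if (!all(c(e$from, e$to) %in% object@nodes))
            return("edges reference symbols outside the node set")
    }
    TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' Symbols are canonicalized, self-loops dropped (with a message giving
#' the count), unordered duplicates within a kind collapsed.
#'
#' @param edges data.frame with two symbol columns and an optional third
#'   kind column.
#' @param nodes optional explicit node universe overriding the default
#'   (symbols on >= 1 edge).
#' @param quiet suppress drop-count messages.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges = data.frame(from = character(),
                                                  to = character(),
                                                  kind = character()),
                               nodes = NULL, quiet = FALSE) {
    stopifnot(ncol(edges) >= 2L)
    from <- canonicalizeSymbol(as.character(edges[[1L]]))
    to <- canonicalizeSymbol(as.character(edges[[2L]]))
    kind <- if (ncol(edges) >= 3L) as.character(edges[[3L]]) else
        rep("unspecified", length(from))
    kind[is.na(kind) | kind == ""] <- "unspecified"
    bad <- !kind %in% c("physical", "genetic", "unspecified")
    if (any(bad)) stop("unknown interaction kind: ",
                       paste(unique(kind[bad]), collapse = ", "))
    loops <- from == to
    if (any(loops) && !quiet)
        message("dropped ", sum(loops), " self-loop(s)")
    from2 <- pmin(from[!loops], to[!loops])
    to2 <- pmax(from[!loops], to[!loops])
    e <- data.frame(from = from2, to = to2, kind = kind[!loops],
                    stringsAsFactors = FALSE)
    ndup <- anyDuplicated(e)
    if (ndup && !quiet)
        message("collapsed ", nrow(e) - nrow(unique(e)), " duplicate edge(s)")
    e <- unique(e)
    e <- e[order(e$from, e$to, e$kind), , drop = FALSE]
    rownames(e) <- NULL
    nds <- if (is.null(nodes)) sort(unique(c(e$from, e$to)))
           else sort(unique(canonicalizeSymbol(nodes)))
    new("InteractionNetwork", edges = e, nodes = nds)
}

#' ExpansionResult: one-hop neighborhood of a seed set
#'
#' @slot seedsUsed seeds present in the network.
#' @slot missingSeeds seeds absent from the network (reported, not fatal).
#' @slot interactome the expanded gene set.
#' @slot neighborCounts named integer, direct-neighbor count per used seed.
#' @slot includeSeeds whether seeds themselves were included.
#' @export
setClass("ExpansionResult",
         representation(seedsUsed = "character", missingSeeds = "character",
                        interactome = "character",
                        neighborCounts = "integer", includeSeeds = "logical"))

#' DECallSet: differential-expression calls for one condition
#'
#' @slot condition condition label (e.g. tissue x gender).
#' @slot threshold absolute Diff-score call threshold (score units).
#' @slot adjusted whether scores were computed from BH-adjusted p-values.
#' @slot table per-gene data.frame (gene, meanCase, meanControl, pRaw,
#'   pUsed, diffScore, direction).
#' @slot up,down called gene sets; disjoint by construction.
#' @export
setClass("DECallSet",
         representation(condition = "character", threshold = "numeric",
                        adjusted = "logical", table = "data.frame",
                        up = "character", down = "character"))

setValidity("DECallSet", function(object) {
    if (length(intersect(object@up, object@down)))
        return("up and down calls must be disjoint")
    TRUE
})

#' SyntheticBundle: a complete synthetic input bundle with recorded truth
#'
#' @slot association data.frame (gene, p) emulating a GWAS-catalog extract.
#' @slot network \linkS4class{InteractionNetwork}.
#' @slot pathways \linkS4class{PathwayCollection}.
#' @slot drugs named list of character vectors (drug -> gene set).
#' @slot expression named list of \code{SummarizedExperiment}, one per
#'   condition.
#' @slot truth list of the planted-signal parameters, recorded verbatim.
#' @export
setClass("SyntheticBundle",
         representation(association = "data.frame",
                        network = "InteractionNetwork",
                        pathways = "PathwayCollection",
                        drugs = "list", expression = "list", truth = "list"))

#' ConvergenceReport: full pipeline output
#'
#' @slot config configuration echo.
#' @slot seeds seed gene set ("disease genome").
#' @slot expansion \linkS4class{ExpansionResult} ("disease interactome").
#' @slot interactomeEnrichment pathway enrichment of the interactome.
#' @slot drugScreen drug-overlap screen results.
#' @slot conditions named list; per condition: transcriptome, intersection,
#'   overlap test row, enrichment table.
#' @slot commonPathways data.frame of cross-condition common pathways.
#' @slot ablation data.frame of per-pathway ablation impacts, ranked.
#' @slot truth planted-truth linkage when inputs were synthetic (else empty).
#' @export
setClass("ConvergenceReport",
         representation(config = "list", seeds = "character",
                        expansion = "ExpansionResult",
                        interactomeEnrichment = "data.frame",
                        drugScreen = "data.frame", conditions = "list",
                        commonPathways = "data.frame",
                        ablation = "data.frame", truth = "list"))
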