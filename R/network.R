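#' Seed genes passing an association p-value cutoff
#'
#' Collapses per-SNP/per-study duplicate rows to the best (minimum)
#' p-value per gene, then returns the unique genes whose best p-value is
#' at or below the cutoff (inclusive comparison: catalog p-values rarely
#' sit exactly on a boundary, and a gene reported by several records
#' passes if any record does). At the conventional catalog cutoff of
#' 1e-5 this is the "disease genome" seed set.
#'
#' @param table data.frame with columns \code{gene}, \code{p} (as read by
#'   \code{\link{readAssociationTable}}).
#' @param cutoff p-value cutoff in (0, 1].
#' @return sorted character vector of seed genes.
#' @export
thresholdGenes <- function(table, cutoff = 1e-5) {
    stopifnot(all(c("gene", "p") %in% names(table)))
    if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
    if (nrow(table) == 0L) return(character())
    if (any(table$p <= 0 | table$p > 1))
        stop("association p-values must lie in (0, 1]")
    best <- tapply(table$p, canonicalizeSymbol(table$gene), min)
    sort(names(best)[best <= cutoff])
}

#' One-hop (first-neighbor) expansion of a seed set
#'
#' Expands a seed gene set into its direct interaction neighborhood: the
#' union of all genes adjacent to at least one seed, optionally together
#' with the seeds themselves. Strictly one hop - no transitive closure.
#' Both physical and genetic edges are traversed by default; an edge-kind
#' filter is available. Seeds absent from the network are reported in the
#' result, never silently dropped.
#'
#' @param seeds character vector of seed symbols.
#' @param network an \linkS4class{InteractionNetwork}.
#' @param includeSeeds include the seeds present in the network in the
#'   result (default TRUE).
#' @param kinds edge kinds to traverse; subset of
#'   \code{c("physical", "genetic", "unspecified")}; default all.
#' @return an \linkS4class{ExpansionResult}.
#' @export
firstNeighborExpand <- function(seeds, network, includeSeeds = TRUE,
                                kinds = c("physical", "genetic",
                                          "unspecified")) {
    stopifnot(is(network, "InteractionNetwork"))
    kinds <- match.arg(kinds, several.ok = TRUE)
    seeds <- unique(canonicalizeSymbol(seeds))
    e <- network@edges
    e <- e[e$kind %in% kinds, , drop = FALSE]
    present <- intersect(seeds, network@nodes)
    missing <- setdiff(seeds, network@nodes)
    hitFrom <- e$from %in% present
    hitTo <- e$to %in% present
    neighbors <- unique(c(e$to[hitFrom], e$from[hitTo]))
    inter <- sort(if (includeSeeds) union(present, neighbors) else neighbors)
    # per-seed direct neighbor counts (within the kind filter)
    counts <- vapply(present, function(s)
        length(unique(c(e$to[e$from == s], e$from[e$to == s]))), 0L)
    if (length(counts) == 0L) counts <- integer()
    new("ExpansionResult", seedsUsed = sort(present),
        missingSeeds = sort(missing), interactome = inter,
        neighborCounts = counts, includeSeeds = includeSeeds)
}
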