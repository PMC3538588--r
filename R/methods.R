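#' @rdname PathwayCollection-class
#' @export
setMethod("pathwayNames", "PathwayCollection", function(x) names(x@sets))

#' @rdname PathwayCollection-class
#' @export
setMethod("members", "PathwayCollection", function(x, name) {
    if (!name %in% names(x@sets)) stop("no pathway named '", name, "'")
    x@sets[[name]]
})

#' @rdname geneUniverse
#' @export
setMethod("geneUniverse", "PathwayCollection",
          function(x) sort(unique(unlist(x@sets, use.names = FALSE))))

#' @rdname PathwayCollection-class
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @rdname PathwayCollection-class
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

#' @rdname PathwayCollection-class
#' @param i pathway name or index.
#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@sets[[i]])

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection with", length(object@sets), "pathway(s),",
        length(geneUniverse(object)), "distinct gene(s)\n")
    if (length(object@sets)) {
        sizes <- vapply(object@sets, length, 0L)
        cat("  sizes:", paste(range(sizes), collapse = "-"), "\n")
    }
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
    if (nrow(object@edges))
        print(table(object@edges$kind))
})

#' @rdname ExpansionResult-class
#' @export
setMethod("interactomeGenes", "ExpansionResult", function(x) x@interactome)

setMethod("show", "ExpansionResult", function(object) {
    cat("ExpansionResult:", length(object@seedsUsed), "seed(s) used",
        sprintf("(%d absent from network),", length(object@missingSeeds)),
        length(object@interactome), "gene(s) in interactome",
        if (object@includeSeeds) "(seeds included)\n" else
            "(seeds excluded)\n")
})

#' @rdname DECallSet-class
#' @export
setMethod("upGenes", "DECallSet", function(x) x@up)

#' @rdname DECallSet-class
#' @export
setMethod("downGenes", "DECallSet", function(x) x@down)

#' @rdname calledGenes
#' @export
setMethod("calledGenes", "DECallSet",
          function(x) sort(unique(c(x@up, x@down))))

#' @rdname DECallSet-class
#' @export
setMethod("deTable", "DECallSet", function(x) x@table)

setMethod("show", "DECallSet", function(object) {
    cat("DECallSet [", object@condition, "]: ", length(object@up), " up, ",
        length(object@down), " down at |Diff score| >= ", object@threshold,
        if (object@adjusted) " (BH-adjusted)\n" else " (unadjusted)\n",
        sep = "")
})

setMethod("show", "SyntheticBundle", function(object) {
    cat("SyntheticBundle:", nrow(object@association), "association rows;",
        length(object@network@nodes), "network nodes /",
        nrow(object@network@edges), "edges;",
        length(object@pathways), "pathways;",
        length(object@drugs), "drugs;",
        length(object@expression), "condition(s)\n")
    if (!is.null(object@truth$causalPathway))
        cat("  planted causal pathway:", object@truth$causalPathway, "\n")
})

setMethod("show", "ConvergenceReport", function(object) {
    cat("ConvergenceReport\n")
    cat("  seeds:", length(object@seeds), "\n")
    cat("  interactome:", length(object@expansion@interactome), "\n")
    cat("  conditions:", paste(names(object@conditions), collapse = ", "),
        "\n")
    cat("  common pathways:", nrow(object@commonPathways), "\n")
    if (nrow(object@ablation))
        cat("  top ablation impact:", object@ablation$pathway[1L], "\n")
})
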