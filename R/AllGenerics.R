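#' @rdname PathwayCollection-class
#' @param x,object a PathwayCollection.
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname PathwayCollection-class
#' @param name pathway name.
#' @export
setGeneric("members", function(x, name) standardGeneric("members"))

#' Union of all member genes of a collection
#' @param x a PathwayCollection.
#' @return character vector of all genes appearing in any pathway.
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname InteractionNetwork-class
#' @param x an InteractionNetwork.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ExpansionResult-class
#' @param x an ExpansionResult.
#' @export
setGeneric("interactomeGenes", function(x) standardGeneric("interactomeGenes"))

#' @rdname DECallSet-class
#' @param x a DECallSet.
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname DECallSet-class
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' Called (up or down) genes of a DECallSet — the condition "transcriptome"
#' @param x a DECallSet.
#' @return character vector, union of up- and down-called genes.
#' @export
setGeneric("calledGenes", function(x) standardGeneric("calledGenes"))

#' @rdname DECallSet-class
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' Run the full genome-to-phenome convergence pipeline
#'
#' @param inputs a \linkS4class{SyntheticBundle} or a named list with
#'   elements \code{association}, \code{network}, \code{pathways},
#'   \code{drugs}, \code{expression}.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return a \linkS4class{ConvergenceReport}.
#' @export
setGeneric("runPipeline",
           function(inputs, config = pipelineConfig())
               standardGeneric("runPipeline"))
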