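#' Published per-condition intersection enrichment table
#'
#' The published enrichment results for the interactome x transcriptome
#' commonality genes of the four tissue-by-gender conditions in the type 2
#' diabetes study this package models (female/male visceral adipose,
#' female subcutaneous adipose, male skeletal muscle), shipped as a
#' plain-text fixture. Each listed row is a pathway with unadjusted
#' enrichment p < 0.05 in that condition; intersecting the four lists
#' gives the study's twelve cross-condition common pathways.
#'
#' @return data.frame with columns condition, pathway, pRaw, pAdj.
#' @export
t2dIntersectionPathways <- function() {
    path <- system.file("extdata", "t2d_intersection_pathways.tsv",
                        package = "convergeR", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
}

#' Published TGF-beta signaling genes in the intersection sets
#'
#' The TGF-beta signaling pathway members found among the commonality
#' genes of the two conditions where insulin signaling was enriched
#' (10 genes in female visceral adipose, 7 in male skeletal muscle);
#' used for the leave-pathway-out ablation worked example.
#'
#' @return data.frame with columns condition, gene.
#' @export
t2dTgfbIntersectionGenes <- function() {
    path <- system.file("extdata", "t2d_tgfb_intersection_genes.tsv",
                        package = "convergeR", mustWork = TRUE)
    d <- read.delim(path, stringsAsFactors = FALSE)
    d$gene <- canonicalizeSymbol(d$gene)
    d
}
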