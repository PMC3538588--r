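#' Canonicalize gene symbols
#'
#' Gene identity throughout the package is the canonicalized symbol string:
#' whitespace-trimmed, uppercased. Canonicalization is idempotent and
#' deterministic; no identifier-mapping service is consulted (inputs are
#' author-reported symbols).
#'
#' @param raw character vector of free-text tokens.
#' @return character vector of canonical symbols.
#' @examples
#' canonicalizeSymbol(c("tgfb1 ", "CDKN2B"))
#' @export
canonicalizeSymbol <- function(raw) {
    if (length(raw) == 0L) return(character())
    out <- toupper(trimws(as.character(raw)))
    if (any(is.na(out) | out == ""))
        stop("malformed gene symbol: empty or whitespace-only input")
    if (any(grepl("[[:space:]]", out)))
        stop("malformed gene symbol: internal whitespace in ",
             paste(head(out[grepl("[[:space:]]", out)], 3L), collapse = ", "))
    out
}

#' Read / write GMT pathway files
#'
#' Standard GMT: one pathway per line, tab-delimited as
#' name, description, gene, gene, ... Symbols are canonicalized and
#' deduplicated; duplicate pathway names are an error.
#'
#' @param path file path.
#' @return \code{readGmt}: a \linkS4class{PathwayCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(PathwayCollection())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, 0L) < 3L)
    if (length(short))
        stop("GMT parse error: line ", short[1L], " has fewer than 3 fields")
    nm <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("GMT parse error: duplicate pathway name '",
             nm[duplicated(nm)][1L], "'")
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- nm
    PathwayCollection(sets)
}

#' @rdname readGmt
#' @param x a PathwayCollection.
#' @param descriptions optional named character of descriptions (default
#'   \code{"na"}).
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
    stopifnot(is(x, "PathwayCollection"))
    nm <- pathwayNames(x)
    desc <- if (is.null(descriptions)) rep("na", length(nm))
            else descriptions[nm]
    lines <- vapply(seq_along(nm), function(i)
        paste(c(nm[i], desc[i], x@sets[[i]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read / write interaction edge lists
#'
#' Tab-delimited, two symbol columns plus an optional kind column
#' (\code{physical} or \code{genetic}). Self-loops are dropped and
#' duplicate edges collapsed, with counts reported.
#'
#' @param path file path.
#' @param nodes optional explicit node universe file content override
#'   (character vector); default universe is the interactors.
#' @param quiet suppress drop-count messages.
#' @return \code{readEdgeList}: an \linkS4class{InteractionNetwork}.
#' @export
readEdgeList <- function(path, nodes = NULL, quiet = FALSE) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(InteractionNetwork(quiet = quiet))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, 0L) < 2L)
    if (length(short))
        stop("edge-list parse error: line ", short[1L],
             " has fewer than 2 columns")
    e <- data.frame(
        from = vapply(fields, `[[`, "", 1L),
        to = vapply(fields, `[[`, "", 2L),
        kind = vapply(fields, function(f)
            if (length(f) >= 3L) f[[3L]] else "unspecified", ""),
        stringsAsFactors = FALSE)
    InteractionNetwork(e, nodes = nodes, quiet = quiet)
}

#' @rdname readEdgeList
#' @param x an InteractionNetwork.
#' @export
writeEdgeList <- function(x, path) {
    stopifnot(is(x, "InteractionNetwork"))
    write.table(x@edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an association table (gene, p-value)
#'
#' Tab-delimited rows of gene symbol and association p-value, emulating a
#' GWAS-catalog "reported genes" extract. Multi-gene entries (e.g.
#' intergenic \code{"A - B"} annotations) are split into atomic symbols,
#' with a message giving the count; the split rule is a package choice
#' since catalogs do not state one. Duplicate genes are kept in the table
#' (per-SNP rows); thresholding collapses them by minimum p.
#'
#' @param path file path.
#' @param quiet suppress split-count messages.
#' @return data.frame with columns \code{gene}, \code{p}.
#' @export
readAssociationTable <- function(path, quiet = FALSE) {
    d <- read.delim(path, header = FALSE, col.names = c("gene", "p"),
                    colClasses = c("character", "numeric"), comment.char = "#")
    if (any(is.na(d$p) | d$p <= 0 | d$p > 1))
        stop("association p-values must lie in (0, 1]")
    # hyphen splits only when space-padded ("A - B" intergenic entries);
    # bare hyphens are part of legitimate symbols (e.g. NKX2-1)
    parts <- strsplit(d$gene, "\\s+-\\s+|\\s*[,;/]\\s*")
    nsplit <- sum(vapply(parts, length, 0L) > 1L)
    if (nsplit && !quiet)
        message("split ", nsplit, " multi-gene entr",
                if (nsplit == 1L) "y" else "ies", " into atomic symbols")
    d <- data.frame(gene = unlist(parts),
                    p = rep(d$p, vapply(parts, length, 0L)),
                    stringsAsFactors = FALSE)
    d <- d[nzchar(trimws(d$gene)), , drop = FALSE]
    d$gene <- canonicalizeSymbol(d$gene)
    rownames(d) <- NULL
    d
}

#' @rdname readAssociationTable
#' @param x data.frame with columns \code{gene}, \code{p}.
#' @export
writeAssociationTable <- function(x, path) {
    write.table(x[c("gene", "p")], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a drug-gene association table
#'
#' Delimited rows (drug, gene) emulating a toxicogenomic (CTD-style)
#' extract. Gene sets are canonicalized and deduplicated per drug.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return named list: drug name -> character vector of genes.
#' @export
readDrugGeneTable <- function(path, sep = "\t") {
    d <- read.delim(path, header = FALSE, sep = sep,
                    col.names = c("drug", "gene"),
                    colClasses = "character", comment.char = "#")
    drugs <- split(canonicalizeSymbol(d$gene), d$drug)
    lapply(drugs, function(g) sort(unique(g)))
}

#' @rdname readDrugGeneTable
#' @param x named list drug -> genes.
#' @export
writeDrugGeneTable <- function(x, path, sep = "\t") {
    d <- data.frame(drug = rep(names(x), vapply(x, length, 0L)),
                    gene = unlist(x, use.names = FALSE))
    write.table(d, path, sep = sep, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an expression matrix with its sample-metadata sidecar
#'
#' The matrix is tab-delimited with the first column holding gene symbols
#' and the header holding sample ids; the sidecar has columns
#' \code{sample}, \code{group} (\code{case}/\code{control}), \code{biorep},
#' \code{techrep}. Returns a \code{SummarizedExperiment} with one assay
#' (\code{log2} if already log-scale, else \code{linear}).
#'
#' @param path matrix file path.
#' @param metadataPath sidecar file path.
#' @param log2Scale whether intensities are already log2 (assay name flag).
#' @return a \code{SummarizedExperiment}.
#' @export
readExpression <- function(path, metadataPath, log2Scale = TRUE) {
    m <- read.delim(path, check.names = FALSE)
    genes <- canonicalizeSymbol(m[[1L]])
    mat <- as.matrix(m[, -1L, drop = FALSE])
    rownames(mat) <- genes
    meta <- read.delim(metadataPath, colClasses = "character")
    need <- c("sample", "group", "biorep", "techrep")
    if (!all(need %in% names(meta)))
        stop("metadata must have columns ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(mat), meta$sample)
    if (length(missing))
        stop("sample(s) in matrix missing from metadata: ",
             paste(missing, collapse = ", "))
    meta <- meta[match(colnames(mat), meta$sample), , drop = FALSE]
    if (any(is.na(meta$group) | meta$group == ""))
        stop("missing group labels in metadata")
    makeExpressionSet(mat, meta, log2Scale = log2Scale)
}

#' Assemble a SummarizedExperiment from a matrix and sample metadata
#'
#' @param mat genes x samples numeric matrix with rownames/colnames.
#' @param meta data.frame with columns sample, group, biorep, techrep.
#' @param log2Scale whether values are log2 (otherwise tagged linear).
#' @return a \code{SummarizedExperiment}.
#' @export
makeExpressionSet <- function(mat, meta, log2Scale = TRUE) {
    stopifnot(ncol(mat) == nrow(meta),
              all(colnames(mat) == meta$sample),
              all(meta$group %in% c("case", "control")))
    cd <- S4Vectors::DataFrame(group = meta$group, biorep = meta$biorep,
                               techrep = meta$techrep,
                               row.names = meta$sample)
    assays <- stats::setNames(list(mat),
                              if (log2Scale) "log2" else "linear")
    SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
}

#' @rdname readExpression
#' @param se a \code{SummarizedExperiment} as produced by
#'   \code{readExpression}.
#' @param metadataPath sidecar output path.
#' @export
writeExpression <- function(se, path, metadataPath) {
    mat <- SummarizedExperiment::assay(se)
    out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- SummarizedExperiment::colData(se)
    meta <- data.frame(sample = rownames(cd), group = cd$group,
                       biorep = cd$biorep, techrep = cd$techrep)
    write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a qPCR Ct table
#'
#' Tab-delimited with columns \code{gene}, \code{sample}, \code{ctTarget},
#' \code{ctReference}, \code{group}. Rows with either Ct above the
#' detection threshold (default 36 cycles) are flagged
#' \code{undetected = TRUE} and excluded from fold-change computation.
#'
#' @param path file path.
#' @param detectionThreshold maximum detectable Ct (cycles).
#' @return data.frame with an added logical \code{undetected} column.
#' @export
readCtTable <- function(path, detectionThreshold = 36) {
    d <- read.delim(path, colClasses = c(gene = "character",
                                         sample = "character",
                                         ctTarget = "numeric",
                                         ctReference = "numeric",
                                         group = "character"))
    d$gene <- canonicalizeSymbol(d$gene)
    d$undetected <- d$ctTarget > detectionThreshold |
        d$ctReference > detectionThreshold
    d
}

#' Write enrichment/overlap results as TSV or JSON
#'
#' @param x a result data.frame from \code{\link{pathwayEnrichment}},
#'   \code{\link{overlapTest}} or \code{\link{drugOverlapScreen}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeResults <- function(x, path, format = c("tsv", "json")) {
    format <- match.arg(format)
    if (format == "tsv") {
        out <- x
        if (!is.null(out$genes) && is.list(out$genes))
            out$genes <- vapply(out$genes, paste, "", collapse = ";")
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    }
    invisible(path)
}
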