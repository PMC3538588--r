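#' Per-gene case/control test on biological-replicate means
#'
#' Technical replicates are averaged within each biological replicate
#' first (pre-averaging avoids pseudoreplication from the replicate
#' structure), then a two-sided Welch t-test compares biological-replicate
#' means per gene. Intensities must be log2; linear inputs are
#' transformed as \code{log2(x + offset)}. Implemented in closed form
#' over the whole matrix (Welch statistic and Satterthwaite df), so
#' thousands of genes are tested in one pass.
#'
#' Degenerate variance: a gene constant and equal across all samples gets
#' p = 1 (no evidence); a gene with zero variance in both groups but
#' unequal means gets the smallest positive p (infinite t), which the
#' Diff-score transform then caps.
#'
#' @param se a \code{SummarizedExperiment} from
#'   \code{\link{readExpression}}/\code{\link{makeExpressionSet}}, with
#'   colData columns group, biorep, techrep.
#' @param log2Offset offset used when the assay is linear scale.
#' @return data.frame: gene, meanCase, meanControl, pRaw.
#' @export
perGeneTest <- function(se, log2Offset = 1) {
    cd <- SummarizedExperiment::colData(se)
    mat <- SummarizedExperiment::assay(se, 1L)
    if (SummarizedExperiment::assayNames(se)[1L] == "linear")
        mat <- log2(mat + log2Offset)
    group <- as.character(cd$group)
    biorep <- paste(group, as.character(cd$biorep), sep = ":")
    # technical replicates -> biological replicate means
    reps <- unique(data.frame(biorep = biorep, group = group,
                              stringsAsFactors = FALSE))
    bmat <- vapply(reps$biorep, function(b)
        rowMeans(mat[, biorep == b, drop = FALSE]),
        numeric(nrow(mat)))
    if (nrow(mat) == 1L) bmat <- matrix(bmat, nrow = 1L,
                                        dimnames = list(rownames(mat),
                                                        reps$biorep))
    nCase <- sum(reps$group == "case")
    nCtrl <- sum(reps$group == "control")
    if (nCase < 2L || nCtrl < 2L)
        stop("each group needs >= 2 biological replicates")
    xc <- bmat[, reps$group == "case", drop = FALSE]
    x0 <- bmat[, reps$group == "control", drop = FALSE]
    mc <- rowMeans(xc); m0 <- rowMeans(x0)
    vc <- rowSums((xc - mc)^2) / (nCase - 1L)
    v0 <- rowSums((x0 - m0)^2) / (nCtrl - 1L)
    sse <- vc / nCase + v0 / nCtrl
    tstat <- (mc - m0) / sqrt(sse)
    df <- sse^2 / ((vc / nCase)^2 / (nCase - 1L) +
                   (v0 / nCtrl)^2 / (nCtrl - 1L))
    p <- 2 * stats::pt(-abs(tstat), df)
    # zero variance in both groups
    degenerate <- sse == 0
    p[degenerate & mc == m0] <- 1
    p[degenerate & mc != m0] <- .Machine$double.xmin
    p[p == 0] <- .Machine$double.xmin
    data.frame(gene = rownames(mat), meanCase = mc, meanControl = m0,
               pRaw = p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Signed Diff score
#'
#' The Diff-score convention maps a p-value and a direction of change to
#' \code{sign * (-10 * log10(p))}: p = 0.05 gives magnitude 13.0103
#' (threshold 13 after rounding), p = 0.01 gives 20. A p of exactly 0 is
#' clamped to the smallest positive double with a warning, capping the
#' score.
#'
#' @param p p-value(s) in [0, 1].
#' @param sign direction(s), +1 or -1.
#' @return signed score(s) in score units.
#' @examples
#' diffScore(0.05, +1)  # 13.0103
#' @export
diffScore <- function(p, sign) {
    if (any(!sign %in% c(-1, 1))) stop("sign must be +1 or -1")
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
    if (any(p == 0)) {
        warning("p = 0 clamped to smallest positive double; score capped")
        p[p == 0] <- .Machine$double.xmin
    }
    sign * (-10 * log10(p))
}

#' Call differentially expressed genes at a Diff-score threshold
#'
#' Runs \code{\link{perGeneTest}}, converts each gene's p-value (raw, or
#' BH-adjusted when \code{adjust = "bh"}) and direction of mean change to
#' a signed Diff score, and calls genes up at score >= +threshold and
#' down at score <= -threshold. The default |13| threshold corresponds to
#' p = 0.05; at unadjusted scores the up/down union is the condition's
#' "disease transcriptome".
#'
#' @param se a \code{SummarizedExperiment} (see
#'   \code{\link{perGeneTest}}).
#' @param threshold absolute Diff-score call threshold (score units).
#' @param adjust \code{"none"} or \code{"bh"}.
#' @param condition label stored in the result.
#' @param log2Offset passed to \code{\link{perGeneTest}}.
#' @return a \linkS4class{DECallSet}.
#' @export
callDE <- function(se, threshold = 13, adjust = c("none", "bh"),
                   condition = "condition", log2Offset = 1) {
    adjust <- match.arg(adjust)
    tab <- perGeneTest(se, log2Offset = log2Offset)
    tab$pUsed <- if (adjust == "bh") bhAdjust(tab$pRaw) else tab$pRaw
    sgn <- ifelse(tab$meanCase >= tab$meanControl, 1, -1)
    tab$diffScore <- diffScore(tab$pUsed, sgn)
    tab$direction <- ifelse(tab$diffScore >= threshold, "up",
                     ifelse(tab$diffScore <= -threshold, "down", "none"))
    new("DECallSet", condition = condition, threshold = threshold,
        adjusted = adjust == "bh", table = tab,
        up = sort(tab$gene[tab$direction == "up"]),
        down = sort(tab$gene[tab$direction == "down"]))
}

#' Relative quantification by the comparative Ct method
#'
#' For each gene, averages replicate Ct values of target and endogenous
#' control within each group, forms per-group
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}, then
#' \eqn{\Delta\Delta Ct = \Delta Ct_{case} - \Delta Ct_{calibrator}} and
#' fold change \eqn{2^{-\Delta\Delta Ct}}. Rows flagged undetected
#' (Ct above the detection threshold, default 36 cycles) are excluded.
#'
#' @param ct data.frame as returned by \code{\link{readCtTable}}
#'   (columns gene, sample, ctTarget, ctReference, group and optionally
#'   undetected).
#' @param calibrator the reference group (default \code{"control"}).
#' @return data.frame: gene, dCtCase, dCtControl, ddCt, fold.
#' @export
deltaDeltaCt <- function(ct, calibrator = "control") {
    need <- c("gene", "sample", "ctTarget", "ctReference", "group")
    stopifnot(all(need %in% names(ct)))
    if (is.null(ct$undetected)) ct$undetected <- FALSE
    ct <- ct[!ct$undetected, , drop = FALSE]
    groups <- unique(ct$group)
    if (!calibrator %in% groups)
        stop("calibrator group '", calibrator, "' not present")
    test <- setdiff(groups, calibrator)
    if (length(test) != 1L)
        stop("exactly one non-calibrator group expected, found: ",
             paste(test, collapse = ", "))
    ct$dct <- ct$ctTarget - ct$ctReference
    agg <- stats::aggregate(dct ~ gene + group, data = ct, FUN = mean)
    wide <- stats::reshape(agg, idvar = "gene", timevar = "group",
                           direction = "wide")
    cCase <- paste0("dct.", test)
    cCal <- paste0("dct.", calibrator)
    if (any(is.na(wide[[cCase]])) || any(is.na(wide[[cCal]])))
        stop("every gene needs detected Ct values in both groups")
    ddct <- wide[[cCase]] - wide[[cCal]]
    data.frame(gene = wide$gene, dCtCase = wide[[cCase]],
               dCtControl = wide[[cCal]], ddCt = ddct,
               fold = 2^(-ddct), stringsAsFactors = FALSE,
               row.names = NULL)
}
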