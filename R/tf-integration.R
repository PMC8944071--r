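#' Group mean FPKM per gene
#'
#' Arithmetic mean FPKM per gene across healthy and cancer samples,
#' and their difference (cancer - healthy).
#'
#' @param fpkm genes x samples matrix (nonnegative).
#' @param condition per-sample `"healthy"`/`"cancer"` labels.
#' @return data.frame with `gene`, `mean_healthy`, `mean_cancer`,
#'   `difference`.
#' @export
groupMeanFpkm <- function(fpkm, condition) {
    fpkm <- as.matrix(fpkm)
    if (any(fpkm < 0)) stop("FPKM values must be nonnegative")
    if (length(condition) != ncol(fpkm))
        stop("one condition label per sample column is required")
    for (cl in c("healthy", "cancer"))
        if (!any(condition == cl)) stop("no '", cl, "' samples")
    if (any(bad <- !stats::complete.cases(fpkm)))
        stop("genes with missing values: ",
             paste(rownames(fpkm)[bad], collapse = ", "))
    mh <- rowGroupMeans(fpkm, which(condition == "healthy"))
    mc <- rowGroupMeans(fpkm, which(condition == "cancer"))
    data.frame(gene = rownames(fpkm), mean_healthy = mh,
               mean_cancer = mc, difference = mc - mh,
               row.names = NULL)
}

#' Differential expression on log2(FPKM + 1)
#'
#' A deliberately simple two-group test: per gene, the log2
#' fold-change is `log2((mean_cancer + 0.5) / (mean_healthy + 0.5))`
#' on the FPKM scale, and the p-value comes from a Welch t test on
#' `log2(FPKM + 1)` with BH adjustment across genes. (Count-model
#' alternatives such as a negative-binomial fit need read counts,
#' which this FPKM-level pipeline does not consume.)
#'
#' @inheritParams groupMeanFpkm
#' @return data.frame with `gene`, `log2FC`, `p`, `q` plus the group
#'   means.
#' @export
differentialExpression <- function(fpkm, condition) {
    fpkm <- as.matrix(fpkm)
    for (cl in c("healthy", "cancer"))
        if (sum(condition == cl) < 2L)
            stop("group '", cl, "' has fewer than 2 samples")
    gm <- groupMeanFpkm(fpkm, condition)
    y <- log2(fpkm + 1)
    iH <- which(condition == "healthy"); iC <- which(condition == "cancer")
    n1 <- length(iH); n2 <- length(iC)
    m1 <- rowGroupMeans(y, iH); m2 <- rowGroupMeans(y, iC)
    v1 <- rowVars(y[, iH, drop = FALSE])
    v2 <- rowVars(y[, iC, drop = FALSE])
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se2 == 0] <- 1           # identical groups: no evidence
    data.frame(gene = gm$gene,
               mean_healthy = gm$mean_healthy,
               mean_cancer = gm$mean_cancer,
               log2FC = log2((gm$mean_cancer + 0.5) /
                             (gm$mean_healthy + 0.5)),
               p = p, q = stats::p.adjust(p, "BH"), row.names = NULL)
}

#' Select candidate driver TFs
#'
#' Combines motif enrichment with TF expression: for enrichments
#' computed on hypo-methylated DMRs a (TF, motif) pair is emitted when
#' the motif's enrichment p-value is below `motifPThreshold` and the
#' TF has a positive mean FPKM difference in cancer (an upregulated TF
#' whose binding could protect its sites from methylation); for
#' hyper-methylated DMRs the expression gate is a negative difference
#' (a lost TF whose sites gain methylation). Expression p/q values are
#' reported but not thresholded.
#'
#' @param enrichment data.frame from [motifEnrichment()] (columns
#'   `motif`, `fold`, `p`).
#' @param expression data.frame from [differentialExpression()].
#' @param motifTFMap data.frame with columns `motif`, `tf` mapping
#'   each motif to one or more TF gene ids; motifs without a mapping
#'   are skipped with a warning.
#' @param direction `"hypo"` or `"hyper"`: the methylation direction
#'   of the DMR set the enrichment was computed on.
#' @param motifPThreshold enrichment gate (default 0.001).
#' @return data.frame of predictions, sorted by motif p, with columns
#'   `tf`, `motif`, `motif_p`, `motif_fold`, `mean_fpkm_healthy`,
#'   `mean_fpkm_cancer`, `log2FC`, `expr_p`, `expr_q`, `direction`.
#' @export
selectCandidateTFs <- function(enrichment, expression, motifTFMap,
                               direction = c("hypo", "hyper"),
                               motifPThreshold = 0.001) {
    direction <- match.arg(direction)
    unmapped <- setdiff(enrichment$motif, motifTFMap$motif)
    if (length(unmapped))
        warning("motif(s) without TF mapping skipped: ",
                paste(unmapped, collapse = ", "))
    hits <- enrichment[enrichment$p < motifPThreshold &
                       enrichment$motif %in% motifTFMap$motif, ,
                       drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(hits))) {
        tfs <- motifTFMap$tf[motifTFMap$motif == hits$motif[i]]
        for (tf in tfs) {
            e <- expression[expression$gene == tf, , drop = FALSE]
            if (!nrow(e)) next
            dif <- e$mean_cancer - e$mean_healthy
            pass <- if (direction == "hypo") dif > 0 else dif < 0
            if (!pass) next
            out[[length(out) + 1L]] <- data.frame(
                tf = tf, motif = hits$motif[i], motif_p = hits$p[i],
                motif_fold = hits$fold[i],
                mean_fpkm_healthy = e$mean_healthy,
                mean_fpkm_cancer = e$mean_cancer,
                log2FC = e$log2FC, expr_p = e$p, expr_q = e$q,
                direction = if (direction == "hypo")
                    "hypo-driver (up)" else "hyper-driver (down)")
        }
    }
    if (!length(out))
        return(data.frame(tf = character(0), motif = character(0),
                          motif_p = numeric(0), motif_fold = numeric(0),
                          mean_fpkm_healthy = numeric(0),
                          mean_fpkm_cancer = numeric(0),
                          log2FC = numeric(0), expr_p = numeric(0),
                          expr_q = numeric(0), direction = character(0)))
    res <- do.call(rbind, out)
    res[order(res$motif_p, res$motif, res$tf), , drop = FALSE]
}

#' Pan-cancer summary: one motif per TF across runs
#'
#' Across several enrichment runs (e.g. cancer types), selects for
#' each TF the motif with the best summed evidence — the largest sum
#' over runs of -log10(motif p) (equivalently the best p-value product
#' across all runs; `method = "min"` ranks by the single best p
#' instead). Ties are broken by motif id.
#'
#' @param enrichments named list of data.frames from
#'   [motifEnrichment()], one per run.
#' @param motifTFMap data.frame with columns `motif`, `tf`.
#' @param method `"sum"` (default) or `"min"`.
#' @return list with `choice` (data.frame tf, motif, score) and `p` /
#'   `fold` matrices (TF x run) for the chosen motifs.
#' @export
panCancerSummary <- function(enrichments, motifTFMap,
                             method = c("sum", "min")) {
    method <- match.arg(method)
    if (!length(enrichments)) stop("need at least one run")
    runs <- names(enrichments)
    if (is.null(runs)) runs <- paste0("run", seq_along(enrichments))
    tfs <- sort(unique(motifTFMap$tf))
    choice <- list()
    pMat <- matrix(NA_real_, length(tfs), length(enrichments),
                   dimnames = list(tfs, runs))
    fMat <- pMat
    for (tf in tfs) {
        motifs <- sort(motifTFMap$motif[motifTFMap$tf == tf])
        score <- vapply(motifs, function(m) {
            ps <- vapply(enrichments, function(e) {
                i <- match(m, e$motif)
                if (is.na(i)) NA_real_ else e$p[i]
            }, numeric(1))
            ps <- ps[!is.na(ps)]
            if (!length(ps)) return(-Inf)
            if (method == "sum") sum(-log10(ps)) else max(-log10(ps))
        }, numeric(1))
        best <- motifs[which.max(score)]   # ties: first in id order
        choice[[tf]] <- data.frame(tf = tf, motif = best,
                                   score = max(score))
        for (r in seq_along(enrichments)) {
            i <- match(best, enrichments[[r]]$motif)
            if (!is.na(i)) {
                pMat[tf, r] <- enrichments[[r]]$p[i]
                fMat[tf, r] <- enrichments[[r]]$fold[i]
            }
        }
    }
    list(choice = do.call(rbind, c(choice, list(make.row.names = FALSE))),
         p = pMat, fold = fMat)
}
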