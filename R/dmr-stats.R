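#' Per-CpG differential methylation statistics
#'
#' Computes, for every probe, the healthy and cancer group means, their
#' difference (delta = cancer - healthy), a two-sample t statistic with
#' empirical-Bayes variance moderation (limma's lmFit/eBayes: per-CpG
#' variances shrunk towards a prior estimated across CpGs, degrees of
#' freedom = residual + prior), the two-sided p-value from the t
#' distribution, and Benjamini-Hochberg q-values across all CpGs. With
#' `moderated = FALSE` the ordinary pooled-variance t is returned
#' (equivalent to zero prior degrees of freedom).
#'
#' @param beta a [BetaSet-class] with at least 2 samples per group.
#' @param moderated use empirical-Bayes moderation (default `TRUE`).
#' @param useM analyse M-values `log2(beta/(1-beta))` instead of beta
#'   values (off by default; group means and delta are always on the
#'   beta scale).
#' @return `GRanges` of the probes (sorted by position) with metadata
#'   columns `probe`, `mean_healthy`, `mean_cancer`, `delta`, `t`,
#'   `p`, `q`.
#' @export
cpgStats <- function(beta, moderated = TRUE, useM = FALSE) {
    stopifnot(is(beta, "BetaSet"))
    cond <- sampleCondition(beta)
    for (cl in c("healthy", "cancer"))
        if (sum(cond == cl) < 2L)
            stop("group '", cl, "' has fewer than 2 samples")
    b <- betaValues(beta)
    y <- if (useM) log2(b / (1 - b)) else b
    design <- cbind(intercept = 1, cancer = as.integer(cond == "cancer"))
    fit <- limma::lmFit(y, design)
    if (moderated) {
        eb <- limma::eBayes(fit)
        tstat <- eb$t[, "cancer"]
        pval <- eb$p.value[, "cancer"]
    } else {
        tstat <- fit$coefficients[, "cancer"] /
            (fit$stdev.unscaled[, "cancer"] * fit$sigma)
        pval <- 2 * stats::pt(-abs(tstat), fit$df.residual)
    }
    gr <- rowRanges(beta)
    o <- order(as.character(seqnames(gr)), start(gr))
    mh <- rowGroupMeans(b, which(cond == "healthy"))
    mc <- rowGroupMeans(b, which(cond == "cancer"))
    mcols(gr) <- DataFrame(
        probe = if (!is.null(names(gr))) names(gr)
                else as.character(seq_along(gr)),
        mean_healthy = unname(mh), mean_cancer = unname(mc),
        delta = unname(mc - mh),
        t = unname(tstat), p = unname(pval),
        q = unname(stats::p.adjust(pval, "BH")))
    gr[o]
}

#' Exclude CpGs located in exons
#'
#' Removes every CpG whose C position falls inside an exon interval
#' (interval starts inclusive, ends exclusive in file coordinates;
#' internally standard `GRanges` overlap of the width-1 C position).
#'
#' @param stats CpG `GRanges` (e.g. from [cpgStats()]).
#' @param exons `GRanges` of exon intervals.
#' @return the filtered `GRanges`; the number removed is reported via
#'   `message()`.
#' @export
excludeExonic <- function(stats, exons) {
    if (!length(exons) || !length(stats)) return(stats)
    cpos <- GenomicRanges::resize(stats, width = 1L, fix = "start")
    drop <- IRanges::overlapsAny(cpos, exons, ignore.strand = TRUE)
    message(sum(drop), " of ", length(stats), " CpGs in exons excluded")
    stats[!drop]
}
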