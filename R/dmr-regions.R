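#' Group significant CpGs into candidate regions
#'
#' A CpG is significant when its smoothed normal p-value is below
#' `smoothedPThreshold` and its per-CpG BH q-value below
#' `cpgFdrThreshold` (both gates applied; either can be disabled by
#' setting its threshold to 1). A candidate region is a maximal run of
#' significant CpGs on one chromosome in which consecutive members are
#' at most `lambda` bp apart.
#'
#' @param stats CpG `GRanges` with `smoothed_p` and `q` columns (from
#'   [kernelSmooth()] after [cpgStats()]).
#' @param lambda maximum gap between consecutive member CpGs (bp,
#'   default 1000).
#' @param smoothedPThreshold default 0.001.
#' @param cpgFdrThreshold default 0.05.
#' @return list of integer vectors, each the indices (into `stats`) of
#'   one candidate region's CpGs.
#' @export
callCandidateRegions <- function(stats, lambda = 1000,
                                 smoothedPThreshold = 0.001,
                                 cpgFdrThreshold = 0.05) {
    sig <- which(stats$smoothed_p < smoothedPThreshold &
                 stats$q < cpgFdrThreshold)
    if (!length(sig)) return(list())
    chroms <- as.character(seqnames(stats))[sig]
    pos <- start(stats)[sig]
    newRun <- c(TRUE, chroms[-1] != chroms[-length(sig)] |
                      diff(pos) > lambda)
    split(sig, cumsum(newRun))
}

#' Extract direction-consistent subregions
#'
#' Within each candidate region, takes maximal runs of consecutive
#' member CpGs whose delta has the same sign; runs of at least
#' `minCpGs` CpGs are emitted as directional regions (hypo for
#' negative delta in cancer, hyper for positive). Region bounds run
#' from the first to the last CpG of the run, with the end extended to
#' cover the final CpG dinucleotide.
#'
#' @param stats CpG `GRanges` with `delta`, `mean_healthy` columns.
#' @param candidates list of index vectors from
#'   [callCandidateRegions()].
#' @param minCpGs minimum run length (default 2).
#' @return `GRanges` of regions with metadata `direction`, `n_cpg`,
#'   `mean_delta`, `mean_healthy` and `cpg_ids` (`CharacterList`).
#' @export
extractConsistentSubregions <- function(stats, candidates,
                                        minCpGs = 2L) {
    out <- list()
    for (idx in candidates) {
        sgn <- sign(stats$delta[idx])
        runs <- rle(sgn)
        endsAt <- cumsum(runs$lengths)
        startsAt <- endsAt - runs$lengths + 1L
        for (r in seq_along(runs$lengths)) {
            if (runs$lengths[r] < minCpGs || runs$values[r] == 0) next
            member <- idx[startsAt[r]:endsAt[r]]
            gr <- GRanges(
                seqnames(stats)[member[1]],
                IRanges(start(stats)[member[1]],
                        start(stats)[member[length(member)]] + 1L))
            mcols(gr)$direction <- if (runs$values[r] < 0) "hypo"
                                   else "hyper"
            mcols(gr)$n_cpg <- length(member)
            mcols(gr)$mean_delta <- mean(stats$delta[member])
            mcols(gr)$mean_healthy <- mean(stats$mean_healthy[member])
            mcols(gr)$cpg_ids <- IRanges::CharacterList(
                list(stats$probe[member]))
            out[[length(out) + 1L]] <- gr
        }
    }
    if (!length(out))
        return(GRanges(direction = character(0), n_cpg = integer(0),
                       mean_delta = numeric(0),
                       mean_healthy = numeric(0),
                       cpg_ids = IRanges::CharacterList()))
    sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
}

#' Filter directional regions on length, effect size and start
#' methylation
#'
#' A region is kept when it is at least `minLength` bp long, its mean
#' delta over member CpGs is at least `minDelta` in absolute value,
#' and its healthy-sample starting methylation obeys the direction
#' rule: above 50% for regions hypo-methylated in cancer, below 50%
#' for hyper-methylated ones. Rejection reasons are recorded in the
#' attribute `"rejected"` of the result.
#'
#' @param regions `GRanges` from [extractConsistentSubregions()].
#' @param minLength minimum width in bp (default 200; `>=` gate).
#' @param minDelta minimum |mean delta| (default 0.20; `>=` gate).
#' @param startMethThreshold healthy-mean boundary (default 0.5;
#'   strict `>` / `<` gates per the direction).
#' @return the surviving `GRanges`.
#' @export
filterDMRs <- function(regions, minLength = 200, minDelta = 0.20,
                       startMethThreshold = 0.5) {
    if (!length(regions)) {
        attr(regions, "rejected") <- character(0)
        return(regions)
    }
    okLen <- width(regions) >= minLength
    okDelta <- abs(regions$mean_delta) >= minDelta
    hypo <- regions$direction == "hypo"
    okStart <- ifelse(hypo, regions$mean_healthy > startMethThreshold,
                      regions$mean_healthy < startMethThreshold)
    reason <- rep(NA_character_, length(regions))
    reason[!okStart] <- "start_methylation"
    reason[!okDelta] <- "delta"
    reason[!okLen] <- "length"
    keep <- okLen & okDelta & okStart
    out <- regions[keep]
    attr(out, "rejected") <- reason[!keep]
    out
}

#' Chromatin-accessibility filter
#'
#' Hypo-methylated regions are kept only when they overlap at least
#' one accessibility (ATAC) peak by >= 1 bp — putative TF binding is
#' expected in open chromatin of the cancer samples — while
#' hyper-methylated regions are kept only when they overlap no peak.
#'
#' @param dmrs directional region `GRanges`.
#' @param atacPeaks `GRanges` of peaks (may be empty: all hypo
#'   rejected, all hyper kept).
#' @return the filtered `GRanges`.
#' @export
atacFilter <- function(dmrs, atacPeaks) {
    if (!length(dmrs)) return(dmrs)
    ov <- IRanges::overlapsAny(dmrs, atacPeaks, ignore.strand = TRUE)
    keep <- ifelse(dmrs$direction == "hypo", ov, !ov)
    dmrs[keep]
}

#' Call differentially methylated regions from a BetaSet
#'
#' The full caller: per-CpG moderated statistics, exon exclusion,
#' signed-t Gaussian smoothing with normal p-values, grouping of
#' significant CpGs (gap <= lambda), direction-consistent subregion
#' extraction, the length / effect-size / start-methylation filters,
#' and the accessibility filter.
#'
#' @param beta a [BetaSet-class].
#' @param exons exon `GRanges` (optional).
#' @param atacPeaks accessibility peak `GRanges`; `NULL` skips the
#'   accessibility filter.
#' @param lambda,C smoothing parameters (see [kernelSmooth()]).
#' @param smoothedPThreshold,cpgFdrThreshold significance gates (see
#'   [callCandidateRegions()]).
#' @param minLength,minDelta,startMethThreshold reporting filters
#'   (see [filterDMRs()]).
#' @param minCpGs minimum consistent run length (default 2).
#' @param moderated,useM passed to [cpgStats()].
#' @return `GRanges` of DMRs; the per-CpG statistics are attached as
#'   attribute `"stats"`.
#' @export
callDMRs <- function(beta, exons = GRanges(), atacPeaks = NULL,
                     lambda = 1000, C = 2, smoothedPThreshold = 0.001,
                     cpgFdrThreshold = 0.05, minLength = 200,
                     minDelta = 0.20, startMethThreshold = 0.5,
                     minCpGs = 2L, moderated = TRUE, useM = FALSE) {
    st <- cpgStats(beta, moderated = moderated, useM = useM)
    st <- excludeExonic(st, exons)
    st <- kernelSmooth(st, lambda = lambda, C = C)
    cand <- callCandidateRegions(st, lambda = lambda,
                                 smoothedPThreshold = smoothedPThreshold,
                                 cpgFdrThreshold = cpgFdrThreshold)
    regions <- extractConsistentSubregions(st, cand, minCpGs = minCpGs)
    regions <- filterDMRs(regions, minLength = minLength,
                          minDelta = minDelta,
                          startMethThreshold = startMethThreshold)
    if (!is.null(atacPeaks))
        regions <- atacFilter(regions, atacPeaks)
    attr(regions, "stats") <- st
    regions
}
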