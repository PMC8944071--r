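#' Extract region sequences from a genome
#'
#' @param genome a [SyntheticGenome-class] or named
#'   [Biostrings::DNAStringSet].
#' @param regions `GRanges`.
#' @return a `DNAStringSet`, one sequence per region.
#' @export
getRegionSeqs <- function(genome, regions) {
    seqs <- if (is(genome, "SyntheticGenome")) genomeSequences(genome)
            else genome
    out <- vapply(seq_along(regions), function(i) {
        as.character(Biostrings::subseq(
            seqs[[as.character(seqnames(regions[i]))]],
            start(regions[i]), end(regions[i])))
    }, character(1))
    DNAStringSet(out)
}

## vectorised composition class for candidate ranges on one chromosome
candCpGClass <- function(subject, starts, ends) {
    v <- Biostrings::Views(subject, start = starts, end = ends)
    base <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    L <- rowSums(base)
    nC <- base[, "C"]; nG <- base[, "G"]
    x <- ifelse(L > 0, (nC + nG) / L, 0)
    nCpG <- Biostrings::vcountPattern("CG", v)
    y <- ifelse(nC * nG > 0, nCpG * L / (nC * nG), 0)
    classifyCpGClass(x, y)
}

#' Generate matched control regions for annotated DMRs
#'
#' For every DMR, samples `nPerDmr` control regions of identical
#' length that share its CpG class, TSS-proximity class and
#' promoter/intron/intergenic context, contain exactly the same
#' number of manifest probes, lie in mappable (non-repeat) space, are
#' not on chromosome Y and do not overlap any DMR or another control.
#' Sampling is batched rejection sampling with a cap; when the cap is
#' hit the probe-count match is relaxed to +/-1 (reported in the
#' `relaxed` column). A DMR for which no control can be found even
#' after relaxation is dropped from enrichment with a warning.
#'
#' @param dmrs annotated `GRanges` (from [annotateDMRs()]); names (or
#'   indices) identify DMRs in the output.
#' @param genome a [SyntheticGenome-class].
#' @param manifest probe `GRanges`.
#' @param annotation result of [generateAnnotation()].
#' @param nPerDmr controls per DMR (default 10; must be >= 1).
#' @param maxBatches rejection-sampling batches of size `batchSize`
#'   per DMR before (and again after) relaxing the probe match.
#' @param batchSize candidates drawn per batch (default 400).
#' @param seed integer seed; the control set is deterministic given
#'   the seed.
#' @return `GRanges` of controls with metadata `dmr_id` and
#'   `relaxed`.
#' @export
generateMatchedControls <- function(dmrs, genome, manifest, annotation,
                                    nPerDmr = 10L, maxBatches = 10L,
                                    batchSize = 400L, seed = 1L) {
    checkCount(nPerDmr, "nPerDmr", min = 1L)
    need <- c("cpg_class", "proximity", "context")
    if (!all(need %in% colnames(mcols(dmrs))))
        stop("dmrs must be annotated (run annotateDMRs first)")
    set.seed(seed)
    seqs <- genomeSequences(genome)
    lens <- chromLengths(genome)
    lens <- lens[names(lens) != "chrY"]
    rmask <- repeatMask(genome)
    ids <- if (!is.null(names(dmrs))) names(dmrs)
           else as.character(seq_along(dmrs))
    dmrProbes <- GenomicRanges::countOverlaps(dmrs, manifest,
                                              ignore.strand = TRUE)
    taken <- GRanges()  # accepted controls, sampled without replacement
    out <- list()
    for (i in seq_along(dmrs)) {
        w <- width(dmrs[i])
        got <- GRanges()
        relaxed <- FALSE
        batch <- 0L
        while (length(got) < nPerDmr) {
            batch <- batch + 1L
            if (batch > 2L * maxBatches) break
            if (batch == maxBatches + 1L && !relaxed) {
                relaxed <- TRUE
                message("control matching relaxed to +/-1 probe for DMR ",
                        ids[i])
            }
            fits <- lens[lens >= w + 1L]
            chr <- sample(names(fits), batchSize, replace = TRUE,
                          prob = fits)
            s <- floor(stats::runif(batchSize) * (fits[chr] - w)) + 1L
            cand <- GRanges(chr, IRanges(s, width = w))
            ## cheap interval constraints first
            keep <- !IRanges::overlapsAny(cand, rmask,
                                          ignore.strand = TRUE) &
                    !IRanges::overlapsAny(cand, dmrs,
                                          ignore.strand = TRUE)
            if (length(taken))
                keep <- keep & !IRanges::overlapsAny(cand, taken,
                                                     ignore.strand = TRUE)
            if (length(got))
                keep <- keep & !IRanges::overlapsAny(cand, got,
                                                     ignore.strand = TRUE)
            cand <- cand[keep]
            if (!length(cand)) next
            np <- GenomicRanges::countOverlaps(cand, manifest,
                                               ignore.strand = TRUE)
            okP <- if (relaxed) abs(np - dmrProbes[i]) <= 1L
                   else np == dmrProbes[i]
            cand <- cand[okP]
            if (!length(cand)) next
            prox <- classifyProximity(cand, annotation$tss)$proximity
            cand <- cand[prox == dmrs$proximity[i]]
            if (!length(cand)) next
            ctx <- classifyContext(cand, annotation)
            cand <- cand[ctx == dmrs$context[i]]
            if (!length(cand)) next
            for (chr2 in unique(as.character(seqnames(cand)))) {
                sel <- as.character(seqnames(cand)) == chr2
                cls <- candCpGClass(seqs[[chr2]], start(cand[sel]),
                                    end(cand[sel]))
                ok <- which(sel)[cls == dmrs$cpg_class[i]]
                for (k in ok) {
                    if (length(got) >= nPerDmr) break
                    if (length(got) &&
                        length(GenomicRanges::findOverlaps(cand[k], got)))
                        next
                    got <- suppressWarnings(c(got, cand[k]))
                }
            }
        }
        if (!length(got)) {
            warning("no matched control found for DMR ", ids[i],
                    "; excluded from enrichment")
            next
        }
        if (length(got) < nPerDmr)
            warning("only ", length(got), "/", nPerDmr,
                    " controls found for DMR ", ids[i])
        mcols(got)$dmr_id <- ids[i]
        mcols(got)$relaxed <- relaxed
        taken <- suppressWarnings(c(taken, got))
        out[[length(out) + 1L]] <- got
    }
    if (!length(out))
        return(GRanges(dmr_id = character(0), relaxed = logical(0)))
    res <- suppressWarnings(do.call(c, out))
    res
}

#' Motif enrichment of a DMR set against matched controls
#'
#' Scans DMR and control sequences with every motif at the `2^-IC`
#' threshold (background = pooled composition of all scanned
#' sequences) and computes the pseudocounted one-sided hypergeometric
#' enrichment per motif.
#'
#' @param motifs list of [Motif-class] objects.
#' @param dmrs `GRanges` of DMRs.
#' @param controls `GRanges` of control regions (e.g. from
#'   [generateMatchedControls()]).
#' @param genome a [SyntheticGenome-class] or `DNAStringSet`.
#' @param bg background passed to [scanRegionPresence()].
#' @param ... passed to [scanRegionPresence()].
#' @return data.frame, one row per motif, with id, TF, gc_class,
#'   cluster and the columns of [enrichmentVsControls()], sorted by p.
#' @export
motifEnrichment <- function(motifs, dmrs, controls, genome, bg = NULL,
                            ...) {
    allSeqs <- getRegionSeqs(genome, suppressWarnings(
        c(GRanges(seqnames(dmrs), IRanges::ranges(dmrs)),
          GRanges(seqnames(controls), IRanges::ranges(controls)))))
    pres <- scanRegionPresence(motifs, allSeqs, bg = bg, ...)
    nD <- length(dmrs)
    recs <- lapply(seq_along(motifs), function(k) {
        r <- enrichmentVsControls(pres[seq_len(nD), k],
                                  pres[nD + seq_len(length(controls)), k])
        cbind(data.frame(motif = motifID(motifs[[k]]),
                         tf = paste(motifTF(motifs[[k]]), collapse = "/"),
                         gc_class = motifGCClass(motifs[[k]]),
                         cluster = motifs[[k]]@cluster), r)
    })
    res <- do.call(rbind, recs)
    res[order(res$p, res$motif), , drop = FALSE]
}
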