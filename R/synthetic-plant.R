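#' Plant differentially methylated regions and embed motif instances
#'
#' Selects non-overlapping candidate regions spanning at least
#' `minProbes` consecutive manifest probes and at least 260 bp (clear of
#' the 200 bp reporting filter), away from exons and chrY, and assigns
#' them a direction and methylation effect. Into each hypo region, the
#' consensus sequence of each motif in `embedMotifs` is written with
#' probability `embedRate` at a position that does not disturb any
#' manifest probe CpG, so that a scan at the 2^-IC threshold is
#' guaranteed to find the instance.
#'
#' @param genome a [SyntheticGenome-class]; returned modified when
#'   motifs are embedded.
#' @param manifest probe `GRanges` from [generateManifest()].
#' @param annotation result of [generateAnnotation()].
#' @param nHypo,nHyper number of hypo-/hyper-methylated truth regions.
#' @param delta methylation-fraction change in cancer (0 < delta < 0.5).
#' @param embedMotifs list of [Motif-class] objects to embed in hypo
#'   regions (may be empty).
#' @param embedRate per-region, per-motif embedding probability.
#' @param minProbes minimum manifest probes per region (>= 2).
#' @param minGap minimum gap between planted regions in bp; defaults to
#'   2000 (twice the smoothing bandwidth) so neighbouring regions are
#'   not merged by the caller.
#' @param tfEffects named numeric vector of planted TF log2
#'   fold-changes recorded in the truth object.
#' @param hyperCpGDense if `TRUE`, hyper regions are drawn from the
#'   most probe-dense half of candidates, mimicking the CpG-island
#'   preference of cancer hyper-methylation.
#' @param seed integer seed.
#' @return list with `truth` (a [SyntheticTruth-class]) and `genome`
#'   (the possibly edited [SyntheticGenome-class]).
#' @export
plantRegionsAndMotifs <- function(genome, manifest, annotation,
                                  nHypo, nHyper, delta = 0.3,
                                  embedMotifs = list(), embedRate = 0,
                                  minProbes = 3L, minGap = 2000L,
                                  tfEffects = stats::setNames(numeric(0),
                                                              character(0)),
                                  hyperCpGDense = FALSE, seed = 1L) {
    checkCount(nHypo, "nHypo"); checkCount(nHyper, "nHyper")
    checkFraction(delta, "delta", 0, 0.5)
    checkFraction(embedRate, "embedRate", open = FALSE)
    checkCount(minProbes, "minProbes", min = 2L)
    set.seed(seed)
    lens <- chromLengths(genome)
    ok <- as.character(seqnames(manifest)) != "chrY"
    if (length(annotation$exons))
        ok <- ok & !IRanges::overlapsAny(manifest, annotation$exons,
                                         ignore.strand = TRUE)
    probes <- manifest[ok]

    ## candidate windows: disjoint runs of consecutive usable probes
    ## with inter-probe gaps below maxProbeGap (so the planted region
    ## is a coherent CpG neighbourhood, not a span across a probe
    ## desert), extended until the span clears 260 bp, padded by 50 bp
    maxProbeGap <- 900L
    cChr <- character(0); cStart <- integer(0); cEnd <- integer(0)
    cNP <- integer(0)
    probeChr <- as.character(seqnames(probes))
    for (chr in unique(probeChr)) {
        posAll <- start(probes)[probeChr == chr]
        if (length(posAll) < minProbes) next
        block <- cumsum(c(0L, diff(posAll) > maxProbeGap))
        for (pos in split(posAll, block)) {
            n <- length(pos)
            if (n < minProbes) next
            starts <- integer(0); ends <- integer(0); nps <- integer(0)
            i <- 1L
            while (i + minProbes - 1L <= n) {
                j <- i + minProbes - 1L
                while (j < n && pos[j] + 1L - pos[i] < 260L)
                    j <- j + 1L
                if (pos[j] + 1L - pos[i] >= 260L) {
                    s <- pos[i] - 50L; e <- pos[j] + 51L
                    if (s >= 1L && e <= lens[chr]) {
                        starts <- c(starts, s); ends <- c(ends, e)
                        nps <- c(nps, j - i + 1L)
                    }
                }
                i <- j + 1L
            }
            cChr <- c(cChr, rep(chr, length(starts)))
            cStart <- c(cStart, starts); cEnd <- c(cEnd, ends)
            cNP <- c(cNP, nps)
        }
    }
    cand <- GRanges(cChr, IRanges(cStart, cEnd))
    if (length(annotation$exons)) {
        keep <- !IRanges::overlapsAny(cand, annotation$exons,
                                      ignore.strand = TRUE)
        cand <- cand[keep]; cNP <- cNP[keep]
    }
    nWant <- nHypo + nHyper
    if (length(cand) < nWant)
        stop("insufficient probe-dense non-exonic space: ",
             length(cand), " candidates for ", nWant, " regions")

    ## greedy non-overlapping selection with a minimum gap, tracked in
    ## plain vectors for speed
    ord <- sample.int(length(cand))
    chosen <- integer(0)
    tChr <- character(0); tStart <- numeric(0); tEnd <- numeric(0)
    candChr <- as.character(seqnames(cand))
    for (k in ord) {
        if (length(chosen) == nWant) break
        same <- tChr == candChr[k]
        if (any(same) &&
            any((start(cand)[k] - minGap) <= tEnd[same] &
                (end(cand)[k] + minGap) >= tStart[same]))
            next
        chosen <- c(chosen, k)
        tChr <- c(tChr, candChr[k])
        tStart <- c(tStart, start(cand)[k])
        tEnd <- c(tEnd, end(cand)[k])
    }
    if (length(chosen) < nWant)
        stop("could not place ", nWant, " regions with gap >= ", minGap,
             " bp (placed ", length(chosen), ")")

    if (hyperCpGDense && nHyper > 0L) {
        dens <- cNP[chosen] / width(cand)[chosen]
        o <- order(dens, decreasing = TRUE)
        hyperIdx <- chosen[o[seq_len(nHyper)]]
        hypoIdx <- setdiff(chosen, hyperIdx)[seq_len(nHypo)]
    } else {
        hypoIdx <- chosen[seq_len(nHypo)]
        hyperIdx <- chosen[nHypo + seq_len(nHyper)]
    }
    regions <- suppressWarnings(c(cand[hypoIdx], cand[hyperIdx]))
    dir <- c(rep("hypo", nHypo), rep("hyper", nHyper))
    healthy <- ifelse(dir == "hypo", stats::runif(nWant, 0.65, 0.85),
                      stats::runif(nWant, 0.15, 0.35))
    mcols(regions)$direction <- dir
    mcols(regions)$delta <- rep(delta, nWant)
    mcols(regions)$healthy_mean <- healthy

    ## motif embedding into hypo regions
    seqs <- genomeSequences(genome)
    motifIds <- vector("list", nWant)
    manByChr <- split(IRanges::ranges(manifest),
                      as.character(seqnames(manifest)))
    regChr <- as.character(seqnames(regions))
    edits <- list()  # per chrom data.frame(start, end, value)
    for (r in which(dir == "hypo")) {
        chr <- regChr[r]
        blocked <- manByChr[[chr]]
        if (is.null(blocked)) blocked <- IRanges()
        placed <- IRanges()
        for (m in embedMotifs) {
            if (stats::runif(1) > embedRate) next
            w <- motifWidth(m)
            lo <- start(regions)[r]; hi <- end(regions)[r] - w + 1L
            if (hi < lo) next
            busy <- IRanges::reduce(c(blocked, placed))
            free <- IRanges::setdiff(IRanges(lo, hi + w - 1L), busy)
            free <- free[width(free) >= w]
            if (!length(free)) next
            iv <- free[sample.int(length(free), 1L)]
            s <- start(iv) + sample.int(width(iv) - w + 1L, 1L) - 1L
            edits[[chr]] <- rbind(
                edits[[chr]],
                data.frame(start = s, end = s + w - 1L,
                           value = motifConsensus(m)))
            placed <- c(placed, IRanges(s, s + w - 1L))
            motifIds[[r]] <- c(motifIds[[r]], motifID(m))
        }
    }
    for (chr in names(edits)) {
        e <- edits[[chr]]
        seqs[[chr]] <- Biostrings::replaceAt(
            seqs[[chr]], IRanges(e$start, e$end), e$value)
    }
    mcols(regions)$motif_ids <- IRanges::CharacterList(
        lapply(motifIds, function(x) if (is.null(x)) character(0) else x))
    o <- order(as.character(seqnames(regions)), start(regions))
    regions <- regions[o]
    truth <- new("SyntheticTruth", regions = regions,
                 tfEffects = tfEffects, seed = as.integer(seed))
    genomeOut <- new("SyntheticGenome", sequences = seqs,
                     repeatMask = repeatMask(genome))
    list(truth = truth, genome = genomeOut)
}
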