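#' Simulate ATAC peaks and WGBS-like validation fixtures
#'
#' Emits (i) an accessibility peak set in which every hypo truth region
#' is overlapped by at least one peak and no hyper truth region is
#' overlapped by any peak — the structure the accessibility filter of
#' the DMR caller expects in cancer samples; (ii) per-CpG bisulfite
#' methylation calls (coverage Poisson, methylated counts binomial at
#' the truth methylation level) for a "healthy" and a "cancer"
#' condition over all CpGs within `callPad` bp of a truth region or
#' summit; and (iii) a width-1 summit set, one summit at the midpoint
#' of each hypo truth region, emulating TF binding summits inside
#' hypo-methylated regions.
#'
#' @param truth a [SyntheticTruth-class].
#' @param genome a [SyntheticGenome-class].
#' @param meanCoverage Poisson mean of per-CpG read coverage
#'   (default 10).
#' @param nNoisePeaks additional peaks placed away from all truth
#'   regions (default 50).
#' @param backgroundMeth methylation level of CpGs outside truth
#'   regions (default 0.75).
#' @param callPad padding around truth regions/summits in which CpG
#'   calls are emitted (default 500 bp).
#' @param seed integer seed.
#' @return list with `atacPeaks` (`GRanges`), `summits` (width-1
#'   `GRanges`), and `calls`: a list with elements `healthy` and
#'   `cancer`, each a data.frame with columns chrom, pos (1-based C
#'   position), coverage, methylated.
#' @export
simulateAtacAndValidationFixtures <- function(truth, genome,
                                              meanCoverage = 10,
                                              nNoisePeaks = 50L,
                                              backgroundMeth = 0.75,
                                              callPad = 500L, seed = 1L) {
    if (meanCoverage <= 0) stop("'meanCoverage' must be positive")
    set.seed(seed)
    regions <- truthRegions(truth)
    hypo <- regions[regions$direction == "hypo"]
    hyper <- regions[regions$direction == "hyper"]
    lens <- chromLengths(genome)

    ## one peak per hypo region, jittered to partially overlap it
    peaks <- GRanges()
    if (length(hypo)) {
        pad <- as.integer(stats::runif(length(hypo), 50, 200))
        s <- pmax(1L, start(hypo) - pad)
        e <- pmin(lens[as.character(seqnames(hypo))], end(hypo) + pad)
        peaks <- GRanges(seqnames(hypo), IRanges(s, e))
    }
    avoid <- regions + 500L
    avChr <- as.character(seqnames(avoid))
    nChr <- character(0); nStart <- numeric(0); nEnd <- numeric(0)
    tries <- 0L
    while (nNoisePeaks > 0L && length(nChr) < nNoisePeaks) {
        tries <- tries + 1L
        if (tries > 200L * nNoisePeaks) break
        chr <- sample(names(lens), 1L, prob = lens)
        w <- sample(300:1500, 1L)
        if (lens[chr] <= w) next
        s <- sample.int(lens[chr] - w, 1L)
        same <- avChr == chr
        if (any(same) && any(s <= end(avoid)[same] &
                             (s + w - 1L) >= start(avoid)[same]))
            next
        nChr <- c(nChr, chr); nStart <- c(nStart, s)
        nEnd <- c(nEnd, s + w - 1L)
    }
    if (length(nChr))
        peaks <- suppressWarnings(
            c(peaks, GRanges(nChr, IRanges(nStart, nEnd))))
    peaks <- sort(peaks, ignore.strand = TRUE)

    summits <- GenomicRanges::resize(hypo, width = 1L, fix = "center")

    ## per-CpG calls in the neighbourhood of truth regions and summits
    space <- IRanges::reduce(c(regions + callPad, summits + callPad),
                             ignore.strand = TRUE)
    seqs <- genomeSequences(genome)
    cg <- lapply(unique(as.character(seqnames(space))), function(chr) {
        m <- Biostrings::matchPattern("CG", seqs[[chr]])
        g <- GRanges(chr, IRanges(Biostrings::start(m), width = 2L))
        IRanges::subsetByOverlaps(g, space, ignore.strand = TRUE)
    })
    cg <- if (length(cg))
        sort(suppressWarnings(do.call(c, cg)), ignore.strand = TRUE)
    else GRanges()
    muH <- rep(backgroundMeth, length(cg))
    muC <- muH
    if (length(regions)) {
        hit <- GenomicRanges::findOverlaps(cg, regions,
                                           ignore.strand = TRUE)
        qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
        muH[qi] <- regions$healthy_mean[si]
        shift <- ifelse(regions$direction[si] == "hypo",
                        -regions$delta[si], regions$delta[si])
        muC[qi] <- regions$healthy_mean[si] + shift
    }
    drawCalls <- function(mu) {
        cov <- stats::rpois(length(cg), meanCoverage)
        meth <- stats::rbinom(length(cg), cov, mu)
        data.frame(chrom = as.character(seqnames(cg)), pos = start(cg),
                   coverage = cov, methylated = meth)
    }
    list(atacPeaks = peaks, summits = summits,
         calls = list(healthy = drawCalls(muH), cancer = drawCalls(muC)))
}
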