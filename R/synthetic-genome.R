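#' Generate a synthetic genome with repeat mask and chrY
#'
#' Chromosome sequences are drawn with iid base composition at the
#' requested G+C fraction. A `chrY` sequence (one tenth of the autosome
#' length, at least 10 kb) is always appended, and a configurable
#' fraction of each chromosome is covered by a repeat mask, so that the
#' exclusion rules applied when control regions are drawn (mappable,
#' non-repetitive, not on chromosome Y) can be exercised.
#'
#' @param nChrom number of autosome-like chromosomes (`chr1` ...).
#' @param chromLength length of each autosome in bp (>= 10000).
#' @param gcFraction target G+C fraction, strictly between 0 and 1.
#' @param repeatFraction fraction of each chromosome covered by repeat
#'   intervals (default 0.05).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return a [SyntheticGenome-class].
#' @examples
#' g <- generateGenome(1, 20000, 0.5, seed = 1)
#' chromLengths(g)
#' @export
generateGenome <- function(nChrom, chromLength, gcFraction,
                           repeatFraction = 0.05, seed = 1L) {
    checkCount(nChrom, "nChrom", min = 1L)
    checkCount(chromLength, "chromLength", min = 10000L)
    checkFraction(gcFraction, "gcFraction")
    checkFraction(repeatFraction, "repeatFraction", open = FALSE)
    set.seed(seed)
    probs <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
               G = gcFraction / 2, T = (1 - gcFraction) / 2)
    lens <- c(rep(chromLength, nChrom),
              max(10000L, as.integer(chromLength %/% 10)))
    nms <- c(paste0("chr", seq_len(nChrom)), "chrY")
    seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
        paste(sample(names(probs), L, replace = TRUE, prob = probs),
              collapse = "")
    }, character(1)))
    names(seqs) <- nms
    ## repeat intervals: random 200-2000 bp blocks until the target
    ## coverage is reached on each chromosome
    mask <- lapply(seq_along(lens), function(i) {
        target <- repeatFraction * lens[i]
        if (target < 1) return(GRanges())
        starts <- integer(0); ends <- integer(0); covered <- 0
        while (covered < target) {
            w <- sample(200:2000, 1L)
            s <- sample.int(max(1L, lens[i] - w), 1L)
            starts <- c(starts, s); ends <- c(ends, s + w - 1L)
            covered <- sum(width(IRanges::reduce(
                IRanges(starts, ends))))
        }
        GRanges(nms[i], IRanges::reduce(IRanges(starts, ends)))
    })
    mask <- sort(suppressWarnings(do.call(c, mask)),
                 ignore.strand = TRUE)
    new("SyntheticGenome", sequences = seqs, repeatMask = mask)
}

#' Generate a synthetic gene annotation
#'
#' Places `nGenes` non-overlapping genes on the autosomes of a
#' synthetic genome, each with a strand, a TSS and 1-4 exons; intervals
#' are reported as `GRanges` (1-based closed internally; exported files
#' use BED/GTF conventions).
#'
#' @param genome a [SyntheticGenome-class].
#' @param nGenes number of genes (0 allowed: empty annotation, all
#'   downstream proximity labels become "distal").
#' @param seed integer seed.
#' @return a list with `genes` (gene bodies, metadata `gene_id`), `tss`
#'   (width-1 ranges) and `exons` (metadata `gene_id`).
#' @export
generateAnnotation <- function(genome, nGenes, seed = 1L) {
    checkCount(nGenes, "nGenes", min = 0L)
    set.seed(seed)
    lens <- chromLengths(genome)
    auto <- lens[names(lens) != "chrY"]
    empty <- GRanges()
    if (nGenes == 0L)
        return(list(genes = empty, tss = empty, exons = empty))
    gChr <- character(0); gStart <- numeric(0); gEnd <- numeric(0)
    gStrand <- character(0)
    tries <- 0L
    while (length(gChr) < nGenes) {
        tries <- tries + 1L
        if (tries > 50L * nGenes)
            stop("genome too small to place ", nGenes,
                 " non-overlapping genes")
        chr <- sample(names(auto), 1L, prob = auto)
        gl <- sample(2000:8000, 1L)
        if (auto[chr] <= gl + 2L) next
        s <- sample.int(auto[chr] - gl, 1L)
        same <- gChr == chr
        if (any(same) && any(s <= gEnd[same] & (s + gl - 1L) >=
                             gStart[same]))
            next
        gChr <- c(gChr, chr); gStart <- c(gStart, s)
        gEnd <- c(gEnd, s + gl - 1L)
        gStrand <- c(gStrand, sample(c("+", "-"), 1L))
    }
    genes <- sort(GRanges(gChr, IRanges(gStart, gEnd),
                          strand = gStrand), ignore.strand = TRUE)
    mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
    tss <- GenomicRanges::resize(genes, width = 1L, fix = "start")
    mcols(tss)$gene_id <- genes$gene_id
    exons <- lapply(seq_along(genes), function(i) {
        g <- genes[i]
        nEx <- sample(1:4, 1L)
        gl <- width(g)
        ## split gene into nEx exon/intron alternations; first exon at TSS
        exw <- pmax(100L, as.integer(stats::runif(nEx, 100, gl / (2 * nEx))))
        gaps <- if (nEx > 1L)
            as.integer(stats::runif(nEx - 1L, 100, gl / (2 * nEx)))
        else integer(0)
        offs <- cumsum(c(0L, head(exw, -1L) + gaps))
        keep <- offs + exw <= gl
        offs <- offs[keep]; exw <- exw[keep]
        if (as.character(strand(g)) == "+") {
            st <- start(g) + offs
        } else {
            st <- end(g) - offs - exw + 1L
        }
        GRanges(seqnames(g), IRanges(st, width = exw), strand = strand(g),
                gene_id = g$gene_id)
    })
    exons <- sort(suppressWarnings(do.call(c, exons)),
                  ignore.strand = TRUE)
    list(genes = genes, tss = tss, exons = exons)
}

#' Generate a probe manifest at CpG dinucleotides
#'
#' Probes are placed at actual CG dinucleotides of the genome, a
#' binomially drawn fraction of them within 2 kb of a TSS to emulate
#' the promoter bias of methylation arrays. Probe ranges cover the CG
#' dinucleotide (width 2, start at the C).
#'
#' @param genome a [SyntheticGenome-class].
#' @param annotation result of [generateAnnotation()].
#' @param nProbes number of probes.
#' @param promoterFraction expected fraction of probes within 2 kb of a
#'   TSS.
#' @param seed integer seed.
#' @return a named, sorted `GRanges` of probes.
#' @export
generateManifest <- function(genome, annotation, nProbes,
                             promoterFraction = 0.3, seed = 1L) {
    checkCount(nProbes, "nProbes", min = 1L)
    checkFraction(promoterFraction, "promoterFraction", open = FALSE)
    set.seed(seed)
    seqs <- genomeSequences(genome)
    cg <- lapply(names(seqs), function(chr) {
        m <- Biostrings::matchPattern("CG", seqs[[chr]])
        GRanges(chr, IRanges(Biostrings::start(m), width = 2L))
    })
    cg <- suppressWarnings(do.call(c, cg))
    if (length(cg) < nProbes)
        stop("genome has only ", length(cg), " CpGs; cannot place ",
             nProbes, " probes")
    tss <- annotation$tss
    nearTSS <- if (length(tss)) {
        d <- GenomicRanges::distanceToNearest(cg, tss,
                                              ignore.strand = TRUE)
        prom <- rep(FALSE, length(cg))
        prom[S4Vectors::queryHits(d)] <- mcols(d)$distance <= 2000
        prom
    } else rep(FALSE, length(cg))
    nProm <- stats::rbinom(1L, nProbes, promoterFraction)
    nProm <- min(nProm, sum(nearTSS))
    nDist <- nProbes - nProm
    if (nDist > sum(!nearTSS)) {
        nDist <- sum(!nearTSS)
        nProm <- nProbes - nDist
        if (nProm > sum(nearTSS))
            stop("genome has too few CpGs outside promoters")
    }
    sel <- c(sample(which(nearTSS), nProm),
             sample(which(!nearTSS), nDist))
    probes <- sort(cg[sel], ignore.strand = TRUE)
    names(probes) <- sprintf("cg%07d", seq_along(probes))
    probes
}
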