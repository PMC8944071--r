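#' Mean methylation in windows around peak summits
#'
#' For each summit, takes the 200 bp window centred on it (`[summit -
#' 100, summit + 100)` in file coordinates), keeps per-CpG bisulfite
#' calls with coverage at least `minCoverage`, drops windows with
#' fewer than `minCpGs` eligible CpGs in any condition, and returns
#' the unweighted mean of the per-CpG methylated fractions per
#' condition.
#'
#' @param summits width-1 `GRanges` of peak summits.
#' @param calls named list of per-condition call tables (data.frame
#'   with `chrom`, `pos` (1-based C position), `coverage`,
#'   `methylated`).
#' @param window window width in bp (default 200).
#' @param minCpGs minimum eligible CpGs per window (default 2).
#' @param minCoverage minimum reads per CpG (default 5).
#' @return data.frame with the window coordinates and one mean-fraction
#'   column per condition; only windows eligible in every condition
#'   are returned.
#' @export
windowMeanMethylation <- function(summits, calls, window = 200L,
                                  minCpGs = 2L, minCoverage = 5L) {
    half <- as.integer(window %/% 2L)
    win <- GRanges(seqnames(summits),
                   IRanges(pmax(1L, start(summits) - half),
                           start(summits) + half - 1L))
    res <- data.frame(chrom = as.character(seqnames(win)),
                      start = start(win), end = end(win))
    keep <- rep(TRUE, length(win))
    for (cnd in names(calls)) {
        cc <- calls[[cnd]]
        cc <- cc[cc$coverage >= minCoverage, , drop = FALSE]
        cgr <- GRanges(cc$chrom, IRanges(cc$pos, width = 1L))
        hit <- GenomicRanges::findOverlaps(win, cgr,
                                           ignore.strand = TRUE)
        frac <- cc$methylated / cc$coverage
        qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
        n <- tabulate(qh, length(win))
        s <- rep(0, length(win))
        agg <- tapply(frac[sh], qh, sum)
        s[as.integer(names(agg))] <- agg
        keep <- keep & n >= minCpGs
        res[[paste0("mean_", cnd)]] <- ifelse(n > 0, s / n, NA_real_)
    }
    res[keep, , drop = FALSE]
}

#' Filter binding peaks affected by genomic amplification
#'
#' In amplified cancer genomes, read pileups can mimic binding peaks.
#' A peak is kept when its input-sample read density is below the
#' third quartile of the peak set's input densities
#' (linear-interpolation quantile) or when it is at least tenfold
#' enriched over the input.
#'
#' @param peaks data.frame (or `GRanges` with these metadata columns)
#'   carrying `input_density` and `fold_over_input` per peak.
#' @param foldThreshold enrichment override (default 10).
#' @return the kept peaks, same class as the input; the computed Q3 is
#'   attached as attribute `"q3"`.
#' @export
amplificationPeakFilter <- function(peaks, foldThreshold = 10) {
    dens <- if (is(peaks, "GRanges")) peaks$input_density
            else peaks$input_density
    fold <- if (is(peaks, "GRanges")) peaks$fold_over_input
            else peaks$fold_over_input
    if (length(dens) == 0L) {
        attr(peaks, "q3") <- NA_real_
        return(peaks)
    }
    q3 <- unname(stats::quantile(dens, 0.75, type = 7))
    keep <- dens < q3 | fold >= foldThreshold
    out <- peaks[keep, ]
    attr(out, "q3") <- q3
    out
}

#' Filter externally called bisulfite-sequencing DMRs
#'
#' Applies the reporting gates of the array DMR caller to regions
#' called from whole-genome bisulfite data: minimum length, minimum
#' absolute methylation change, and the starting-methylation rule in
#' the reference condition (above 50% for regions hypo-methylated in
#' the test condition, below 50% for hyper-methylated ones). A
#' provenance column records which gates each region passed.
#'
#' @param regions `GRanges` with metadata `direction`
#'   (`"hypo"`/`"hyper"`), `mean_delta` (test - reference) and
#'   `mean_reference` (mean methylation in the reference condition).
#' @param minDelta default 0.20 (`>=` on |mean_delta|).
#' @param minLength default 200 bp (`>=` on width).
#' @param startMethThreshold default 0.5.
#' @return the surviving `GRanges` with a `gates` metadata column
#'   (comma-separated gates passed) on the full input attached as
#'   attribute `"provenance"`.
#' @export
filterWgbsDmrs <- function(regions, minDelta = 0.20, minLength = 200,
                           startMethThreshold = 0.5) {
    if (!length(regions)) {
        attr(regions, "provenance") <- data.frame(
            length = logical(0), delta = logical(0), start = logical(0))
        return(regions)
    }
    okLen <- width(regions) >= minLength
    okDelta <- abs(regions$mean_delta) >= minDelta
    hypo <- regions$direction == "hypo"
    okStart <- ifelse(hypo,
                      regions$mean_reference > startMethThreshold,
                      regions$mean_reference < startMethThreshold)
    out <- regions[okLen & okDelta & okStart]
    attr(out, "provenance") <- data.frame(length = okLen,
                                          delta = okDelta,
                                          start = okStart)
    out
}

#' Overlap fold-enrichment of binding regions in one region set versus
#' another
#'
#' The fold is the fraction of set-A regions overlapping at least one
#' binding region divided by the same fraction for set B, with a
#' pseudocount of 1 on all four counts; the p-value is the one-sided
#' upper-tail hypergeometric on the pseudocounted urn (population
#' |A| + |B|, successes all overlapping regions, |A| draws).
#'
#' @param binding `GRanges` of binding regions (e.g. ChIP peaks).
#' @param setA,setB `GRanges` region sets (half-open in file
#'   coordinates; overlap by >= 1 bp counts).
#' @param pseudocount default 1.
#' @return one-row data.frame with the counts, `fold` and `p`.
#' @export
overlapFoldEnrichment <- function(binding, setA, setB,
                                  pseudocount = 1) {
    a <- sum(IRanges::overlapsAny(setA, binding, ignore.strand = TRUE))
    c <- sum(IRanges::overlapsAny(setB, binding, ignore.strand = TRUE))
    h <- pseudoHyper(a, length(setA), c, length(setB), pseudocount,
                     "one")
    data.frame(n_A_with = h$counts[["n_with"]],
               n_A_total = h$counts[["n_total"]],
               n_B_with = h$counts[["ctrl_with"]],
               n_B_total = h$counts[["ctrl_total"]],
               fold = h$fold, p = h$p)
}

#' Shuffle-based overlap enrichment
#'
#' Relocates every region of the set to a uniformly random start
#' within the shuffle space of its own chromosome (length preserved;
#' regions are placed independently), recomputes the fraction of
#' binding regions overlapping the shuffled set, and compares the
#' observed fraction with the null: fold = observed / mean(null),
#' empirical p = (1 + #\{null >= observed\}) / (1 + nShuffles). The
#' first `k` null draws are reproduced exactly when `nShuffles` is
#' increased with the same seed.
#'
#' @param binding `GRanges` of binding regions.
#' @param regions `GRanges` region set to shuffle.
#' @param shuffleSpace `GRanges` of allowed placement space
#'   (chromosome extents minus exclusions).
#' @param nShuffles number of shuffles (default 100).
#' @param seed integer seed.
#' @return list with `observed`, `nullMean`, `fold`, `p` and the
#'   vector of `null` fractions.
#' @export
shuffleOverlapEnrichment <- function(binding, regions, shuffleSpace,
                                     nShuffles = 100L, seed = 1L) {
    checkCount(nShuffles, "nShuffles", 1L)
    set.seed(seed)
    frac <- function(set) mean(IRanges::overlapsAny(
        binding, set, ignore.strand = TRUE))
    observed <- frac(regions)
    spaceByChr <- split(shuffleSpace,
                        as.character(seqnames(shuffleSpace)))
    nullFrac <- numeric(nShuffles)
    for (s in seq_len(nShuffles)) {
        newStarts <- integer(length(regions))
        newChrom <- character(length(regions))
        for (i in seq_along(regions)) {
            chr <- as.character(seqnames(regions[i]))
            w <- width(regions[i])
            sp <- spaceByChr[[chr]]
            if (is.null(sp))
                stop("no shuffle space on ", chr)
            room <- width(sp) - w + 1L
            ok <- room > 0L
            if (!any(ok))
                stop("region of width ", w, " does not fit in the ",
                     "shuffle space of ", chr)
            iv <- sample(which(ok), 1L, prob = room[ok])
            newStarts[i] <- start(sp)[iv] +
                sample.int(room[iv], 1L) - 1L
            newChrom[i] <- chr
        }
        shuf <- GRanges(newChrom,
                        IRanges(newStarts, width = width(regions)))
        nullFrac[s] <- frac(shuf)
    }
    nullMean <- mean(nullFrac)
    list(observed = observed, nullMean = nullMean,
         fold = if (nullMean > 0) observed / nullMean else Inf,
         p = (1 + sum(nullFrac >= observed)) / (1 + nShuffles),
         null = nullFrac)
}
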