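#' G+C content and observed/expected CpG ratio of a sequence
#'
#' `x` is the G+C fraction of the unambiguous bases and `y` the
#' observed-over-expected CpG ratio in the Gardiner-Garden form
#' `N_CpG * L / (N_C * N_G)` (0 when the sequence has no C or no G).
#' Case-insensitive; ambiguous bases are excluded from all counts.
#'
#' @param sequence a [Biostrings::DNAString] or character string of
#'   length >= 2.
#' @return list with `x` (GC content) and `y` (obs/exp CpG).
#' @examples
#' regionComposition("CGCGCG")  # x = 1, y = 2
#' @export
regionComposition <- function(sequence) {
    s <- toupper(as.character(sequence))
    if (nchar(s) < 2L) stop("sequence must have length >= 2")
    dna <- DNAString(s)
    base <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
    L <- sum(base)
    if (L == 0L) return(list(x = 0, y = 0))
    nC <- base[["C"]]; nG <- base[["G"]]
    x <- (nC + nG) / L
    nCpG <- length(Biostrings::matchPattern("CG", dna))
    y <- if (nC * nG == 0) 0 else nCpG * L / (nC * nG)
    list(x = unname(x), y = unname(y))
}

#' Classify a region as CpG-poor or CpG-rich
#'
#' Regions are split by the empirical boundary line
#' `y = -1.4 (x - 0.38) + 0.51` in the plane of G+C content (x)
#' against observed/expected CpG ratio (y): above the line is
#' `"rich"`, below (or exactly on it, the documented tie rule) is
#' `"poor"`.
#'
#' @param x G+C content.
#' @param y observed/expected CpG ratio.
#' @param slope,x0,y0 boundary line parameters (defaults -1.4, 0.38,
#'   0.51).
#' @return `"rich"` or `"poor"` (vectorised over x/y).
#' @export
classifyCpGClass <- function(x, y, slope = -1.4, x0 = 0.38, y0 = 0.51) {
    line <- slope * (x - x0) + y0
    ifelse(y > line, "rich", "poor")
}

#' Classify regions by distance to the nearest TSS
#'
#' The distance is the gap between the TSS point and the region
#' interval (0 when the TSS lies inside the region). Regions at most
#' `threshold` bp from a TSS (tie at exactly the threshold included)
#' are `"proximal"`, others `"distal"`. With no TSS on the chromosome
#' the region is distal with infinite distance.
#'
#' @param regions `GRanges`.
#' @param tss width-1 `GRanges` of transcription start sites.
#' @param threshold proximity threshold in bp (default 2000).
#' @return data.frame with `proximity` and `distance` per region.
#' @export
classifyProximity <- function(regions, tss, threshold = 2000) {
    dist <- rep(Inf, length(regions))
    if (length(tss)) {
        hit <- GenomicRanges::distanceToNearest(regions, tss,
                                                ignore.strand = TRUE)
        dist[S4Vectors::queryHits(hit)] <- mcols(hit)$distance
    }
    data.frame(proximity = ifelse(dist <= threshold, "proximal",
                                  "distal"),
               distance = dist)
}

#' Classify regions as promoter, intron or intergenic
#'
#' The region midpoint decides: promoter when within `promoterWindow`
#' bp of a TSS, else intron when inside a gene body, else intergenic
#' (precedence promoter > intron > intergenic).
#'
#' @param regions `GRanges`.
#' @param annotation result of [generateAnnotation()] (or any list
#'   with `tss` and `genes` `GRanges`).
#' @param promoterWindow promoter distance from TSS in bp
#'   (default 2000).
#' @return character vector of context labels.
#' @export
classifyContext <- function(regions, annotation,
                            promoterWindow = 2000) {
    mid <- GenomicRanges::resize(regions, width = 1L, fix = "center")
    ctx <- rep("intergenic", length(regions))
    if (length(annotation$genes))
        ctx[IRanges::overlapsAny(mid, annotation$genes,
                                 ignore.strand = TRUE)] <- "intron"
    if (length(annotation$tss)) {
        hit <- GenomicRanges::distanceToNearest(mid, annotation$tss,
                                                ignore.strand = TRUE)
        near <- S4Vectors::queryHits(hit)[
            mcols(hit)$distance <= promoterWindow]
        ctx[near] <- "promoter"
    }
    ctx
}

#' Annotate DMRs with composition, proximity and context labels
#'
#' Adds `gc_content`, `obs_exp_cpg`, `cpg_class`, `proximity`,
#' `distance` and `context` metadata columns to a region set, the
#' three classification axes being independent functions of the
#' region.
#'
#' @param dmrs `GRanges` of regions.
#' @param genome a [SyntheticGenome-class] (or a named
#'   `DNAStringSet`).
#' @param annotation result of [generateAnnotation()].
#' @return the annotated `GRanges`.
#' @export
annotateDMRs <- function(dmrs, genome, annotation) {
    seqs <- if (is(genome, "SyntheticGenome")) genomeSequences(genome)
            else genome
    if (!length(dmrs)) {
        for (col in c("gc_content", "obs_exp_cpg"))
            mcols(dmrs)[[col]] <- numeric(0)
        for (col in c("cpg_class", "proximity", "context"))
            mcols(dmrs)[[col]] <- character(0)
        mcols(dmrs)$distance <- numeric(0)
        return(dmrs)
    }
    comp <- t(vapply(seq_along(dmrs), function(i) {
        s <- Biostrings::subseq(seqs[[as.character(seqnames(dmrs[i]))]],
                                start(dmrs[i]), end(dmrs[i]))
        unlist(regionComposition(s))
    }, numeric(2)))
    mcols(dmrs)$gc_content <- comp[, "x"]
    mcols(dmrs)$obs_exp_cpg <- comp[, "y"]
    mcols(dmrs)$cpg_class <- classifyCpGClass(comp[, "x"], comp[, "y"])
    prox <- classifyProximity(dmrs, annotation$tss)
    mcols(dmrs)$proximity <- prox$proximity
    mcols(dmrs)$distance <- prox$distance
    mcols(dmrs)$context <- classifyContext(dmrs, annotation)
    dmrs
}
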