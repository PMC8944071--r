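#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges assayNames
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' BetaSet: probe-level methylation fractions with genomic coordinates
#'
#' A `BetaSet` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one assay, `"beta"`, of per-probe methylation fractions in
#' \[0,1\], with `rowRanges()` giving the CpG position of each probe
#' (width-2 ranges covering the CG dinucleotide) and a mandatory
#' `condition` column in `colData()` with levels `"healthy"` and
#' `"cancer"`.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("BetaSet", contains = "RangedSummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- NULL
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (any(!is.na(b) & (b < 0 | b > 1)))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (!"condition" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    else if (!all(object$condition %in% c("healthy", "cancer")))
        msg <- c(msg, "condition must be 'healthy' or 'cancer'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix, probes x samples, values in \[0,1\].
#' @param probes `GRanges` of probe positions (one per row of `beta`);
#'   names are probe ids.
#' @param condition character vector, one of `"healthy"`/`"cancer"` per
#'   sample (column).
#' @return a [BetaSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), width = 2))
#' names(gr) <- c("cg01", "cg02")
#' b <- matrix(runif(4), 2, dimnames = list(names(gr), c("s1", "s2")))
#' BetaSet(b, gr, c("healthy", "cancer"))
#' @export
BetaSet <- function(beta, probes, condition) {
    beta <- as.matrix(beta)
    if (length(probes) != nrow(beta))
        stop("'probes' must have one range per row of 'beta'")
    if (length(condition) != ncol(beta))
        stop("'condition' must have one entry per column of 'beta'")
    if (!is.null(names(probes)) && is.null(rownames(beta)))
        rownames(beta) <- names(probes)
    se <- SummarizedExperiment(
        assays = list(beta = beta),
        rowRanges = probes,
        colData = DataFrame(condition = as.character(condition))
    )
    new("BetaSet", se)
}

#' @describeIn BetaSet the beta-value matrix.
#' @param object,x a `BetaSet`.
#' @export
betaValues <- function(object) SummarizedExperiment::assay(object, "beta")

#' @describeIn BetaSet the per-sample condition labels.
#' @export
sampleCondition <- function(object) object$condition

setMethod("show", "BetaSet", function(object) {
    cnd <- table(object$condition)
    cat("BetaSet with", nrow(object), "probes and", ncol(object),
        "samples (", paste(names(cnd), cnd, sep = "=", collapse = ", "),
        ")\n")
})

#' SyntheticGenome: simulated genome with repeat/mappability annotation
#'
#' Holds the chromosome sequences of a simulated genome together with a
#' repeat mask (intervals regarded as non-mappable by short reads). The
#' complement of the repeat mask is the mappable space used when control
#' regions are placed.
#'
#' @slot sequences a [Biostrings::DNAStringSet], one entry per chromosome
#'   (a `"chrY"` entry is always present so sex-chromosome exclusion
#'   rules can be exercised).
#' @slot repeatMask a `GRanges` of masked (repeat-like) intervals.
#' @export
setClass("SyntheticGenome",
    representation(sequences = "DNAStringSet", repeatMask = "GRanges"))

setValidity("SyntheticGenome", function(object) {
    msg <- NULL
    if (is.null(names(object@sequences)))
        msg <- c(msg, "chromosome sequences must be named")
    if (!"chrY" %in% names(object@sequences))
        msg <- c(msg, "a 'chrY' sequence must be present")
    bad <- !as.character(seqnames(object@repeatMask)) %in%
        names(object@sequences)
    if (any(bad))
        msg <- c(msg, "repeatMask on unknown chromosome")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SyntheticGenome chromosome sequences.
#' @param object a `SyntheticGenome`.
#' @export
genomeSequences <- function(object) object@sequences

#' @describeIn SyntheticGenome masked repeat intervals.
#' @export
repeatMask <- function(object) object@repeatMask

#' @describeIn SyntheticGenome named vector of chromosome lengths.
#' @export
chromLengths <- function(object) {
    stats::setNames(Biostrings::width(object@sequences),
                    names(object@sequences))
}

setMethod("show", "SyntheticGenome", function(object) {
    cat("SyntheticGenome with", length(object@sequences),
        "chromosomes,", sum(Biostrings::width(object@sequences)),
        "bp total;", length(object@repeatMask), "repeat intervals\n")
})

#' SyntheticTruth: ground truth of a simulated methylation study
#'
#' Records the regions of planted differential methylation, the motif
#' instances embedded in them and the TF expression effects, so that
#' downstream recovery can be scored.
#'
#' @slot regions a `GRanges` with metadata columns `direction`
#'   (`"hypo"`/`"hyper"`), `delta` (methylation-fraction change in
#'   cancer), `healthy_mean` (mean methylation in healthy samples) and
#'   `motif_ids` (`CharacterList` of embedded motif ids).
#' @slot tfEffects named numeric vector of planted log2 fold-changes,
#'   names are gene/TF ids.
#' @slot seed integer seed used by the generator.
#' @export
setClass("SyntheticTruth",
    representation(regions = "GRanges", tfEffects = "numeric",
                   seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- NULL
    r <- object@regions
    need <- c("direction", "delta", "healthy_mean", "motif_ids")
    if (!all(need %in% colnames(mcols(r))))
        msg <- c(msg, paste("regions need metadata columns:",
                            paste(need, collapse = ", ")))
    else {
        if (!all(r$direction %in% c("hypo", "hyper")))
            msg <- c(msg, "direction must be 'hypo' or 'hyper'")
        if (any(width(r) < 200))
            msg <- c(msg, "planted regions must be at least 200 bp")
        hypo <- r$direction == "hypo"
        if (any(hypo & r$healthy_mean <= 0.5))
            msg <- c(msg, "hypo regions need healthy mean > 0.5")
        if (any(!hypo & r$healthy_mean >= 0.5))
            msg <- c(msg, "hyper regions need healthy mean < 0.5")
        if (length(r) > 1L) {
            hits <- GenomicRanges::findOverlaps(r, r)
            if (length(hits) > length(r))
                msg <- c(msg, "planted regions must not overlap")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SyntheticTruth planted regions with their attributes.
#' @param object a `SyntheticTruth`.
#' @export
truthRegions <- function(object) object@regions

#' @describeIn SyntheticTruth planted TF log2 fold-changes.
#' @export
tfEffects <- function(object) object@tfEffects

setMethod("show", "SyntheticTruth", function(object) {
    d <- table(object@regions$direction)
    cat("SyntheticTruth:", length(object@regions), "planted regions (",
        paste(names(d), d, sep = "=", collapse = ", "), "),",
        length(object@tfEffects), "TF effects, seed",
        object@seed, "\n")
})

#' Motif: a position frequency matrix with information-content summaries
#'
#' Base frequencies per motif column together with the derived
#' per-column information content, total information content (bits), the
#' information-weighted mean G+C frequency and its rich/poor/medium
#' class. These summaries drive the genome-scan p-value threshold
#' (2^-IC) and the GC classing used when enrichment results are
#' reported.
#'
#' @slot id motif identifier.
#' @slot tf character vector of TF names the motif represents.
#' @slot matrix 4 x width numeric matrix of base frequencies, rows
#'   A, C, G, T; columns sum to 1.
#' @slot localIC numeric, information content per column (bits).
#' @slot ic numeric(1), total information content.
#' @slot gcFreq numeric, per-column G+C frequency.
#' @slot meanGC numeric(1), IC-weighted mean of `gcFreq`.
#' @slot gcClass `"rich"` (> 0.75), `"poor"` (< 0.25) or `"medium"`.
#' @slot cluster integer(1) cluster id (NA until clustering).
#' @export
setClass("Motif",
    representation(id = "character", tf = "character", matrix = "matrix",
                   localIC = "numeric", ic = "numeric", gcFreq = "numeric",
                   meanGC = "numeric", gcClass = "character",
                   cluster = "integer"))

setValidity("Motif", function(object) {
    m <- object@matrix
    msg <- NULL
    if (nrow(m) != 4L)
        msg <- c(msg, "frequency matrix must have 4 rows (A, C, G, T)")
    if (any(abs(colSums(m) - 1) > 1e-6))
        msg <- c(msg, "frequency columns must sum to 1 (tolerance 1e-6)")
    if (any(m < 0))
        msg <- c(msg, "frequencies must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn Motif frequency matrix (rows A, C, G, T).
#' @param object a `Motif`.
#' @export
motifMatrix <- function(object) object@matrix

#' @describeIn Motif total information content in bits.
#' @export
motifIC <- function(object) object@ic

#' @describeIn Motif motif width (number of columns).
#' @export
motifWidth <- function(object) ncol(object@matrix)

#' @describeIn Motif motif identifier.
#' @export
motifID <- function(object) object@id

#' @describeIn Motif TF name(s) associated with the motif.
#' @export
motifTF <- function(object) object@tf

#' @describeIn Motif IC-weighted mean G+C frequency and class.
#' @export
motifMeanGC <- function(object) object@meanGC

#' @describeIn Motif GC class ("rich", "poor" or "medium").
#' @export
motifGCClass <- function(object) object@gcClass

#' @describeIn Motif consensus sequence (highest-frequency base per
#'   column, ties broken in A<C<G<T order).
#' @export
motifConsensus <- function(object) {
    paste(rownames(object@matrix)[apply(object@matrix, 2, which.max)],
          collapse = "")
}

setMethod("show", "Motif", function(object) {
    cat(sprintf("Motif %s (%s): width %d, IC %.2f bits, mean GC %.2f (%s)\n",
                object@id, paste(object@tf, collapse = "/"),
                motifWidth(object), object@ic, object@meanGC,
                object@gcClass))
})
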