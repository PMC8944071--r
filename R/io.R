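#' Write and read the plain-file study formats
#'
#' All interval files follow the BED convention (0-based, half-open);
#' internal `GRanges` are 1-based closed, and these helpers perform
#' the conversion. The beta matrix TSV has columns `probe`, `chrom`,
#' `pos` (0-based C position) and one column per sample.
#'
#' @param beta a [BetaSet-class].
#' @param path output file.
#' @return the path, invisibly (writers); the parsed object (readers).
#' @name study-io
NULL

#' @rdname study-io
#' @export
writeBetaMatrix <- function(beta, path) {
    gr <- rowRanges(beta)
    df <- data.frame(probe = names(gr),
                     chrom = as.character(seqnames(gr)),
                     pos = start(gr) - 1L,
                     betaValues(beta), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname study-io
#' @param sampleSheet data.frame with columns `sample`, `condition`,
#'   or the path of such a TSV.
#' @export
readBetaMatrix <- function(path, sampleSheet) {
    df <- utils::read.delim(path, check.names = FALSE)
    if (is.character(sampleSheet))
        sampleSheet <- utils::read.delim(sampleSheet)
    samples <- as.character(sampleSheet$sample)
    missing <- setdiff(samples, colnames(df))
    if (length(missing))
        stop("samples absent from beta matrix: ",
             paste(missing, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$pos + 1L, width = 2L))
    names(gr) <- df$probe
    BetaSet(as.matrix(df[, samples, drop = FALSE]), gr,
            as.character(sampleSheet$condition))
}

#' @rdname study-io
#' @param x object to write (see individual writers).
#' @export
writeSampleSheet <- function(x, path) {
    df <- data.frame(sample = colnames(x),
                     condition = sampleCondition(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname study-io
#' @param manifest probe `GRanges`.
#' @export
writeManifest <- function(manifest, path) {
    df <- data.frame(probe = names(manifest),
                     chrom = as.character(seqnames(manifest)),
                     pos = start(manifest) - 1L, strand = "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname study-io
#' @export
readManifest <- function(path) {
    df <- utils::read.delim(path)
    gr <- GRanges(df$chrom, IRanges(df$pos + 1L, width = 2L))
    names(gr) <- df$probe
    gr
}

#' @rdname study-io
#' @param genome a [SyntheticGenome-class].
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genomeSequences(genome), path)
    invisible(path)
}

#' @rdname study-io
#' @param regions `GRanges` to write as BED6 (name from `names()` or a
#'   `direction`/`name` column; score column `score` if present, else
#'   0).
#' @export
writeBed <- function(regions, path) {
    nm <- if (!is.null(names(regions)) && any(nzchar(names(regions))))
        names(regions)
    else if ("direction" %in% colnames(mcols(regions)))
        regions$direction
    else if ("name" %in% colnames(mcols(regions))) regions$name
    else rep(".", length(regions))
    sc <- if ("score" %in% colnames(mcols(regions))) regions$score
          else rep(0, length(regions))
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = nm, score = sc,
                     strand = ifelse(as.character(strand(regions)) ==
                                     "*", ".",
                                     as.character(strand(regions))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname study-io
#' @export
readBed <- function(path) {
    df <- utils::read.delim(path, header = FALSE)
    gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
    if (ncol(df) >= 4L) names(gr) <- as.character(df[[4]])
    if (ncol(df) >= 5L) mcols(gr)$score <- df[[5]]
    gr
}

#' @rdname study-io
#' @param dmrs annotated DMR `GRanges`.
#' @export
writeDmrTable <- function(dmrs, path) {
    df <- data.frame(chrom = as.character(seqnames(dmrs)),
                     start = start(dmrs) - 1L, end = end(dmrs))
    keep <- setdiff(colnames(mcols(dmrs)), "cpg_ids")
    df <- cbind(df, as.data.frame(mcols(dmrs)[, keep, drop = FALSE]))
    if ("cpg_ids" %in% colnames(mcols(dmrs)))
        df$cpg_ids <- vapply(dmrs$cpg_ids, paste, character(1),
                             collapse = ",")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname study-io
#' @param truth a [SyntheticTruth-class].
#' @export
writeTruthJSON <- function(truth, path) {
    r <- truthRegions(truth)
    obj <- list(
        planted_regions = data.frame(
            chrom = as.character(seqnames(r)), start = start(r) - 1L,
            end = end(r), direction = r$direction, delta = r$delta,
            healthy_mean = r$healthy_mean,
            embedded_motif_ids = vapply(r$motif_ids, paste,
                                        character(1), collapse = ",")),
        tf_effects = as.list(tfEffects(truth)),
        seed = truth@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname study-io
#' @param annotation result of [generateAnnotation()].
#' @export
writeAnnotationGTF <- function(annotation, path) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("rtracklayer is required to write GTF")
    genes <- annotation$genes
    mcols(genes)$type <- "gene"
    exons <- annotation$exons
    mcols(exons)$type <- "exon"
    gr <- c(genes, exons)
    mcols(gr)$source <- "methTF"
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}
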