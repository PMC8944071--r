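#' Simulate a complete synthetic methylation study
#'
#' Orchestrates all generators into one study: genome, annotation,
#' probe manifest, planted truth regions with optional embedded motif
#' consensus instances, beta-value matrix, expression table, and the
#' accessibility / bisulfite validation fixtures. One global seed fans
#' out to per-generator child seeds via [childSeed()] (counters 1-7 in
#' the order below), so the generators' streams are independent of
#' one another.
#'
#' The defaults reproduce the package's benchmark study conditions:
#' 8 autosomes of 2 Mb at GC 0.5, 80 genes, 40,000 probes with 30%
#' promoter bias, 120 hypo plus 80 hyper planted regions of
#' methylation change 0.3 spanning at least 3 probes, 20 healthy and
#' 20 cancer samples at Beta precision 30.
#'
#' @param seed global integer seed.
#' @param nChrom,chromLength,gcFraction,repeatFraction see
#'   [generateGenome()].
#' @param nGenes see [generateAnnotation()].
#' @param nProbes,promoterFraction see [generateManifest()].
#' @param nHypo,nHyper,delta,minProbes,embedMotifs,embedRate,tfEffects
#'   see [plantRegionsAndMotifs()]; `nHypo = nHyper = 0` gives a null
#'   study.
#' @param nHealthy,nCancer,phi see [simulateBetaMatrix()].
#' @param expressionGenes optional extra gene ids (e.g. TF names) to
#'   include in the expression table in addition to the annotation's
#'   genes.
#' @param dispersion see [simulateExpression()].
#' @param meanCoverage see [simulateAtacAndValidationFixtures()].
#' @return list with `genome`, `annotation`, `manifest`, `truth`,
#'   `beta` (a [BetaSet-class]), `expression`, `fixtures` (ATAC peaks,
#'   summits, bisulfite calls) and `seed`.
#' @export
simulateStudy <- function(seed = 1L, nChrom = 8L, chromLength = 2e6,
                          gcFraction = 0.5, repeatFraction = 0.05,
                          nGenes = 80L, nProbes = 40000L,
                          promoterFraction = 0.3, nHypo = 120L,
                          nHyper = 80L, delta = 0.3, minProbes = 3L,
                          embedMotifs = list(), embedRate = 0,
                          tfEffects = stats::setNames(numeric(0),
                                                      character(0)),
                          nHealthy = 20L, nCancer = 20L, phi = 30,
                          expressionGenes = character(0),
                          dispersion = 0.2, meanCoverage = 10) {
    genome <- generateGenome(nChrom, chromLength, gcFraction,
                             repeatFraction, seed = childSeed(seed, 1L))
    annotation <- generateAnnotation(genome, nGenes,
                                     seed = childSeed(seed, 2L))
    manifest <- generateManifest(genome, annotation, nProbes,
                                 promoterFraction,
                                 seed = childSeed(seed, 3L))
    if (nHypo + nHyper > 0L) {
        pl <- plantRegionsAndMotifs(genome, manifest, annotation,
                                    nHypo = nHypo, nHyper = nHyper,
                                    delta = delta,
                                    embedMotifs = embedMotifs,
                                    embedRate = embedRate,
                                    minProbes = minProbes,
                                    tfEffects = tfEffects,
                                    seed = childSeed(seed, 4L))
        truth <- pl$truth
        genome <- pl$genome
    } else {
        truth <- new("SyntheticTruth",
                     regions = GRanges(direction = character(0),
                                       delta = numeric(0),
                                       healthy_mean = numeric(0),
                                       motif_ids = IRanges::CharacterList()),
                     tfEffects = tfEffects, seed = as.integer(seed))
    }
    beta <- simulateBetaMatrix(manifest, truth, nHealthy, nCancer,
                               phi = phi, seed = childSeed(seed, 5L))
    geneIds <- unique(c(annotation$genes$gene_id, expressionGenes,
                        names(tfEffects)))
    expression <- simulateExpression(geneIds, tfEffects, nHealthy,
                                     nCancer, dispersion = dispersion,
                                     seed = childSeed(seed, 6L))
    fixtures <- simulateAtacAndValidationFixtures(
        truth, genome, meanCoverage = meanCoverage,
        seed = childSeed(seed, 7L))
    list(genome = genome, annotation = annotation, manifest = manifest,
         truth = truth, beta = beta, expression = expression,
         fixtures = fixtures, seed = as.integer(seed))
}

#' Score DMR recovery against the planted truth
#'
#' A called DMR counts as correct when it overlaps a truth region of
#' the same direction by at least 1 bp; recall is the fraction of
#' truth regions overlapped by a correct call and precision the
#' fraction of calls that are correct.
#'
#' @param called DMR `GRanges` with a `direction` column.
#' @param truth a [SyntheticTruth-class] or truth-region `GRanges`.
#' @return list with `recall`, `precision`, `nCalled`, `nTruth`.
#' @export
scoreRecovery <- function(called, truth) {
    regions <- if (is(truth, "SyntheticTruth")) truthRegions(truth)
               else truth
    if (!length(regions))
        return(list(recall = NA_real_,
                    precision = if (length(called)) 0 else NA_real_,
                    nCalled = length(called), nTruth = 0L))
    if (!length(called))
        return(list(recall = 0, precision = NA_real_, nCalled = 0L,
                    nTruth = length(regions)))
    hit <- GenomicRanges::findOverlaps(called, regions,
                                       ignore.strand = TRUE)
    sameDir <- called$direction[S4Vectors::queryHits(hit)] ==
        regions$direction[S4Vectors::subjectHits(hit)]
    hit <- hit[sameDir]
    recall <- length(unique(S4Vectors::subjectHits(hit))) /
        length(regions)
    precision <- length(unique(S4Vectors::queryHits(hit))) /
        length(called)
    list(recall = recall, precision = precision,
         nCalled = length(called), nTruth = length(regions))
}
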