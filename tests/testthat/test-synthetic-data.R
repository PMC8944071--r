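test_that("generated genomes hit the requested composition and carry chrY", {
    g <- generateGenome(1, 100000, 0.5, seed = 1)
    expect_setequal(names(genomeSequences(g)), c("chr1", "chrY"))
    gc <- sum(Biostrings::letterFrequency(genomeSequences(g)[["chr1"]],
                                          c("C", "G"))) / 100000
    expect_lt(abs(gc - 0.5), 0.02)  # binomial CI at n = 100k
    ## repeat mask within bounds and roughly at the requested coverage
    rm <- repeatMask(g)
    expect_true(all(GenomicRanges::end(rm) <=
                    chromLengths(g)[as.character(
                        GenomicRanges::seqnames(rm))]))
    expect_error(generateGenome(1, 100000, 1.0, seed = 1), "gcFraction")
    expect_error(generateGenome(1, 5000, 0.5, seed = 1), "chromLength")
})

test_that("generators are pure functions of their seed", {
    g1 <- generateGenome(2, 20000, 0.4, seed = 7)
    g2 <- generateGenome(2, 20000, 0.4, seed = 7)
    expect_identical(as.character(genomeSequences(g1)),
                     as.character(genomeSequences(g2)))
    a1 <- generateAnnotation(g1, 5, seed = 3)
    a2 <- generateAnnotation(g2, 5, seed = 3)
    expect_identical(a1$exons, a2$exons)
    m1 <- generateManifest(g1, a1, 200, seed = 9)
    m2 <- generateManifest(g2, a2, 200, seed = 9)
    expect_identical(m1, m2)
})

test_that("annotation stays inside the genome and supports n_genes = 0", {
    g <- generateGenome(1, 100000, 0.5, seed = 2)
    a <- generateAnnotation(g, 10, seed = 2)
    expect_length(a$tss, 10)
    expect_true(all(GenomicRanges::end(a$genes) <= 100000))
    expect_true(all(GenomicRanges::start(a$exons) >= 1))
    ## every gene has at least one exon
    expect_true(all(a$genes$gene_id %in% a$exons$gene_id))
    a0 <- generateAnnotation(g, 0, seed = 2)
    expect_length(a0$tss, 0)
    prox <- classifyProximity(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(5000, 5200)), a0$tss)
    expect_equal(prox$proximity, "distal")
    expect_equal(prox$distance, Inf)
})

test_that("manifest probes sit on CpGs with the requested promoter bias", {
    g <- generateGenome(2, 200000, 0.5, seed = 4)
    a <- generateAnnotation(g, 20, seed = 4)
    mf <- generateManifest(g, a, 1000, promoterFraction = 0.6, seed = 4)
    expect_length(mf, 1000)
    expect_false(is.unsorted(GenomicRanges::start(
        mf[GenomicRanges::seqnames(mf) == "chr1"])))
    ## every probe covers an actual CG dinucleotide
    dinuc <- as.character(getRegionSeqs(g, mf))
    expect_true(all(dinuc == "CG"))
    nearTSS <- GenomicRanges::distanceToNearest(mf, a$tss,
                                                ignore.strand = TRUE)
    nProm <- sum(S4Vectors::mcols(nearTSS)$distance <= 2000)
    expect_lt(abs(nProm - 600), 60)   # binomial tolerance
    expect_error(generateManifest(g, a, 10^7, seed = 1), "CpGs")
})

test_that("planted regions respect the truth invariants", {
    g <- generateGenome(2, 500000, 0.5, seed = 5)
    a <- generateAnnotation(g, 20, seed = 5)
    mf <- generateManifest(g, a, 4000, seed = 5)
    pl <- plantRegionsAndMotifs(g, mf, a, nHypo = 15, nHyper = 10,
                                delta = 0.3, seed = 5)
    tr <- truthRegions(pl$truth)
    expect_length(tr, 25)
    expect_true(all(GenomicRanges::width(tr) >= 200))
    expect_true(all(GenomicRanges::countOverlaps(tr, mf) >= 2))
    hypo <- tr$direction == "hypo"
    expect_true(all(tr$healthy_mean[hypo] > 0.5))
    expect_true(all(tr$healthy_mean[!hypo] < 0.5))
    ## pairwise non-overlap
    expect_equal(length(GenomicRanges::findOverlaps(tr, tr)), length(tr))
    ## no genome edits without embedding
    expect_identical(as.character(genomeSequences(pl$genome)),
                     as.character(genomeSequences(g)))
})

test_that("motif embedding edits hypo regions at the requested rate", {
    g <- generateGenome(2, 500000, 0.5, seed = 6)
    a <- generateAnnotation(g, 10, seed = 6)
    mf <- generateManifest(g, a, 4000, seed = 6)
    m <- consensusMotif("planted", "ACGTACGTAC")
    pl <- plantRegionsAndMotifs(g, mf, a, nHypo = 50, nHyper = 0,
                                embedMotifs = list(m), embedRate = 0.8,
                                seed = 6)
    tr <- truthRegions(pl$truth)
    nEmb <- sum(lengths(tr$motif_ids) > 0)
    expect_lt(abs(nEmb - 40), 9)    # binomial tolerance around 0.8 * 50
    ## embedded regions contain the consensus verbatim; probes intact
    seqs <- getRegionSeqs(pl$genome, tr)
    found <- Biostrings::vcountPattern("ACGTACGTAC", seqs) > 0
    expect_identical(unname(found), unname(lengths(tr$motif_ids) > 0))
    expect_true(all(as.character(getRegionSeqs(pl$genome, mf)) == "CG"))
})

test_that("beta simulation reproduces the planted means and the null", {
    g <- generateGenome(1, 300000, 0.5, seed = 8)
    a <- generateAnnotation(g, 5, seed = 8)
    mf <- generateManifest(g, a, 2000, seed = 8)
    pl <- plantRegionsAndMotifs(g, mf, a, nHypo = 10, nHyper = 0,
                                delta = 0.3, seed = 8)
    b <- simulateBetaMatrix(mf, pl$truth, 50, 50, phi = 30, seed = 8)
    tr <- truthRegions(pl$truth)
    inReg <- IRanges::overlapsAny(
        SummarizedExperiment::rowRanges(b), tr)
    bm <- betaValues(b)
    cancer <- sampleCondition(b) == "cancer"
    mH <- rowMeans(bm[inReg, !cancer]); mC <- rowMeans(bm[inReg, cancer])
    hit <- GenomicRanges::findOverlaps(
        SummarizedExperiment::rowRanges(b)[inReg], tr)
    mu <- tr$healthy_mean[S4Vectors::subjectHits(hit)]
    expect_true(all(abs(mH - mu) < 0.05))
    expect_true(all(abs(mC - (mu - 0.3)) < 0.05))
    ## null: no planted regions
    nullTruth <- new("SyntheticTruth",
                     regions = GenomicRanges::GRanges(
                         direction = character(0), delta = numeric(0),
                         healthy_mean = numeric(0),
                         motif_ids = IRanges::CharacterList()),
                     tfEffects = stats::setNames(numeric(0),
                                                 character(0)),
                     seed = 1L)
    b0 <- simulateBetaMatrix(mf, nullTruth, 30, 30, seed = 9)
    d <- rowMeans(betaValues(b0)[, 31:60]) -
         rowMeans(betaValues(b0)[, 1:30])
    expect_lt(max(abs(d)), 0.15)
    expect_lt(abs(mean(d)), 0.005)
    expect_error(simulateBetaMatrix(mf, nullTruth, 5, 5, phi = -1),
                 "phi")
    expect_identical(betaValues(simulateBetaMatrix(mf, nullTruth, 3, 3,
                                                   seed = 11)),
                     betaValues(simulateBetaMatrix(mf, nullTruth, 3, 3,
                                                   seed = 11)))
})

test_that("expression simulation plants fold-changes on the FPKM scale", {
    genes <- sprintf("gene%03d", 1:200)
    eff <- c(gene001 = 2)
    ex <- simulateExpression(genes, eff, 30, 30, dispersion = 0.2,
                             seed = 12)
    expect_true(all(ex$fpkm >= 0))
    mh <- rowMeans(ex$fpkm[, ex$condition == "healthy"])
    mc <- rowMeans(ex$fpkm[, ex$condition == "cancer"])
    expect_lt(abs(log2(mc["gene001"] / mh["gene001"]) - 2), 0.3)
    ## null genes do not pass a log2FC threshold of 1
    lfc <- log2((mc[-1] + 0.5) / (mh[-1] + 0.5))
    expect_lt(mean(abs(lfc) > 1), 0.01)
    expect_error(simulateExpression(genes, c(nosuch = 1), 5, 5),
                 "nosuch")
})

test_that("validation fixtures honour the accessibility construction", {
    g <- generateGenome(2, 400000, 0.5, seed = 13)
    a <- generateAnnotation(g, 10, seed = 13)
    mf <- generateManifest(g, a, 3000, seed = 13)
    pl <- plantRegionsAndMotifs(g, mf, a, nHypo = 12, nHyper = 8,
                                seed = 13)
    fx <- simulateAtacAndValidationFixtures(pl$truth, g,
                                            meanCoverage = 10,
                                            seed = 13)
    tr <- truthRegions(pl$truth)
    hypo <- tr[tr$direction == "hypo"]
    hyper <- tr[tr$direction == "hyper"]
    expect_true(all(IRanges::overlapsAny(hypo, fx$atacPeaks)))
    expect_false(any(IRanges::overlapsAny(hyper, fx$atacPeaks)))
    ## coverage >= 5 fraction matches the Poisson tail P(X >= 5 | 10)
    cov <- fx$calls$healthy$coverage
    expect_lt(abs(mean(cov >= 5) - stats::ppois(4, 10,
                                                lower.tail = FALSE)),
              0.02)
    expect_true(all(fx$calls$cancer$methylated <=
                    fx$calls$cancer$coverage))
})

test_that("planted-effect recovery is monotone in delta and sample size", {
    ## detection recall: reporting filters off, because at delta equal
    ## to the 20%-change gate the filter censors each region with
    ## probability ~1/2 regardless of n (see the methods vignette)
    recallAt <- function(delta, n) {
        study <- simulateStudy(seed = 21, nChrom = 3,
                               chromLength = 1e6, nGenes = 30,
                               nProbes = 12000, nHypo = 25, nHyper = 15,
                               delta = delta, nHealthy = n, nCancer = n)
        dmrs <- suppressMessages(callDMRs(
            study$beta, exons = study$annotation$exons,
            atacPeaks = study$fixtures$atacPeaks,
            minLength = 0, minDelta = 0))
        scoreRecovery(dmrs, study$truth)$recall
    }
    grid <- expand.grid(delta = c(0.2, 0.4), n = c(10, 40))
    rec <- mapply(recallAt, grid$delta, grid$n)
    ## larger delta never hurts at fixed n; larger n never hurts at
    ## fixed delta
    expect_gte(rec[2], rec[1]); expect_gte(rec[4], rec[3])
    expect_gte(rec[3], rec[1]); expect_gte(rec[4], rec[2])
    expect_gte(rec[4], 0.9)
})
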