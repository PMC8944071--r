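mkCalls <- function(pos, cov, meth, chrom = "chr1") {
    data.frame(chrom = chrom, pos = pos, coverage = cov,
               methylated = meth)
}

test_that("window means follow the coverage and CpG-count rules", {
    summit <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(1000, width = 1))
    calls <- list(
        healthy = mkCalls(c(950, 1050, 1080), c(10, 10, 4),
                          c(2, 4, 4)),
        cancer = mkCalls(c(950, 1050), c(10, 10), c(9, 9)))
    wm <- windowMeanMethylation(summit, calls)
    ## coverage-4 CpG excluded; means over the two eligible CpGs
    expect_equal(wm$mean_healthy, 0.3)
    expect_equal(wm$mean_cancer, 0.9)
    ## a window with one eligible CpG is dropped
    calls1 <- list(healthy = mkCalls(c(950), 10, 5),
                   cancer = mkCalls(c(950), 10, 5))
    expect_equal(nrow(windowMeanMethylation(summit, calls1)), 0)
})

test_that("amplification filter combines the Q3 and tenfold rules", {
    peaks <- data.frame(input_density = c(1, 2, 3, 4),
                        fold_over_input = c(2, 2, 2, 12))
    kept <- amplificationPeakFilter(peaks)
    expect_equal(attr(kept, "q3"), 3.25)    # linear interpolation
    ## density 4 kept only through the fold rule
    expect_true(4 %in% kept$input_density)
    peaks$fold_over_input[4] <- 2
    kept2 <- amplificationPeakFilter(peaks)
    expect_false(4 %in% kept2$input_density)
    expect_true(1 %in% kept2$input_density)
})

test_that("bisulfite DMR filters mirror the array gates", {
    mk <- function(w, dir, md, mr) {
        gr <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(100, width = w))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            direction = dir, mean_delta = md, mean_reference = mr)
        gr
    }
    expect_length(filterWgbsDmrs(mk(250, "hypo", -0.25, 0.45)), 0)
    expect_length(filterWgbsDmrs(mk(250, "hypo", -0.25, 0.80)), 1)
    expect_length(filterWgbsDmrs(mk(250, "hypo", -0.19, 0.80)), 0)
    expect_length(filterWgbsDmrs(mk(150, "hypo", -0.25, 0.80)), 0)
    expect_length(filterWgbsDmrs(mk(250, "hyper", 0.25, 0.30)), 1)
})

test_that("overlap fold-enrichment reuses the pseudocounted urn", {
    binding <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(100, 5000), width = 50))
    A <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(90, 4990), width = 200))
    B <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(9000, 12000),
                                                 width = 200))
    r <- overlapFoldEnrichment(binding, A, B)
    expect_equal(r$fold, 3.0)
    expect_equal(r$p, 0.2)             # identical urn to the motif case
    ## equal overlap fractions: fold 1
    expect_equal(overlapFoldEnrichment(binding, A, A)$fold, 1)
    ## invariant to interval order within sets
    r2 <- overlapFoldEnrichment(binding, rev(A), rev(B))
    expect_equal(r2$p, r$p)
})

test_that("shuffle enrichment obeys its formula and seeding contract", {
    set.seed(81)
    binding <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(sample.int(90000, 40), width = 100))
    space <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    ## region set covering the whole space: fold 1, p 1
    full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    rs <- shuffleOverlapEnrichment(binding, full, space,
                                   nShuffles = 20, seed = 5)
    expect_equal(rs$fold, 1)
    expect_equal(rs$p, 1)
    ## an observed fraction above all null draws gives p = 1/(n+1)
    regions <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(GenomicRanges::start(binding),
                                 width = 100))
    ro <- shuffleOverlapEnrichment(binding, regions, space,
                                   nShuffles = 99, seed = 6)
    expect_equal(ro$observed, 1)
    expect_equal(ro$p, 1 / 100)
    ## doubling nShuffles reproduces the first half of the null stream
    r1 <- shuffleOverlapEnrichment(binding, regions, space,
                                   nShuffles = 10, seed = 7)
    r2 <- shuffleOverlapEnrichment(binding, regions, space,
                                   nShuffles = 20, seed = 7)
    expect_equal(r2$null[1:10], r1$null)
    ## a region wider than the space is a placement failure
    wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200000))
    expect_error(shuffleOverlapEnrichment(binding, wide, space,
                                          nShuffles = 2, seed = 1),
                 "fit")
})

test_that("shuffle null is calibrated for uniformly placed regions", {
    set.seed(82)
    space <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200000))
    binding <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(sample.int(199000, 60), width = 150))
    ps <- vapply(1:25, function(k) {
        regions <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(sample.int(198000, 25),
                                     width = 400))
        shuffleOverlapEnrichment(binding, regions, space,
                                 nShuffles = 19, seed = 900 + k)$p
    }, numeric(1))
    ## super-uniform: P(p <= 0.05) should not exceed the nominal level
    ## by more than binomial noise
    expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 25))
})

test_that("summit windows in planted hypo regions show cancer hypo-methylation", {
    study <- simulateStudy(seed = 83, nChrom = 4, chromLength = 1.2e6,
                           nGenes = 40, nProbes = 20000, nHypo = 110,
                           nHyper = 0)
    fx <- study$fixtures
    wm <- windowMeanMethylation(fx$summits, fx$calls)
    expect_gte(nrow(wm), 100)
    wt <- wilcox.test(wm$mean_cancer, wm$mean_healthy, paired = TRUE,
                      alternative = "less")
    expect_lt(wt$p.value, 0.01)
})
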