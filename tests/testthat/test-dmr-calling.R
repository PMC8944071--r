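test_that("unmoderated per-CpG t equals the hand-computed pooled t", {
    b <- matrix(c(0.30, 0.35, 0.25, 0.55, 0.60, 0.50,
                  0.70, 0.72, 0.68, 0.71, 0.69, 0.70), 2, 6,
                byrow = TRUE)
    bs <- toyBetaSet(b, rep(c("healthy", "cancer"), each = 3))
    st <- cpgStats(bs, moderated = FALSE)
    ## hand computation for probe 1
    h <- b[1, 1:3]; c1 <- b[1, 4:6]
    sp2 <- (2 * var(h) + 2 * var(c1)) / 4
    tHand <- (mean(c1) - mean(h)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(st$t[1], tHand, tolerance = 1e-10)
    expect_equal(st$p[1], 2 * pt(-abs(tHand), 4), tolerance = 1e-10)
    expect_equal(st$delta[1], mean(c1) - mean(h), tolerance = 1e-12)
})

test_that("a probe identical in both groups gives zero moderated t", {
    set.seed(10)
    b <- matrix(runif(50 * 8, 0.2, 0.8), 50, 8)
    b[7, ] <- 0.42                      # constant probe
    bs <- toyBetaSet(b, rep(c("healthy", "cancer"), each = 4))
    st <- cpgStats(bs)
    expect_equal(st$delta[7], 0)
    expect_equal(st$t[7], 0)
    expect_equal(st$p[7], 1)
    expect_error(cpgStats(toyBetaSet(b[, 1:3],
                                     c("healthy", "cancer", "cancer"))),
                 "healthy")
})

test_that("per-CpG p-values are calibrated under the null", {
    set.seed(11)
    mu <- runif(5000, 0.2, 0.8)
    b <- matrix(rbeta(5000 * 40, mu * 30, (1 - mu) * 30), 5000, 40)
    bs <- toyBetaSet(b, rep(c("healthy", "cancer"), each = 20))
    st <- cpgStats(bs)
    expect_lt(abs(mean(st$p < 0.05) - 0.05), 0.01)
})

test_that("exon exclusion follows half-open file conventions", {
    ## probes at file positions 50, 100, ..., 300 (internal = file + 1)
    pos <- c(51L, 101L, 151L, 201L, 251L, 301L)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 2))
    S4Vectors::mcols(gr)$probe <- sprintf("cg%02d", seq_along(pos))
    ## exon [150, 250) in file coordinates -> internal [151, 250]
    exon <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150 + 1, 250))
    kept <- suppressMessages(excludeExonic(gr, exon))
    filePos <- GenomicRanges::start(kept) - 1L
    ## CpG at the exon start coordinate (150, inclusive) removed; CpG
    ## at the exon end coordinate (250, exclusive) kept
    expect_false(150 %in% filePos)
    expect_true(250 %in% filePos)
    expect_length(kept, 4)
})

test_that("kernel smoothing matches locality expectations", {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1000, 50000),
                                                  width = 2))
    S4Vectors::mcols(gr)$t <- c(3.2, 3.2)
    sm <- kernelSmooth(gr)
    ## isolated CpGs: smoothed z equals the raw t
    expect_equal(sm$smoothed_z, c(3.2, 3.2), tolerance = 1e-12)
    expect_equal(sm$smoothed_p, rep(2 * pnorm(-3.2), 2),
                 tolerance = 1e-12)
    bad <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(500, 100),
                                                   width = 2))
    S4Vectors::mcols(bad)$t <- c(1, 1)
    expect_error(kernelSmooth(bad), "increasing")
})

test_that("kernel smoothing equals the O(n^2) brute force", {
    set.seed(12)
    pos <- sort(sample.int(2e5, 400))
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 2))
    S4Vectors::mcols(gr)$t <- rnorm(400)
    sm <- kernelSmooth(gr, lambda = 1000, C = 2)
    expect_equal(sm$smoothed_z, bruteSmooth(pos, gr$t), tolerance = 1e-10)
})

test_that("candidate grouping follows the lambda gap rule", {
    pos <- c(1, 501, 2001)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 2))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        probe = as.character(1:3), smoothed_p = rep(1e-5, 3),
        q = rep(1e-3, 3))
    cand <- callCandidateRegions(gr, lambda = 1000)
    expect_length(cand, 2)
    expect_equal(unname(lengths(cand)), c(2L, 1L))
    ## no significant CpG: zero regions
    S4Vectors::mcols(gr)$smoothed_p <- 0.5
    expect_length(callCandidateRegions(gr), 0)
    ## five CpGs 100 bp apart form a single region
    gr5 <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, 401, 100),
                                                   width = 2))
    S4Vectors::mcols(gr5) <- S4Vectors::DataFrame(
        probe = as.character(1:5), smoothed_p = rep(1e-5, 5),
        q = rep(1e-3, 5))
    expect_equal(unname(lengths(callCandidateRegions(gr5))), 5L)
})

test_that("consistent subregions split by delta sign", {
    mkStats <- function(deltas) {
        gr <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(seq_along(deltas) * 150, width = 2))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            probe = sprintf("cg%d", seq_along(deltas)), delta = deltas,
            mean_healthy = rep(0.7, length(deltas)))
        gr
    }
    r1 <- extractConsistentSubregions(mkStats(c(-0.3, -0.3, -0.3)),
                                      list(1:3))
    expect_length(r1, 1)
    expect_equal(r1$direction, "hypo")
    expect_equal(r1$n_cpg, 3L)
    ## end extended to cover the final CpG dinucleotide
    expect_equal(GenomicRanges::width(r1), 3 * 150 - 150 + 2)
    r2 <- extractConsistentSubregions(mkStats(c(-0.3, -0.3, 0.3, 0.3)),
                                      list(1:4))
    expect_equal(r2$direction, c("hypo", "hyper"))
    expect_equal(r2$n_cpg, c(2L, 2L))
    r3 <- extractConsistentSubregions(mkStats(c(-0.3, 0.3, -0.3)),
                                      list(1:3))
    expect_length(r3, 0)
})

test_that("reporting filters apply the length, delta and start rules", {
    mkRegion <- function(w, dir, md, mh) {
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000,
                                                              width = w))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            direction = dir, n_cpg = 3L, mean_delta = md,
            mean_healthy = mh,
            cpg_ids = IRanges::CharacterList(list(c("a", "b", "c"))))
        gr
    }
    expect_length(filterDMRs(mkRegion(150, "hypo", -0.3, 0.8)), 0)
    expect_length(filterDMRs(mkRegion(300, "hypo", -0.3, 0.40)), 0)
    expect_length(filterDMRs(mkRegion(300, "hypo", -0.19, 0.80)), 0)
    expect_length(filterDMRs(mkRegion(300, "hyper", 0.25, 0.30)), 1)
    ## exact boundaries: length 200 and |delta| 0.20 pass, healthy 0.5
    ## fails both direction rules
    expect_length(filterDMRs(mkRegion(200, "hypo", -0.20, 0.51)), 1)
    expect_length(filterDMRs(mkRegion(200, "hypo", -0.20, 0.50)), 0)
    expect_length(filterDMRs(mkRegion(200, "hyper", 0.20, 0.50)), 0)
})

test_that("the accessibility filter keeps open hypo and closed hyper", {
    dmr <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1000, 5000),
                                                   width = 300))
    S4Vectors::mcols(dmr)$direction <- c("hypo", "hyper")
    ## peak overlapping the hypo DMR by exactly 1 bp
    peak1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1299, 1500))
    kept <- atacFilter(dmr, peak1)
    expect_equal(kept$direction, c("hypo", "hyper"))
    ## hyper DMR inside a peak is rejected
    peak2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4900, 5600))
    expect_equal(atacFilter(dmr, c(peak1, peak2))$direction, "hypo")
    ## empty peaks: all hypo rejected, all hyper kept
    expect_equal(atacFilter(dmr, GenomicRanges::GRanges())$direction,
                 "hyper")
})
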