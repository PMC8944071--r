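test_that("the pseudocounted enrichment reproduces the worked example", {
    r <- enrichmentVsControls(c(TRUE, TRUE), c(FALSE, FALSE))
    expect_equal(r$fold, 3.0)
    expect_equal(r$p, 0.2)            # C(4,3)C(2,0)/C(6,3) = 4/20
    expect_false(r$enriched)
    ## identical presence rates: fold 1, p > 0.5
    null <- enrichmentVsControls(c(TRUE, FALSE), c(TRUE, FALSE))
    expect_equal(null$fold, 1.0)
    expect_gt(null$p, 0.5)
})

test_that("hypergeometric tails match exhaustive enumeration", {
    for (b in 1:4) for (d in 1:4) for (a in 0:b) for (cc in 0:d) {
        one <- enrichmentVsControls(rep(c(TRUE, FALSE), c(a, b - a)),
                                    rep(c(TRUE, FALSE), c(cc, d - cc)))
        N <- b + d + 2; K <- a + cc + 2; n <- b + 1
        expect_equal(one$p, enumUpperTail(a + 1, N, K, n),
                     tolerance = 1e-12)
        two <- enrichmentHypoVsHyper(rep(c(TRUE, FALSE), c(a, b - a)),
                                     rep(c(TRUE, FALSE), c(cc, d - cc)))
        expect_equal(two$p,
                     min(1, 2 * min(enumUpperTail(a + 1, N, K, n),
                                    enumLowerTail(a + 1, N, K, n))),
                     tolerance = 1e-12)
    }
})

test_that("two-sided enrichment is symmetric and caps at 1", {
    sym <- enrichmentHypoVsHyper(c(TRUE, TRUE, FALSE),
                                 c(TRUE, TRUE, FALSE))
    expect_equal(sym$p, 1)
    a <- c(rep(TRUE, 5)); b <- c(rep(FALSE, 5))
    r1 <- enrichmentHypoVsHyper(a, b)
    r2 <- enrichmentHypoVsHyper(b, a)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    expect_equal(r1$fold, 1 / r2$fold, tolerance = 1e-12)
    ## matches 2x the exact tail on the pseudocounted table
    expect_equal(r1$p, min(1, 2 * min(enumUpperTail(6, 12, 7, 6),
                                      enumLowerTail(6, 12, 7, 6))),
                 tolerance = 1e-12)
})

test_that("enrichment is invariant to region order", {
    set.seed(61)
    dm <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    ct <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(.2, .8))
    r1 <- enrichmentVsControls(dm, ct)
    r2 <- enrichmentVsControls(sample(dm), sample(ct))
    expect_equal(r1$fold, r2$fold)
    expect_equal(r1$p, r2$p)
})

test_that("motif clustering groups copies and reverse complements", {
    m <- randomMotifSet(1, width = 8, seed = 62)[[1]]
    copy <- Motif("copy", motifMatrix(m))
    rc <- Motif("rc", motifMatrix(m)[4:1, 8:1])
    ## two width-6 motifs dissimilar on both orientations (A-rich vs
    ## C-rich columns; the reverse complement of C-rich is G-rich)
    f1 <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), 6), 4, 6)
    f2 <- matrix(rep(c(0.1, 0.7, 0.1, 0.1), 6), 4, 6)
    far1 <- Motif("far1", f1); far2 <- Motif("far2", f2)
    cl <- clusterMotifs(list(m, copy, rc, far1, far2), threshold = 0.5)
    ids <- vapply(cl, function(x) x@cluster, integer(1))
    expect_equal(ids[1], ids[2])
    expect_equal(ids[1], ids[3])
    expect_true(ids[4] != ids[1])
    expect_true(ids[4] != ids[5])     # anti-correlated columns
    one <- clusterMotifs(list(m))
    expect_equal(one[[1]]@cluster, 1L)
})

test_that("matched controls satisfy every matching constraint", {
    study <- simulateStudy(seed = 63, nChrom = 3, chromLength = 1e6,
                           nGenes = 30, nProbes = 12000, nHypo = 12,
                           nHyper = 0)
    tr <- truthRegions(study$truth)
    names(tr) <- paste0("r", seq_along(tr))
    ann <- annotateDMRs(tr, study$genome, study$annotation)
    ctrl <- suppressWarnings(suppressMessages(generateMatchedControls(
        ann, study$genome, study$manifest, study$annotation,
        nPerDmr = 4, seed = 64)))
    expect_gt(length(ctrl), 0)
    probesOf <- function(gr) GenomicRanges::countOverlaps(
        gr, study$manifest, ignore.strand = TRUE)
    for (id in unique(ctrl$dmr_id)) {
        d <- ann[id]
        cc <- ctrl[ctrl$dmr_id == id]
        expect_true(all(GenomicRanges::width(cc) ==
                        GenomicRanges::width(d)))
        tol <- if (any(cc$relaxed)) 1L else 0L
        expect_true(all(abs(probesOf(cc) - probesOf(d)) <= tol))
        expect_equal(classifyProximity(cc,
                                       study$annotation$tss)$proximity,
                     rep(d$proximity, length(cc)))
        expect_equal(classifyContext(cc, study$annotation),
                     rep(d$context, length(cc)))
        compEq <- vapply(seq_along(cc), function(i) {
            s <- as.character(getRegionSeqs(study$genome, cc[i]))
            comp <- regionComposition(s)
            classifyCpGClass(comp$x, comp$y)
        }, character(1))
        expect_equal(compEq, rep(d$cpg_class, length(cc)))
    }
    expect_false(any(as.character(GenomicRanges::seqnames(ctrl)) ==
                     "chrY"))
    expect_false(any(IRanges::overlapsAny(ctrl, repeatMask(study$genome))))
    expect_false(any(IRanges::overlapsAny(ctrl, ann)))
    ## determinism and parameter validation
    ctrl2 <- suppressWarnings(suppressMessages(generateMatchedControls(
        ann, study$genome, study$manifest, study$annotation,
        nPerDmr = 4, seed = 64)))
    expect_identical(as.data.frame(ctrl), as.data.frame(ctrl2))
    expect_error(generateMatchedControls(ann, study$genome,
                                         study$manifest,
                                         study$annotation, nPerDmr = 0),
                 "nPerDmr")
})
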