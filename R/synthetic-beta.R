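#' Simulate a probe-level beta-value matrix with planted effects
#'
#' Per probe and sample, the methylation fraction is drawn from a
#' Beta(mu * phi, (1 - mu) * phi) distribution, so that values keep the
#' bounded support of array beta values with mean mu and precision phi.
#' Outside planted regions mu is a per-probe baseline shared by both
#' groups, drawn from a bimodal mixture (lowly and highly methylated
#' compartments) that mimics the typical array beta distribution.
#' Inside a planted region, healthy samples use the region's
#' `healthy_mean` and cancer samples the mean shifted by `-delta`
#' (hypo) or `+delta` (hyper).
#'
#' @param manifest probe `GRanges`.
#' @param truth a [SyntheticTruth-class] (may contain zero regions for
#'   a null simulation).
#' @param nHealthy,nCancer samples per group.
#' @param phi Beta precision (> 0; > 2 recommended so draws are
#'   unimodal around the mean; default 30).
#' @param lowFraction fraction of background probes in the lowly
#'   methylated compartment (default 0.4).
#' @param seed integer seed.
#' @return a [BetaSet-class]; sample names `H001...`/`C001...`.
#' @export
simulateBetaMatrix <- function(manifest, truth, nHealthy, nCancer,
                               phi = 30, lowFraction = 0.4, seed = 1L) {
    checkCount(nHealthy, "nHealthy", 1L); checkCount(nCancer, "nCancer", 1L)
    if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
        stop("'phi' must be a positive number")
    checkFraction(lowFraction, "lowFraction", open = FALSE)
    set.seed(seed)
    nP <- length(manifest)
    low <- stats::runif(nP) < lowFraction
    mu0 <- ifelse(low, stats::rbeta(nP, 5, 20), stats::rbeta(nP, 20, 5))
    mu0 <- pmin(pmax(mu0, 0.02), 0.98)
    muH <- mu0
    muC <- mu0
    regions <- truthRegions(truth)
    if (length(regions)) {
        hit <- GenomicRanges::findOverlaps(manifest, regions,
                                           ignore.strand = TRUE)
        qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
        muH[qi] <- regions$healthy_mean[si]
        shift <- ifelse(regions$direction[si] == "hypo",
                        -regions$delta[si], regions$delta[si])
        muC[qi] <- regions$healthy_mean[si] + shift
    }
    ## rbeta(shape1 = mu*phi, shape2 = (1-mu)*phi)
    bH <- matrix(stats::rbeta(nP * nHealthy, rep(muH, nHealthy) * phi,
                              rep(1 - muH, nHealthy) * phi), nrow = nP)
    bC <- matrix(stats::rbeta(nP * nCancer, rep(muC, nCancer) * phi,
                              rep(1 - muC, nCancer) * phi), nrow = nP)
    beta <- cbind(bH, bC)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    colnames(beta) <- c(sprintf("H%03d", seq_len(nHealthy)),
                        sprintf("C%03d", seq_len(nCancer)))
    rownames(beta) <- names(manifest)
    BetaSet(beta, manifest,
            c(rep("healthy", nHealthy), rep("cancer", nCancer)))
}

#' Simulate a gene-by-sample FPKM expression table
#'
#' FPKM values are log-normal: per gene, a baseline log2 level is drawn
#' once and shared by both groups; genes named in `tfEffects` are
#' shifted by the stated log2 fold-change in the cancer group. Sample
#' noise is normal on the log2 scale with standard deviation
#' `dispersion`.
#'
#' @param geneIds character vector of gene ids.
#' @param tfEffects named numeric vector of planted log2 fold-changes;
#'   all names must appear in `geneIds`.
#' @param nHealthy,nCancer samples per group.
#' @param dispersion sd of log2 FPKM within a group (default 0.2).
#' @param baselineMean,baselineSD distribution of per-gene baseline
#'   log2 FPKM (defaults 3 and 1.5).
#' @param seed integer seed.
#' @return list with `fpkm` (genes x samples matrix, nonnegative) and
#'   `condition` (per-sample labels).
#' @export
simulateExpression <- function(geneIds, tfEffects = c(), nHealthy,
                               nCancer, dispersion = 0.2,
                               baselineMean = 3, baselineSD = 1.5,
                               seed = 1L) {
    checkCount(nHealthy, "nHealthy", 1L); checkCount(nCancer, "nCancer", 1L)
    if (length(tfEffects)) {
        bad <- setdiff(names(tfEffects), geneIds)
        if (length(bad))
            stop("tfEffects name unknown gene(s): ",
                 paste(bad, collapse = ", "))
    }
    set.seed(seed)
    nG <- length(geneIds)
    base <- stats::rnorm(nG, baselineMean, baselineSD)
    eff <- stats::setNames(rep(0, nG), geneIds)
    eff[names(tfEffects)] <- tfEffects
    n <- nHealthy + nCancer
    isCancer <- c(rep(0, nHealthy), rep(1, nCancer))
    lg <- outer(base, rep(1, n)) + outer(eff, isCancer) +
        matrix(stats::rnorm(nG * n, 0, dispersion), nG, n)
    fpkm <- 2^lg
    rownames(fpkm) <- geneIds
    colnames(fpkm) <- c(sprintf("H%03d", seq_len(nHealthy)),
                        sprintf("C%03d", seq_len(nCancer)))
    list(fpkm = fpkm,
         condition = c(rep("healthy", nHealthy), rep("cancer", nCancer)))
}
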