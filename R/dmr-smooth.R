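#' Gaussian-kernel smoothing of signed t statistics
#'
#' For CpGs at positions x with statistics t, using a Gaussian kernel
#' of bandwidth sigma = lambda / C truncated at |dx| <= lambda, the
#' smoothed statistic at CpG i is
#' `S_i = sum_j w_ij t_j / sum_j w_ij` with
#' `w_ij = exp(-(x_i - x_j)^2 / (2 sigma^2))`. Treating the per-CpG t
#' statistics as independent and approximately standard normal under
#' the null, `Var_i = sum_j w_ij^2 / (sum_j w_ij)^2`, giving
#' `z_i = S_i / sqrt(Var_i)` and the two-sided normal p-value
#' `2 Phi(-|z_i|)`. Because the t is signed (unlike a smoothed t^2 /
#' chi-square formulation), regions of opposite methylation change
#' cannot reinforce each other.
#'
#' @param stats CpG `GRanges` with metadata column `t`, positions
#'   strictly increasing within each chromosome.
#' @param lambda kernel truncation half-width in bp (default 1000).
#' @param C kernel scaling, sigma = lambda / C (default 2).
#' @return `stats` with metadata columns `smoothed_z` and
#'   `smoothed_p` added.
#' @export
kernelSmooth <- function(stats, lambda = 1000, C = 2) {
    if (lambda <= 0 || C <= 0) stop("'lambda' and 'C' must be positive")
    if (!length(stats)) {
        mcols(stats)$smoothed_z <- numeric(0)
        mcols(stats)$smoothed_p <- numeric(0)
        return(stats)
    }
    sigma <- lambda / C
    z <- numeric(length(stats))
    chroms <- as.character(seqnames(stats))
    for (chr in unique(chroms)) {
        idx <- which(chroms == chr)
        x <- start(stats)[idx]
        if (is.unsorted(x, strictly = TRUE))
            stop("positions must be strictly increasing within ", chr)
        tt <- stats$t[idx]
        n <- length(x)
        zc <- numeric(n)
        lo <- 1L
        hi <- 1L
        for (i in seq_len(n)) {
            while (x[i] - x[lo] > lambda) lo <- lo + 1L
            if (hi < i) hi <- i
            while (hi < n && x[hi + 1L] - x[i] <= lambda) hi <- hi + 1L
            w <- exp(-(x[i] - x[lo:hi])^2 / (2 * sigma^2))
            sw <- sum(w)
            S <- sum(w * tt[lo:hi]) / sw
            V <- sum(w^2) / sw^2
            zc[i] <- S / sqrt(V)
        }
        z[idx] <- zc
    }
    mcols(stats)$smoothed_z <- z
    mcols(stats)$smoothed_p <- 2 * stats::pnorm(-abs(z))
    stats
}
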