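## Pseudocounted hypergeometric machinery shared by motif enrichment
## and the peak/DMR overlap statistics. With a = regions of interest
## containing the feature, b = their total, c/d the same for the
## comparison set, each incremented by the pseudocount, the urn has
## population b + d, successes a + c, and b draws; the one-sided
## p-value is the upper tail P(X >= a).
pseudoHyper <- function(a, b, c, d, pseudocount = 1,
                        sided = c("one", "two")) {
    sided <- match.arg(sided)
    a <- a + pseudocount; b <- b + pseudocount
    c <- c + pseudocount; d <- d + pseudocount
    fold <- (a / b) / (c / d)
    upper <- stats::phyper(a - 1, a + c, b + d - a - c, b,
                           lower.tail = FALSE)
    if (sided == "one") {
        p <- upper
    } else {
        lower <- stats::phyper(a, a + c, b + d - a - c, b)
        p <- min(1, 2 * min(upper, lower))
    }
    list(fold = fold, p = p,
         counts = c(n_with = a, n_total = b,
                    ctrl_with = c, ctrl_total = d))
}

#' Motif enrichment of DMRs against matched controls
#'
#' Counts regions containing at least one motif occurrence in the DMR
#' set and in the control set, adds a pseudocount of 1 to all four
#' counts, and reports the fold (percent of DMRs with the motif over
#' the percent of controls) with a one-sided upper-tail hypergeometric
#' p-value. A motif is flagged enriched when p < 0.001.
#'
#' @param dmrHas logical vector: DMR contains >= 1 occurrence.
#' @param ctrlHas logical vector for the control regions.
#' @param pseudocount added to all four counts (default 1).
#' @param pThreshold enrichment flag threshold (default 0.001).
#' @return one-row data.frame with pseudocounted counts, `fold`, `p`,
#'   `sided` and `enriched`.
#' @examples
#' enrichmentVsControls(c(TRUE, TRUE), c(FALSE, FALSE))  # fold 3, p 0.2
#' @export
enrichmentVsControls <- function(dmrHas, ctrlHas, pseudocount = 1,
                                 pThreshold = 0.001) {
    h <- pseudoHyper(sum(dmrHas), length(dmrHas), sum(ctrlHas),
                     length(ctrlHas), pseudocount, "one")
    data.frame(n_dmr_with = h$counts[["n_with"]],
               n_dmr_total = h$counts[["n_total"]],
               n_ctrl_with = h$counts[["ctrl_with"]],
               n_ctrl_total = h$counts[["ctrl_total"]],
               fold = h$fold, p = h$p, sided = "one",
               enriched = h$p < pThreshold)
}

#' Motif enrichment of hypo- versus hyper-methylated DMRs
#'
#' Same counting as [enrichmentVsControls()] with the hyper-methylated
#' DMRs playing the control role, but with a two-sided p-value
#' (2 x min(upper tail, lower tail), capped at 1) so depletion is
#' tested as well.
#'
#' @param hypoHas,hyperHas logical presence vectors.
#' @inheritParams enrichmentVsControls
#' @return one-row data.frame as in [enrichmentVsControls()].
#' @export
enrichmentHypoVsHyper <- function(hypoHas, hyperHas, pseudocount = 1,
                                  pThreshold = 0.001) {
    h <- pseudoHyper(sum(hypoHas), length(hypoHas), sum(hyperHas),
                     length(hyperHas), pseudocount, "two")
    data.frame(n_dmr_with = h$counts[["n_with"]],
               n_dmr_total = h$counts[["n_total"]],
               n_ctrl_with = h$counts[["ctrl_with"]],
               n_ctrl_total = h$counts[["ctrl_total"]],
               fold = h$fold, p = h$p, sided = "two",
               enriched = h$p < pThreshold)
}

## similarity of two frequency matrices: best mean column-wise Pearson
## correlation over ungapped offsets with >= minOverlap overlapping
## columns, considering the reverse complement of the second motif
motifSimilarity <- function(f1, f2, minOverlap = 4L) {
    colCor <- function(a, b) {
        if (stats::sd(a) == 0 || stats::sd(b) == 0)
            return(if (isTRUE(all.equal(a, b))) 1 else 0)
        stats::cor(a, b)
    }
    best <- -Inf
    f2rc <- f2[4:1, rev(seq_len(ncol(f2))), drop = FALSE]
    for (g in list(f2, f2rc)) {
        w1 <- ncol(f1); w2 <- ncol(g)
        for (off in seq(-(w2 - minOverlap), w1 - minOverlap)) {
            j1 <- seq(max(1L, 1L + off), min(w1, w2 + off))
            j2 <- j1 - off
            if (length(j1) < minOverlap) next
            cs <- vapply(seq_along(j1), function(k)
                colCor(f1[, j1[k]], g[, j2[k]]), numeric(1))
            best <- max(best, mean(cs))
        }
    }
    best
}

#' Cluster motifs by frequency-matrix similarity
#'
#' Pairwise similarity is the best (over ungapped offsets with at
#' least `minOverlap` overlapping columns, including the reverse
#' complement) mean column-wise Pearson correlation of the frequency
#' columns. Motifs are grouped by average-linkage hierarchical
#' clustering on distance 1 - similarity, cut at `threshold`.
#'
#' @param motifs list of [Motif-class] objects.
#' @param threshold cut height on the 1 - similarity distance
#'   (default 0.05).
#' @param minOverlap minimum overlapping columns (default 4).
#' @return the motif list with `cluster` slots filled; cluster ids are
#'   integers in order of the first motif of each cluster.
#' @export
clusterMotifs <- function(motifs, threshold = 0.05, minOverlap = 4L) {
    n <- length(motifs)
    if (n == 0L) stop("need at least one motif")
    if (n == 1L) {
        motifs[[1]]@cluster <- 1L
        return(motifs)
    }
    sim <- matrix(1, n, n)
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            sim[i, j] <- sim[j, i] <- motifSimilarity(
                motifMatrix(motifs[[i]]), motifMatrix(motifs[[j]]),
                minOverlap)
    dm <- 1 - sim
    dm[dm < 0] <- 0
    d <- stats::as.dist(dm)
    hc <- stats::hclust(d, method = "average")
    raw <- stats::cutree(hc, h = threshold)
    ids <- match(raw, unique(raw))  # renumber in motif order
    for (i in seq_len(n)) motifs[[i]]@cluster <- as.integer(ids[i])
    motifs
}
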