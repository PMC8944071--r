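## Independent oracles and small fixture builders used across tests.

## Exhaustive hypergeometric tails from first principles (choose()),
## independent of stats::phyper. Population N, K successes, n draws.
enumUpperTail <- function(a, N, K, n) {
    ks <- max(0, n - (N - K)):min(n, K)
    mass <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
    sum(mass[ks >= a])
}
enumLowerTail <- function(a, N, K, n) {
    ks <- max(0, n - (N - K)):min(n, K)
    mass <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
    sum(mass[ks <= a])
}

## O(n^2) brute-force kernel smoother (double loop over all CpG pairs).
bruteSmooth <- function(pos, tstat, lambda = 1000, C = 2) {
    sigma <- lambda / C
    n <- length(pos)
    z <- numeric(n)
    for (i in seq_len(n)) {
        S <- 0; W <- 0; W2 <- 0
        for (j in seq_len(n)) {
            dx <- abs(pos[i] - pos[j])
            if (dx > lambda) next
            w <- exp(-dx^2 / (2 * sigma^2))
            S <- S + w * tstat[j]
            W <- W + w
            W2 <- W2 + w^2
        }
        z[i] <- (S / W) / sqrt(W2 / W^2)
    }
    z
}

## Brute-force motif scanner: integer scores per offset/strand with the
## same discretisation, null distribution by full enumeration of all
## 4^w words (not by convolution).
bruteScan <- function(motif, seqchar, bg, pseudo = 0.01,
                      granularity = 1e-3) {
    f <- motifMatrix(motif)
    f[f == 0] <- pseudo
    f <- sweep(f, 2, colSums(f), "/")
    Sint <- round(log2(f / bg) / granularity)
    w <- ncol(Sint)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    wordScores <- function(S) {
        tot <- numeric(nrow(words))
        for (j in seq_len(w)) tot <- tot + S[cbind(words[, j], j)]
        tot
    }
    wordProb <- {
        pr <- rep(1, nrow(words))
        for (j in seq_len(w)) pr <- pr * bg[words[, j]]
        pr
    }
    Srev <- Sint[4:1, w:1, drop = FALSE]
    code <- match(strsplit(toupper(seqchar), "")[[1]],
                  c("A", "C", "G", "T"))
    hits <- list()
    thr <- 2^-motifIC(motif)
    for (str in c("+", "-")) {
        S <- if (str == "+") Sint else Srev
        tot <- wordScores(S)
        for (off in seq_len(length(code) - w + 1L)) {
            word <- code[off:(off + w - 1L)]
            if (anyNA(word)) next
            s <- sum(S[cbind(word, seq_len(w))])
            p <- sum(wordProb[tot >= s])
            if (p <= thr)
                hits[[length(hits) + 1L]] <-
                    data.frame(position = off - 1L, strand = str,
                               score = s * granularity, score_p = p)
        }
    }
    if (!length(hits))
        return(data.frame(position = integer(0), strand = character(0),
                          score = numeric(0), score_p = numeric(0)))
    res <- do.call(rbind, hits)
    res[order(res$position, res$strand), , drop = FALSE]
}

## deterministic motif with one certain base per column
consensusMotif <- function(id, bases) {
    idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
    f <- matrix(0, 4, length(idx))
    f[cbind(idx, seq_along(idx))] <- 1
    Motif(id, f)
}

## tiny BetaSet built directly from a matrix with evenly spaced probes
toyBetaSet <- function(beta, condition, spacing = 100L,
                       chrom = "chr1") {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(seq_len(nrow(beta)) * spacing,
                                width = 2L))
    names(gr) <- sprintf("cg%03d", seq_len(nrow(beta)))
    if (is.null(rownames(beta))) rownames(beta) <- names(gr)
    if (is.null(colnames(beta)))
        colnames(beta) <- sprintf("s%03d", seq_len(ncol(beta)))
    BetaSet(beta, gr, condition)
}

## random sequence of given base composition
randomSeq <- function(n, bg = rep(0.25, 4), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = bg),
          collapse = "")
}
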