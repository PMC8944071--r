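#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

## Integer log-odds score matrices for both strands.
## Zero frequencies are replaced by a pseudofrequency (columns then
## renormalised) before taking log2(f/bg); scores are discretised to
## `granularity` bits so that the exact null distribution of the total
## score can be obtained by convolution over columns.
motifScoreScheme <- function(motif, bg = rep(0.25, 4), pseudo = 0.01,
                             granularity = 1e-3) {
    stopifnot(is(motif, "Motif"))
    if (abs(sum(bg) - 1) > 1e-6)
        stop("background frequencies must sum to 1")
    f <- motifMatrix(motif)
    f[f == 0] <- pseudo
    f <- sweep(f, 2L, colSums(f), "/")
    S <- log2(f / bg)
    Sint <- round(S / granularity)
    mode(Sint) <- "integer"
    w <- ncol(Sint)
    ## reverse-complement matrix: complement base rows, reverse columns
    Srev <- Sint[4:1, w:1, drop = FALSE]
    list(fwd = Sint, rev = Srev, granularity = granularity, bg = bg)
}

## Exact distribution of the integer total score under iid background:
## convolve the per-column score distributions. Returns the minimum
## achievable score and the upper-tail function tail[k] = P(S >= min+k-1).
scoreTail <- function(Sint, bg) {
    pmf <- 1
    minSum <- 0L
    for (j in seq_len(ncol(Sint))) {
        sj <- Sint[, j]
        mn <- min(sj)
        new <- numeric(length(pmf) + max(sj) - mn)
        for (i in 1:4) {
            idx <- seq_along(pmf) + (sj[i] - mn)
            new[idx] <- new[idx] + pmf * bg[i]
        }
        pmf <- new
        minSum <- minSum + mn
    }
    list(min = minSum, tail = rev(cumsum(rev(pmf))))
}

lookupTail <- function(dist, score) {
    idx <- score - dist$min + 1L
    p <- rep(0, length(score))
    p[idx <= 0L] <- 1
    inR <- idx >= 1L & idx <= length(dist$tail)
    p[inR] <- dist$tail[idx[inR]]
    p
}

## integer scores of every offset of `code` (integer base codes 1..4,
## NA for ambiguous); offsets containing NA are dropped (score NA)
offsetScores <- function(code, Sint) {
    w <- ncol(Sint)
    nOff <- length(code) - w + 1L
    if (nOff < 1L) return(integer(0))
    tot <- integer(nOff)
    bad <- logical(nOff)
    for (j in seq_len(w)) {
        cj <- code[j:(j + nOff - 1L)]
        bad <- bad | is.na(cj)
        sc <- Sint[cbind(cj, j)]
        sc[is.na(sc)] <- 0L
        tot <- tot + sc
    }
    tot[bad] <- NA_integer_
    tot
}

#' Scan a sequence for motif occurrences at an exact p-value threshold
#'
#' Scores every offset on both strands with the log-odds of the
#' (pseudofrequency-regularised) frequency matrix against an iid
#' background, converts each score to an exact position p-value
#' `P(score >= observed | background)` computed by dynamic-programming
#' convolution of the discretised per-column score distributions, and
#' reports offsets whose p-value is at or below the threshold. The
#' default threshold is `2^-IC`, tying scan stringency to the motif's
#' information content. Offsets containing ambiguous bases are skipped;
#' hits are reported 0-based on the forward strand.
#'
#' @param motif a [Motif-class].
#' @param sequence a [Biostrings::DNAString] or single character string.
#' @param bg background base frequencies (A, C, G, T); defaults to the
#'   base composition of the scanned sequence (uniform if the sequence
#'   is degenerate).
#' @param pThreshold hit threshold on the position p-value (default
#'   `2^-IC`).
#' @param pseudo pseudofrequency replacing zero entries before log-odds
#'   (default 0.01).
#' @param granularity score discretisation in bits (default 1/1000).
#' @return data.frame with columns `position` (0-based, forward
#'   strand), `strand`, `score` (bits) and `score_p`. A motif wider
#'   than the sequence yields an empty result.
#' @export
scanHits <- function(motif, sequence, bg = NULL,
                     pThreshold = 2^-motifIC(motif), pseudo = 0.01,
                     granularity = 1e-3) {
    seqchar <- toupper(as.character(sequence))
    code <- match(strsplit(seqchar, "")[[1]], c("A", "C", "G", "T"))
    if (is.null(bg)) {
        tab <- tabulate(code, 4L)
        bg <- if (sum(tab) == 0L || any(tab == 0L)) rep(0.25, 4)
              else tab / sum(tab)
    }
    scheme <- motifScoreScheme(motif, bg = bg, pseudo = pseudo,
                               granularity = granularity)
    empty <- data.frame(position = integer(0), strand = character(0),
                        score = numeric(0), score_p = numeric(0))
    w <- ncol(scheme$fwd)
    if (length(code) < w) return(empty)
    out <- lapply(c("+", "-"), function(str) {
        S <- if (str == "+") scheme$fwd else scheme$rev
        tot <- offsetScores(code, S)
        ok <- !is.na(tot)
        if (!any(ok)) return(empty)
        dist <- scoreTail(S, bg)
        p <- lookupTail(dist, tot[ok])
        hit <- p <= pThreshold
        data.frame(position = (which(ok)[hit]) - 1L,
                   strand = rep(str, sum(hit)),
                   score = tot[ok][hit] * granularity,
                   score_p = p[hit])
    })
    res <- do.call(rbind, out)
    res[order(res$position, res$strand), , drop = FALSE]
}

#' Presence of motifs in a set of region sequences
#'
#' Scans every sequence with every motif at the `2^-IC` threshold and
#' records whether each region contains at least one occurrence — the
#' presence/absence summary the enrichment test consumes. The
#' background defaults to the pooled base composition of the scanned
#' sequence set.
#'
#' @param motifs list of [Motif-class] objects.
#' @param sequences a [Biostrings::DNAStringSet] or character vector of
#'   region sequences.
#' @param bg background base frequencies; `NULL` for the pooled
#'   composition of `sequences`, `"uniform"` for 0.25 each.
#' @param ... passed to [scanHits()] (e.g. `pseudo`, `granularity`).
#' @return logical matrix, regions x motifs.
#' @export
scanRegionPresence <- function(motifs, sequences, bg = NULL, ...) {
    seqs <- as.character(sequences)
    if (is.null(bg)) {
        tab <- colSums(Biostrings::letterFrequency(
            DNAStringSet(seqs), c("A", "C", "G", "T")))
        bg <- if (sum(tab) == 0 || any(tab == 0)) rep(0.25, 4)
              else tab / sum(tab)
    } else if (identical(bg, "uniform")) bg <- rep(0.25, 4)
    pres <- matrix(FALSE, length(seqs), length(motifs))
    colnames(pres) <- vapply(motifs, motifID, character(1))
    codes <- lapply(toupper(seqs), function(s)
        match(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
    for (k in seq_along(motifs)) {
        m <- motifs[[k]]
        scheme <- motifScoreScheme(m, bg = bg, ...)
        thr <- 2^-motifIC(m)
        ## smallest integer score whose exact tail p is within threshold
        cuts <- lapply(list(scheme$fwd, scheme$rev), function(S) {
            dist <- scoreTail(S, bg)
            ok <- dist$tail <= thr
            if (!any(ok)) Inf else dist$min + min(which(ok)) - 1L
        })
        for (i in seq_along(codes)) {
            if (length(codes[[i]]) < ncol(scheme$fwd)) next
            tf <- offsetScores(codes[[i]], scheme$fwd)
            if (any(!is.na(tf) & tf >= cuts[[1]])) {
                pres[i, k] <- TRUE
                next
            }
            tr <- offsetScores(codes[[i]], scheme$rev)
            pres[i, k] <- any(!is.na(tr) & tr >= cuts[[2]])
        }
    }
    pres
}

#' Attained p-value of a motif scan threshold
#'
#' The exact tail probability actually attained at the largest
#' achievable score whose p-value does not exceed the threshold —
#' i.e. the per-offset false-positive rate of the scan on iid
#' background. Returned per strand.
#'
#' @inheritParams scanHits
#' @return named numeric of length 2 (`fwd`, `rev`).
#' @export
attainedScanP <- function(motif, bg = rep(0.25, 4),
                          pThreshold = 2^-motifIC(motif), pseudo = 0.01,
                          granularity = 1e-3) {
    scheme <- motifScoreScheme(motif, bg = bg, pseudo = pseudo,
                               granularity = granularity)
    vapply(list(fwd = scheme$fwd, rev = scheme$rev), function(S) {
        dist <- scoreTail(S, bg)
        tl <- dist$tail
        ok <- tl <= pThreshold
        if (!any(ok)) 0 else max(tl[ok])
    }, numeric(1))
}
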