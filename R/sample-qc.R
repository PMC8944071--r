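#' Select the most variable probes
#'
#' Keeps the `k` probes with the largest across-sample variance (ties
#' broken by row order, i.e. probe id order); sample column order is
#' preserved.
#'
#' @param beta a [BetaSet-class] or numeric matrix (probes x samples).
#' @param k number of probes to keep (default 5000).
#' @return matrix of the top-`k` rows.
#' @export
topVariablePositions <- function(beta, k = 5000L) {
    m <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
    checkCount(k, "k", min = 1L)
    if (k > nrow(m))
        stop("k = ", k, " exceeds the number of probes (", nrow(m), ")")
    v <- rowVars(m)
    ord <- order(-v)           # stable: ties keep row order
    m[sort(ord[seq_len(k)]), , drop = FALSE]
}

#' PCA with relative-variance component retention
#'
#' Principal components are computed by SVD on the column-centered
#' (not scaled: beta values share a scale) probe matrix; all
#' components whose variance is at least `retentionRatio` times the
#' variance of the first component are retained. The first component
#' is always retained.
#'
#' @param reduced probes x samples matrix (e.g. from
#'   [topVariablePositions()]).
#' @param retentionRatio variance retention threshold relative to
#'   component 1 (default 0.10).
#' @return list with `scores` (samples x retained components),
#'   `variances` (all component variances) and `nRetained`.
#' @export
pcaRetain <- function(reduced, retentionRatio = 0.10) {
    checkFraction(retentionRatio, "retentionRatio", 0, 1, open = FALSE)
    if (ncol(reduced) < 2L) stop("need at least 2 samples")
    pc <- stats::prcomp(t(reduced), center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    keep <- which(v >= retentionRatio * v[1])
    keep <- union(1L, keep)
    list(scores = pc$x[, keep, drop = FALSE], variances = v,
         nRetained = length(keep))
}

#' Discard samples misclassified by quadratic discriminant analysis
#'
#' Fits one Gaussian per class (class mean, class covariance plus a
#' small ridge, priors equal to class frequencies) on the retained
#' component scores and discards every sample whose
#' maximum-posterior class differs from its label. The fit uses all
#' samples, including those later discarded; there is no refit loop.
#'
#' @param scores samples x components matrix.
#' @param labels factor/character of class labels (two classes, e.g.
#'   `"cancer"`/`"healthy"`), one per sample.
#' @param ridge ridge added to each class covariance as
#'   `ridge * mean(diag(cov))` (default 1e-6); needed when the number
#'   of retained components approaches the per-class sample count.
#' @return list with `retained` (sample ids/indices kept),
#'   `discarded`, `posterior` (samples x classes) and `predicted`.
#' @export
qdaDiscard <- function(scores, labels, ridge = 1e-6) {
    scores <- as.matrix(scores)
    labels <- as.character(labels)
    cls <- sort(unique(labels))
    if (length(cls) != 2L) stop("exactly two classes are required")
    for (cl in cls)
        if (sum(labels == cl) < 2L)
            stop("class '", cl, "' has fewer than 2 samples")
    n <- nrow(scores)
    logdens <- matrix(NA_real_, n, 2L, dimnames = list(NULL, cls))
    for (ci in seq_along(cls)) {
        idx <- labels == cls[ci]
        mu <- colMeans(scores[idx, , drop = FALSE])
        S <- stats::cov(scores[idx, , drop = FALSE])
        S <- S + diag(ridge * mean(diag(S)), ncol(scores))
        ch <- tryCatch(chol(S), error = function(e)
            stop("covariance of class '", cls[ci],
                 "' is singular even after ridge regularization"))
        xc <- sweep(scores, 2L, mu)
        z <- backsolve(ch, t(xc), transpose = TRUE)
        maha <- colSums(z^2)
        logdet <- 2 * sum(log(diag(ch)))
        logdens[, ci] <- log(mean(idx)) - 0.5 * logdet - 0.5 * maha -
            0.5 * ncol(scores) * log(2 * pi)
    }
    post <- exp(logdens - apply(logdens, 1L, max))
    post <- post / rowSums(post)
    pred <- cls[max.col(logdens, ties.method = "first")]
    ids <- if (!is.null(rownames(scores))) rownames(scores)
           else seq_len(n)
    keep <- pred == labels
    list(retained = ids[keep], discarded = ids[!keep],
         posterior = post, predicted = pred)
}

#' Sample quality control by PCA and QDA
#'
#' Runs the full sample-filtering step: variance ranking of probes,
#' PCA with relative-variance component retention, QDA on the
#' retained components, and discard of misclassified samples. A
#' single pass: the variance ranking is not recomputed after the
#' discard.
#'
#' @param beta a [BetaSet-class].
#' @param nTopPositions probes entering the PCA (default 5000, capped
#'   at the probe count).
#' @param retentionRatio see [pcaRetain()].
#' @param ridge see [qdaDiscard()].
#' @return list with `retained`, `discarded`, `nRetainedComponents`,
#'   `scores` and `posterior`.
#' @export
sampleQC <- function(beta, nTopPositions = 5000L,
                     retentionRatio = 0.10, ridge = 1e-6) {
    stopifnot(is(beta, "BetaSet"))
    k <- min(nTopPositions, nrow(beta))
    red <- topVariablePositions(beta, k)
    pca <- pcaRetain(red, retentionRatio)
    sc <- pca$scores
    rownames(sc) <- colnames(beta)
    qda <- qdaDiscard(sc, sampleCondition(beta), ridge)
    list(retained = qda$retained, discarded = qda$discarded,
         nRetainedComponents = pca$nRetained, scores = sc,
         posterior = qda$posterior)
}
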