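#' Derive a child seed from a global seed
#'
#' One global seed fans out to per-generator child seeds through a fixed
#' counter scheme (`seed * 1000 + counter`, reduced mod 2^31 - 1), so
#' adding a generator to a simulation does not perturb the streams of
#' the others.
#'
#' @param seed integer global seed.
#' @param counter nonnegative integer slot of the consuming generator.
#' @return an integer seed.
#' @export
childSeed <- function(seed, counter) {
    as.integer((as.numeric(seed) * 1000 + as.numeric(counter)) %%
               2147483647)
}

## Validate a fraction-type scalar parameter in the open interval (0,1)
## unless bounds are widened by the caller.
checkFraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name))
    bad <- if (open) (x <= lo || x >= hi) else (x < lo || x > hi)
    if (bad)
        stop(sprintf("'%s' must lie in %s%g, %g%s", name,
                     if (open) "(" else "[", lo, hi,
                     if (open) ")" else "]"))
    invisible(x)
}

checkCount <- function(x, name, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < min)
        stop(sprintf("'%s' must be an integer >= %d", name, min))
    invisible(as.integer(x))
}

## Row means over a subset of columns without dropping dimensions.
rowGroupMeans <- function(m, idx) {
    if (length(idx) == 1L) m[, idx] else rowMeans(m[, idx, drop = FALSE])
}

## Row variances (denominator n-1).
rowVars <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1)
}
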