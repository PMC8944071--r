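#' Information-content and GC summaries of a frequency matrix
#'
#' For base frequencies f (rows A, C, G, T; columns sum to 1) the
#' per-column information content is `local_IC_j = 2 + sum_i f_ij
#' log2(f_ij)` (with 0 log 0 = 0), the total information content is
#' `IC = sum_j local_IC_j`, the per-column G+C frequency is
#' `GC_freq_j = f_Gj + f_Cj`, and `mean_GC` is the mean of `GC_freq_j`
#' weighted by `local_IC_j`. The GC class is `"rich"` when mean_GC is
#' above 0.75, `"poor"` below 0.25, otherwise `"medium"`.
#'
#' @param f 4 x width numeric matrix of base frequencies; rows in order
#'   A, C, G, T; each column must sum to 1 within 1e-6.
#' @return list with `localIC`, `ic`, `gcFreq`, `meanGC`, `gcClass`.
#' @examples
#' motifInformation(matrix(c(.5, .5, 0, 0), 4, 1))$localIC  # 1 bit
#' @export
motifInformation <- function(f) {
    f <- as.matrix(f)
    if (nrow(f) != 4L)
        stop("frequency matrix must have 4 rows (A, C, G, T)")
    if (any(abs(colSums(f) - 1) > 1e-6))
        stop("frequency columns must sum to 1 (tolerance 1e-6)")
    plogp <- f * log2(f)
    plogp[f == 0] <- 0
    localIC <- 2 + colSums(plogp)
    ic <- sum(localIC)
    gcFreq <- f[2L, ] + f[3L, ]
    meanGC <- if (ic > 0) sum(gcFreq * localIC) / ic else mean(gcFreq)
    gcClass <- if (meanGC > 0.75) "rich" else if (meanGC < 0.25) "poor"
               else "medium"
    list(localIC = unname(localIC), ic = ic, gcFreq = unname(gcFreq),
         meanGC = meanGC, gcClass = gcClass)
}

#' Construct a Motif from a frequency matrix
#'
#' @param id motif identifier.
#' @param f 4 x width frequency matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @param tf character vector of TF names (defaults to `id`).
#' @return a [Motif-class] with derived information-content and GC
#'   summaries filled in.
#' @export
Motif <- function(id, f, tf = id) {
    f <- as.matrix(f)
    rownames(f) <- c("A", "C", "G", "T")
    info <- motifInformation(f)
    new("Motif", id = as.character(id), tf = as.character(tf),
        matrix = f, localIC = info$localIC, ic = info$ic,
        gcFreq = info$gcFreq, meanGC = info$meanGC,
        gcClass = info$gcClass, cluster = NA_integer_)
}

#' Random motif library generator
#'
#' Draws each column from a symmetric Dirichlet and sharpens it towards
#' its largest entry so that motifs have realistic information content
#' (roughly 10-14 bits at the default width, the range typical of
#' curated TF motif collections).
#'
#' @param n number of motifs.
#' @param width motif width (single value or vector to sample from).
#' @param sharpen exponent applied to Dirichlet draws before
#'   renormalisation; larger gives more informative columns.
#' @param seed integer seed.
#' @param prefix id prefix (`"motif"`).
#' @return list of [Motif-class] objects with ids `prefix1..n` and TF
#'   names `TF_<id>`.
#' @export
randomMotifSet <- function(n, width = 8L, sharpen = 5, seed = 1L,
                           prefix = "motif") {
    checkCount(n, "n", 1L)
    set.seed(seed)
    lapply(seq_len(n), function(i) {
        w <- if (length(width) > 1L) sample(width, 1L) else width
        f <- matrix(stats::rgamma(4L * w, 1), 4L, w)
        f <- f^sharpen
        f <- sweep(f, 2L, colSums(f), "/")
        id <- paste0(prefix, i)
        Motif(id, f, tf = paste0("TF_", id))
    })
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the minimal motif format (`MEME version`, `ALPHABET`,
#' `MOTIF <id> [<alt>]`, `letter-probability matrix:` blocks).
#'
#' @param path file path.
#' @return list of [Motif-class] objects.
#' @export
readMEME <- function(path) {
    lines <- readLines(path)
    starts <- grep("^MOTIF\\b", lines)
    if (!length(starts)) stop("no MOTIF blocks found in ", path)
    lapply(seq_along(starts), function(k) {
        hdr <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]]
        id <- hdr[2]
        tf <- if (length(hdr) >= 3L) hdr[3] else id
        upto <- if (k < length(starts)) starts[k + 1L] - 1L
                else length(lines)
        block <- lines[starts[k]:upto]
        mi <- grep("^letter-probability matrix", block)
        if (!length(mi)) stop("motif ", id, ": no probability matrix")
        rows <- list()
        for (ln in block[-seq_len(mi[1])]) {
            ln <- trimws(ln)
            if (ln == "" || grepl("^(URL|MOTIF)", ln)) break
            rows[[length(rows) + 1L]] <-
                as.numeric(strsplit(ln, "\\s+")[[1]])
        }
        f <- t(do.call(rbind, rows))
        ## absorb the rounding of text representations
        cs <- colSums(f)
        if (any(abs(cs - 1) > 1e-3))
            stop("motif ", id, ": probability columns do not sum to 1")
        f <- sweep(f, 2L, cs, "/")
        Motif(id, f, tf = tf)
    })
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of [Motif-class] objects.
#' @param path output file path.
#' @param bg background base frequencies written to the header.
#' @return `path`, invisibly.
#' @export
writeMEME <- function(motifs, path, bg = rep(0.25, 4)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f",
                         bg[1], bg[2], bg[3], bg[4]), ""), con)
    for (m in motifs) {
        f <- motifMatrix(m)
        writeLines(sprintf("MOTIF %s %s", motifID(m),
                           paste(motifTF(m), collapse = "::")), con)
        writeLines(sprintf(
            "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            ncol(f)), con)
        for (j in seq_len(ncol(f)))
            writeLines(paste(sprintf("%.6f", f[, j]), collapse = "  "),
                       con)
        writeLines("", con)
    }
    invisible(path)
}
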