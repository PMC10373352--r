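# Decomposition of a nucleotide sequence into an optimal string of motifs
# (minimum total edit distance over all exact tilings), plus the motif-string
# metrics used for allele comparison and annotation-error evaluation.

#' Decompose a sequence into a string of motifs
#'
#' Partitions the sequence into contiguous blocks covering it exactly, each
#' block assigned one motif from the set, minimizing the sum over blocks of
#' the unit-cost edit distance between block and motif. Ties among optimal
#' tilings are broken by fewest blocks, then leftmost-longest blocks, then
#' lowest motif index.
#'
#' Block lengths are searched up to \code{maxBlock} (default twice the
#' longest motif). The bound affects completeness only in the degenerate case
#' of a block needing to absorb more than one motif length of extra
#' sequence; \code{exact = TRUE} removes the bound.
#'
#' @param sequence a non-empty DNA string.
#' @param motifs non-empty character vector of motifs.
#' @param maxBlock maximum block length searched (\code{NULL}: twice the
#'   longest motif).
#' @param exact search all block lengths (overrides \code{maxBlock}).
#' @return A \code{\linkS4class{MotifDecomposition}}.
#' @examples
#' d <- decomposeSequence("ACGGTACGGTACCGTACGT", "ACGGT")
#' length(d)       # 4 motif occurrences
#' totalCost(d)    # 2
#' @export
decomposeSequence <- function(sequence, motifs, maxBlock = NULL,
                              exact = FALSE) {
    .stopifempty(sequence, "sequence")
    .stopifempty(motifs, "motif list")
    sequence <- toupper(sequence)
    motifs <- toupper(motifs)
    n <- nchar(sequence)
    if (exact || is.null(maxBlock))
        maxBlock <- if (exact) n else min(n, 2L * max(nchar(motifs)))
    res <- .cpp_decompose(sequence, motifs, as.integer(maxBlock))
    blocks <- data.frame(start = res$start, end = res$end,
                         motif = res$motif, cost = res$cost)
    new("MotifDecomposition", sequence = sequence, motifs = motifs,
        blocks = blocks, totalCost = res$total)
}

#' Translate a decomposition back to nucleotides
#'
#' Concatenates the motif assigned to each block, in order. For a zero-cost
#' decomposition the translation equals the input sequence; in general the
#' edit distance between translation and input is at most the decomposition's
#' total cost.
#'
#' @param decomposition a \code{\linkS4class{MotifDecomposition}}, or a
#'   vector of motif indices.
#' @param motifs motif list (required when \code{decomposition} is an index
#'   vector; ignored otherwise).
#' @return A DNA string.
#' @rdname decomposeSequence
#' @export
translateAnnotation <- function(decomposition, motifs = NULL) {
    if (is(decomposition, "MotifDecomposition")) {
        motifs <- decomposition@motifs
        idx <- decomposition@blocks$motif
    } else {
        idx <- as.integer(decomposition)
        if (is.null(motifs)) stop("motifs required for an index vector")
    }
    paste(motifs[idx], collapse = "")
}

#' Edit distance between two motif strings
#'
#' Levenshtein distance over motif symbols (unit-cost motif mismatch,
#' insertion and deletion). The two strings must index a shared motif space.
#'
#' @param a,b motif strings as integer index vectors (or character vectors of
#'   motif names over a shared alphabet).
#' @return non-negative integer count of motif edits.
#' @examples
#' motifStringDist(c(1, 2, 1), c(1, 1))  # 1
#' @export
motifStringDist <- function(a, b) {
    if (is.character(a) || is.character(b)) {
        lev <- sort(unique(c(a, b)))
        a <- match(a, lev)
        b <- match(b, lev)
    }
    as.integer(adist(.encodeSymbols(a), .encodeSymbols(b)))
}

#' Test whether a motif set is a uniquely decodable code
#'
#' A motif string can be recovered exactly from its concatenated nucleotide
#' sequence only when no two distinct motif strings spell the same sequence,
#' i.e. when the motif set is a uniquely decodable code. Decided by the
#' Sardinas-Patterson algorithm: iteratively form dangling suffixes between
#' motifs; the set fails exactly when some dangling suffix is itself a
#' motif. Motif sets of a common length are always uniquely decodable; sets
#' mixing a motif with both a left- and right-extended variant (\code{Xm}
#' and \code{mX}) typically are not.
#'
#' @param motifs character vector of distinct motifs.
#' @return \code{TRUE} when every concatenation has a unique factorization.
#' @examples
#' uniquelyDecodable(c("ACGGT", "ACCGT"))          # TRUE (equal lengths)
#' uniquelyDecodable(c("A", "AG", "GA"))           # FALSE ("AGA" is ambiguous)
#' @export
uniquelyDecodable <- function(motifs) {
    motifs <- unique(motifs)
    if (length(motifs) <= 1L) return(TRUE)
    dangle <- function(a, b) {
        # suffix w such that a + w == b
        if (nchar(b) > nchar(a) && startsWith(b, a))
            substring(b, nchar(a) + 1L)
        else character(0)
    }
    S <- character(0)
    for (a in motifs) for (b in motifs)
        if (a != b) S <- c(S, dangle(a, b))
    S <- unique(S)
    seen <- S
    while (length(S)) {
        if (any(S %in% motifs)) return(FALSE)
        nxt <- character(0)
        for (w in S) for (m in motifs)
            nxt <- c(nxt, dangle(w, m), dangle(m, w))
        S <- setdiff(unique(nxt), seen)
        seen <- union(seen, S)
    }
    TRUE
}

#' Annotation error against a ground-truth motif string
#'
#' The motif-string edit distance between predicted and truth annotation,
#' divided by the number of motifs in the truth.
#'
#' @param predicted,truth motif strings (integer index vectors or character
#'   vectors over a shared motif space); \code{truth} must be non-empty.
#' @return fraction (0 for identical annotations; 1 when the prediction is
#'   empty).
#' @export
annotationError <- function(predicted, truth) {
    if (length(truth) == 0L)
        stop("truth annotation must be non-empty")
    motifStringDist(predicted, truth) / length(truth)
}
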