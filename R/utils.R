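# Internal helpers shared across modules.

# Unit-cost Levenshtein distance. utils::adist with default costs is exactly
# this; kept behind a wrapper so all call sites share one definition.
.ed <- function(a, b) {
    drop(adist(a, b))
}

# Bounded edit distance: exact when <= limit, otherwise limit + 1.
.edBounded <- function(a, b, limit) {
    .cpp_edit_distance_bounded(a, b, as.integer(limit))
}

.stopifempty <- function(x, what) {
    if (length(x) == 0L || any(!nzchar(x)))
        stop(what, " must be non-empty", call. = FALSE)
}

# All cyclic rotations of a string, offset k = left rotation by k.
.rotations <- function(s) {
    n <- nchar(s)
    if (n == 1L) return(s)
    vapply(seq_len(n) - 1L, function(k)
        paste0(substr(s, k + 1L, n), substr(s, 1L, k)), character(1))
}

# Map motif-index strings to single-character encodings so adist can compute
# symbol-level Levenshtein distances. Index space must be shared between the
# compared strings. Offset avoids NUL/control code points.
.encodeSymbols <- function(idx) {
    if (length(idx) == 0L) return("")
    intToUtf8(as.integer(idx) + 256L)
}

# Reverse complement without requiring a DNAString round-trip.
.revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", vapply(s, function(x)
        paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""),
        character(1), USE.NAMES = FALSE))
}

# Deterministic medoid over a character vector with multiplicities:
# minimizes total edit distance to all occurrences; ties broken by higher
# multiplicity, then lexicographic order.
.medoid <- function(occ) {
    .stopifempty(occ, "occurrence list")
    tab <- table(occ)
    uniq <- names(tab)
    mult <- as.integer(tab)
    if (length(uniq) == 1L) return(uniq)
    d <- adist(uniq)
    tot <- as.numeric(d %*% mult)
    ord <- order(tot, -mult, uniq)
    uniq[ord[1L]]
}
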