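# Building the original motif set of a VNTR locus from per-haplotype
# repeat-finder candidate motifs: candidate filtering, re-annotation,
# consensus, boundary trimming, cyclic rotation normalization and the
# locus-level exclusion rules.

#' Normalize a motif by cyclic rotation against an anchor
#'
#' Repeat finders report motifs in arbitrary phase; rotating every motif
#' in-frame with a locus consensus makes motif identity comparable across
#' haplotypes. Returns the rotation of \code{motif} with minimal edit
#' distance to \code{anchor}; ties are broken by the smallest rotation
#' offset, then lexicographic order.
#'
#' @param motif,anchor non-empty DNA strings.
#' @return A rotation of \code{motif} (same multiset of characters).
#' @examples
#' normalizeRotation("GGTAC", "ACGGT")  # "ACGGT"
#' @export
normalizeRotation <- function(motif, anchor) {
    .stopifempty(motif, "motif")
    .stopifempty(anchor, "anchor")
    rot <- .rotations(motif)
    d <- adist(rot, anchor)[, 1L]
    ord <- order(d, seq_along(rot), rot)
    rot[ord[1L]]
}

#' Filter homopolymer and approximate-concatenate motif candidates
#'
#' Removes candidates composed of a single repeated base, and candidates that
#' are redundant concatenates of a smaller retained candidate: a candidate c
#' is dropped when some retained shorter candidate s satisfies
#' \code{nchar(c) > 1.5 * nchar(s)} and the best (fitting) alignment of c
#' against a tandem concatenation of s has identity >= 80 percent over c.
#' Candidates are evaluated shortest-first so the result does not depend on
#' input order; the retained candidates keep their original order.
#'
#' @param candidates character vector of candidate consensus motifs.
#' @return The retained candidates (possibly empty; the caller should flag
#'   the locus when everything is removed).
#' @examples
#' filterMotifCandidates(c("AC", "ACAC"))        # "AC"
#' filterMotifCandidates(c("AAAA", "ACGGT"))     # "ACGGT"
#' @export
filterMotifCandidates <- function(candidates) {
    .stopifempty(candidates, "candidate list")
    candidates <- toupper(candidates)
    homo <- vapply(candidates, function(x) {
        length(unique(strsplit(x, "", fixed = TRUE)[[1L]])) == 1L
    }, logical(1), USE.NAMES = FALSE)
    keep <- !homo
    ord <- order(nchar(candidates))          # decide shortest-first
    for (i in ord) {
        if (!keep[i]) next
        ci <- candidates[i]
        for (j in ord) {
            if (!keep[j]) next
            sj <- candidates[j]
            if (nchar(ci) <= 1.5 * nchar(sj)) next
            reps <- ceiling(nchar(ci) / nchar(sj)) + 1L
            d <- .cpp_fit_align_cost(ci, strrep(sj, reps))
            if ((nchar(ci) - d) / nchar(ci) >= 0.8) {
                keep[i] <- FALSE
                break
            }
        }
    }
    candidates[keep]
}

#' Consensus motif over a set of occurrences
#'
#' Deterministic medoid: the occurrence minimizing total edit distance to all
#' occurrences (with multiplicity); ties broken by higher multiplicity, then
#' lexicographic order. This serves as the locus consensus against which
#' motifs are rotated in-frame; a partial-order-alignment consensus backend
#' can be substituted as long as it honours the same contract
#' (deterministic, returns a motif-length DNA string).
#'
#' @param occurrences non-empty character vector of motif occurrences.
#' @return A single DNA string.
#' @examples
#' consensusMotif(c("ACGGT", "ACGGT", "ACCGT"))  # "ACGGT"
#' @export
consensusMotif <- function(occurrences) {
    .medoid(occurrences)
}

#' Trim partial boundary motifs from an occurrence list
#'
#' Motifs at sequence boundaries are often partial copies. Repeatedly removes
#' the first/last occurrence while its length is shorter than 2/3 or longer
#' than 4/3 of the consensus length. Interior occurrences are never removed.
#'
#' @param occ ordered character vector of motif occurrences.
#' @param consensus non-empty consensus motif.
#' @return The trimmed occurrence vector (possibly empty).
#' @examples
#' trimBoundaryMotifs(c("ACG", "ACGGT", "ACGGT", "ACGGTAC"), "ACGGT")
#' @export
trimBoundaryMotifs <- function(occ, consensus) {
    .stopifempty(consensus, "consensus")
    lo <- (2 / 3) * nchar(consensus)
    hi <- (4 / 3) * nchar(consensus)
    bad <- function(x) nchar(x) < lo || nchar(x) > hi
    while (length(occ) && bad(occ[1L])) occ <- occ[-1L]
    while (length(occ) && bad(occ[length(occ)])) occ <- occ[-length(occ)]
    occ
}

#' Build the original motif set of a locus from per-haplotype occurrences
#'
#' Takes the ordered motif occurrences of each panel haplotype, rotates every
#' occurrence in-frame with the panel-wide consensus, and counts the distinct
#' motifs. The sum of counts equals the total number of retained occurrences.
#'
#' @param perHaplotype list of character vectors, one per haplotype, each the
#'   ordered motif occurrences on that haplotype's locus sequence.
#' @param consensus optional consensus motif; defaults to the medoid over all
#'   occurrences.
#' @param normalize rotate occurrences in-frame with the consensus
#'   (default \code{TRUE}).
#' @param locusId optional locus identifier stored in the result.
#' @return A \code{\linkS4class{MotifSet}} (motifs ordered by decreasing
#'   count, then lexicographically), or \code{NULL} with a warning when there
#'   are no occurrences (the caller should flag the locus).
#' @examples
#' buildMotifSet(list(c("ACGGT", "ACGGT"), c("ACGGT", "ACCGT")))
#' @export
buildMotifSet <- function(perHaplotype, consensus = NULL, normalize = TRUE,
                          locusId = NA_character_) {
    stopifnot(is.list(perHaplotype), length(perHaplotype) >= 1L)
    occ <- toupper(unlist(perHaplotype, use.names = FALSE))
    if (length(occ) == 0L) {
        warning("no motif occurrences; locus should be flagged")
        return(NULL)
    }
    if (is.null(consensus)) consensus <- .medoid(occ)
    if (normalize) {
        uniq <- unique(occ)
        rot <- vapply(uniq, normalizeRotation, character(1),
                      anchor = consensus, USE.NAMES = TRUE)
        occ <- unname(rot[occ])
    }
    tab <- table(occ)
    ord <- order(-as.integer(tab), names(tab))
    MotifSet(names(tab)[ord], as.integer(tab)[ord], locusId = locusId)
}

#' Apply locus-level exclusion rules
#'
#' Flags a VNTR locus for each failed retention rule: reference span longer
#' than 10 kb; transposable-element fraction above 40 percent; overlap with a
#' caller-supplied mask (e.g. centromeres, alternative contigs); consensus
#' period 1 or 2 (homopolymer / dinucleotide locus); more than 500 distinct
#' motifs. Unflagged loci pass downstream.
#'
#' @param locus a length-1 \code{GRanges} describing the locus on the
#'   reference.
#' @param motifSet the locus \code{\linkS4class{MotifSet}} (or \code{NULL}).
#' @param consensus the locus consensus motif (period taken as its length
#'   after rotation normalization).
#' @param teFraction fraction of the locus annotated as transposable element
#'   (caller-supplied; this package does not compute repeat-element
#'   annotations).
#' @param masks named list of \code{GRanges} masks; overlap adds the mask
#'   name as a flag.
#' @param maxLength,maxTeFraction,maxMotifs rule thresholds.
#' @return The input \code{GRanges} with a character \code{flags} metadata
#'   column (comma-separated reasons, \code{""} when retained).
#' @export
applyLocusFilters <- function(locus, motifSet = NULL, consensus = NULL,
                              teFraction = 0, masks = list(),
                              maxLength = 10000L, maxTeFraction = 0.4,
                              maxMotifs = 500L) {
    stopifnot(is(locus, "GRanges"), length(locus) == 1L)
    flags <- character()
    if (GenomicRanges::width(locus) > maxLength) flags <- c(flags, "length")
    if (teFraction > maxTeFraction) flags <- c(flags, "te_fraction")
    for (nm in names(masks)) {
        if (length(IRanges::findOverlaps(locus, masks[[nm]])) > 0L)
            flags <- c(flags, nm)
    }
    if (!is.null(consensus)) {
        if (nchar(consensus) == 1L) flags <- c(flags, "homopolymer")
        if (nchar(consensus) == 2L) flags <- c(flags, "dinucleotide")
    }
    if (!is.null(motifSet) && length(motifSet) > maxMotifs)
        flags <- c(flags, "motif_count")
    GenomicRanges::mcols(locus)$flags <- paste(flags, collapse = ",")
    locus
}

#' Full catalog pass for one locus
#'
#' Runs the per-locus catalog pipeline on a panel of haplotype locus
#' sequences with their repeat-finder candidate motifs: filter candidates
#' (homopolymers, approximate concatenates), re-annotate each haplotype
#' sequence into candidate-motif blocks, form the panel consensus over the
#' observed block sequences, trim partial boundary occurrences, and build the
#' rotation-normalized original motif set. One pass is run (no iteration to
#' convergence).
#'
#' @param haplotypeSeqs character vector (or \code{DNAStringSet}) of the
#'   locus sequence in each panel haplotype.
#' @param candidates either one character vector of candidate motifs shared
#'   by all haplotypes, or a list of per-haplotype candidate vectors.
#' @param locusId optional locus identifier.
#' @return A list with elements \code{motifSet}
#'   (\code{\linkS4class{MotifSet}} or \code{NULL}), \code{consensus}, and
#'   \code{occurrences} (per-haplotype character vectors after trimming and
#'   rotation).
#' @export
catalogLocus <- function(haplotypeSeqs, candidates, locusId = NA_character_) {
    haplotypeSeqs <- toupper(as.character(haplotypeSeqs))
    .stopifempty(haplotypeSeqs, "haplotype sequences")
    if (!is.list(candidates))
        candidates <- rep(list(candidates), length(haplotypeSeqs))
    stopifnot(length(candidates) == length(haplotypeSeqs))
    perHap <- vector("list", length(haplotypeSeqs))
    for (h in seq_along(haplotypeSeqs)) {
        cand <- filterMotifCandidates(candidates[[h]])
        if (length(cand) == 0L) next
        dec <- decomposeSequence(haplotypeSeqs[h], cand)
        b <- blocks(dec)
        perHap[[h]] <- substring(haplotypeSeqs[h], b$start + 1L, b$end)
    }
    allOcc <- unlist(perHap, use.names = FALSE)
    if (length(allOcc) == 0L)
        return(list(motifSet = NULL, consensus = NULL,
                    occurrences = perHap))
    cons <- .medoid(allOcc)
    perHap <- lapply(perHap, function(occ) {
        if (is.null(occ)) character() else trimBoundaryMotifs(occ, cons)
    })
    ms <- buildMotifSet(perHap, consensus = cons, locusId = locusId)
    list(motifSet = ms, consensus = cons, occurrences = perHap)
}
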