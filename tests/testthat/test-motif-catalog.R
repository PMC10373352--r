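# Original motif set construction: rotation normalization, candidate
# filtering, consensus, boundary trimming, union counting, locus filters.

test_that("cyclic rotation normalization picks the in-frame rotation", {
    expect_identical(normalizeRotation("GGTAC", "ACGGT"), "ACGGT")
    expect_identical(normalizeRotation("ACGGT", "ACGGT"), "ACGGT")
    expect_identical(normalizeRotation("AAAA", "AAAT"), "AAAA")
    expect_error(normalizeRotation("", "ACGT"), "non-empty")
})

test_that("rotation normalization is idempotent and rotation-preserving", {
    set.seed(11)
    for (rep in 1:25) {
        m <- randDna(sample(3:9, 1))
        a <- randDna(sample(3:9, 1))
        r1 <- normalizeRotation(m, a)
        expect_identical(normalizeRotation(r1, a), r1)
        # same multiset of characters
        expect_identical(sort(strsplit(r1, "")[[1]]),
                         sort(strsplit(m, "")[[1]]))
    }
})

test_that("homopolymer and approximate-concatenate candidates are removed", {
    expect_identical(filterMotifCandidates(c("AC", "ACAC")), "AC")
    expect_identical(filterMotifCandidates(c("AAAA", "ACGGT")), "ACGGT")
    expect_identical(filterMotifCandidates(c("ACGGT", "TTAGGC")),
                     c("ACGGT", "TTAGGC"))
    # near-perfect triple of a 4-mer with one substitution: 11/12 = 92%
    expect_identical(filterMotifCandidates(c("ACGT", "ACGTACTTACGT")),
                     "ACGT")
    # all removed -> empty
    expect_identical(filterMotifCandidates(c("AAAA", "TT")), character(0))
})

test_that("concatenate filter is independent of candidate order", {
    set.seed(12)
    for (rep in 1:10) {
        base <- randDna(sample(2:4, 1))
        cand <- c(base, strrep(base, 3), randDna(7), randDna(10))
        ref <- sort(filterMotifCandidates(cand))
        for (k in 1:5) {
            perm <- sample(cand)
            expect_identical(sort(filterMotifCandidates(perm)), ref)
        }
    }
})

test_that("consensus is the deterministic medoid with stated tie rules", {
    expect_identical(consensusMotif(c("ACGGT", "ACGGT", "ACCGT")), "ACGGT")
    expect_identical(consensusMotif("ACGGT"), "ACGGT")
    expect_identical(consensusMotif(c("AC", "GT")), "AC")       # lex tie
    expect_identical(consensusMotif(c("GT", "AC", "GT")), "GT") # multiplicity
    expect_error(consensusMotif(character(0)), "non-empty")
})

test_that("boundary trimming removes only out-of-range edge occurrences", {
    expect_identical(
        trimBoundaryMotifs(c("ACG", "ACGGT", "ACGGT", "ACGGTAC"), "ACGGT"),
        c("ACGGT", "ACGGT"))
    expect_identical(trimBoundaryMotifs(c("ACGGT", "ACGGT"), "ACGGT"),
                     c("ACGGT", "ACGGT"))
    expect_identical(trimBoundaryMotifs("AC", "ACGGT"), character(0))
    # interior occurrences survive even when out of range
    expect_identical(trimBoundaryMotifs(c("ACGGT", "A", "ACGGT"), "ACGGT"),
                     c("ACGGT", "A", "ACGGT"))
})

test_that("trimming output is a contiguous interior slice of the input", {
    set.seed(13)
    for (rep in 1:20) {
        occ <- replicate(sample(1:8, 1), randDna(sample(2:8, 1)))
        cons <- randDna(5)
        out <- trimBoundaryMotifs(occ, cons)
        expect_lte(length(out), length(occ))
        if (length(out))
            expect_true(any(vapply(seq_len(length(occ) - length(out) + 1),
                function(s) identical(occ[s:(s + length(out) - 1)], out),
                logical(1))))
    }
})

test_that("building the motif set counts occurrences conservatively", {
    ms <- buildMotifSet(list(c("ACGGT", "ACGGT"), c("ACGGT", "ACCGT")))
    expect_identical(motifs(ms), c("ACGGT", "ACCGT"))
    expect_identical(unname(motifCounts(ms)), c(3L, 1L))
    expect_identical(occurrenceTotal(ms), 4L)
    # constant repeat across many haplotypes collapses to p = 1
    ms1 <- buildMotifSet(rep(list(rep("ACGGT", 3)), 148))
    expect_identical(length(ms1), 1L)
    # rotated motifs merge under normalization
    ms2 <- buildMotifSet(list("GGTAC", "ACGGT"), consensus = "ACGGT")
    expect_identical(motifs(ms2), "ACGGT")
    expect_identical(occurrenceTotal(ms2), 2L)
    expect_warning(out <- buildMotifSet(list(character(0))), "flagged")
    expect_null(out)
})

test_that("occurrence conservation holds on random panels", {
    set.seed(14)
    for (rep in 1:10) {
        panel <- replicate(sample(2:6, 1),
            replicate(sample(1:10, 1), randDna(sample(3:6, 1))),
            simplify = FALSE)
        ms <- buildMotifSet(panel)
        expect_identical(occurrenceTotal(ms),
                         length(unlist(panel)))
    }
})

test_that("locus filters flag each exclusion rule", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12000))
    f <- applyLocusFilters(gr)
    expect_identical(GenomicRanges::mcols(f)$flags, "length")
    gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2, consensus = "AT"))$flags,
        "dinucleotide")
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2, consensus = "A"))$flags,
        "homopolymer")
    big <- randMotifSet(8)
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2, motifSet = big,
                                               maxMotifs = 7))$flags,
        "motif_count")
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2,
            teFraction = 0.5))$flags, "te_fraction")
    cen <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2,
            masks = list(centromere = cen)))$flags, "centromere")
    expect_identical(
        GenomicRanges::mcols(applyLocusFilters(gr2, consensus = "ACGGT",
            teFraction = 0.1))$flags, "")
})

test_that("full catalog pass recovers the motif structure of a clean locus", {
    set.seed(15)
    seqs <- vapply(1:4, function(h)
        paste(sample(c("ACGGT", "ACCGT"), 20, replace = TRUE, prob = c(.8, .2)),
              collapse = ""), character(1))
    cat0 <- catalogLocus(seqs, candidates = "ACGGT", locusId = "L1")
    expect_s4_class(cat0$motifSet, "MotifSet")
    expect_setequal(motifs(cat0$motifSet), c("ACGGT", "ACCGT"))
    expect_identical(occurrenceTotal(cat0$motifSet), 80L)
    expect_identical(cat0$consensus, "ACGGT")
})
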