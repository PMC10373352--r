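# Sequence decomposition into motif strings and the motif-string metrics.

test_that("worked decomposition examples", {
    d <- decomposeSequence("ACGGTACGGTACCGTACGT", "ACGGT")
    expect_identical(length(d), 4L)
    expect_identical(totalCost(d), 2)
    d3 <- decomposeSequence("ACGGTACGGTACCGTACGT",
                            c("ACGGT", "ACCGT", "ACGT"))
    expect_identical(motifs(d3)[blocks(d3)$motif],
                     c("ACGGT", "ACGGT", "ACCGT", "ACGT"))
    expect_identical(totalCost(d3), 0)
    d2 <- decomposeSequence("ACGGTACGGT", "ACGGT")
    expect_identical(length(d2), 2L)
    expect_identical(totalCost(d2), 0)
    expect_error(decomposeSequence("ACGT", character(0)), "non-empty")
})

test_that("blocks tile the sequence exactly and costs add up", {
    set.seed(31)
    for (rep in 1:20) {
        motifs <- unique(replicate(sample(1:3, 1), randDna(sample(2:6, 1))))
        s <- paste(c(sample(motifs, sample(2:6, 1), replace = TRUE),
                     randDna(sample(0:4, 1))), collapse = "")
        d <- decomposeSequence(s, motifs)
        b <- blocks(d)
        expect_identical(b$start[1], 0L)
        expect_identical(b$end[nrow(b)], nchar(s))
        if (nrow(b) > 1)
            expect_identical(b$start[-1], b$end[-nrow(b)])
        expect_identical(sum(b$cost), as.integer(totalCost(d)))
        # per-block costs are the true block-vs-motif edit distances
        expect_identical(b$cost,
            as.integer(mapply(function(s0, e0, m)
                drop(adist(substring(s, s0 + 1, e0), motifs[m])),
                b$start, b$end, b$motif)))
    }
})

test_that("decomposition cost matches the exhaustive partition enumeration", {
    set.seed(32)
    for (rep in 1:15) {
        motifs <- unique(replicate(sample(1:3, 1), randDna(sample(2:5, 1))))
        s <- randDna(sample(4:11, 1))
        expect_identical(totalCost(decomposeSequence(s, motifs, exact = TRUE)),
                         enumDecomposeCost(s, motifs))
    }
})

test_that("translation inverts zero-cost decompositions and bounds hold", {
    d <- decomposeSequence("ACGGTACGGT", "ACGGT")
    expect_identical(translateAnnotation(d), "ACGGTACGGT")
    expect_identical(translateAnnotation(c(1, 1, 2), c("AC", "GT")),
                     "ACACGT")
    set.seed(33)
    for (rep in 1:20) {
        motifs <- unique(replicate(sample(1:3, 1), randDna(sample(2:6, 1))))
        s <- randDna(sample(5:30, 1))
        d <- decomposeSequence(s, motifs)
        expect_lte(drop(adist(translateAnnotation(d), s)), totalCost(d))
    }
    # the 4-block worked example attains equality
    d3 <- decomposeSequence("ACGGTACGGTACCGTACGT", "ACGGT")
    expect_equal(drop(adist(translateAnnotation(d3),
                            "ACGGTACGGTACCGTACGT")),
                 totalCost(d3), ignore_attr = TRUE)
})

test_that("cost is zero exactly for concatenations of motifs", {
    set.seed(34)
    for (rep in 1:20) {
        motifs <- unique(replicate(2, randDna(sample(3:6, 1))))
        exact <- paste(sample(motifs, 5, replace = TRUE), collapse = "")
        expect_identical(totalCost(decomposeSequence(exact, motifs)), 0)
        corrupted <- paste0(substr(exact, 1, nchar(exact) - 1),
            setdiff(c("A", "C", "G", "T"),
                    substr(exact, nchar(exact), nchar(exact)))[1])
        expect_gt(totalCost(decomposeSequence(corrupted, motifs)), 0)
    }
})

test_that("adding a motif never increases decomposition cost", {
    set.seed(35)
    for (rep in 1:20) {
        motifs <- unique(replicate(2, randDna(sample(3:6, 1))))
        s <- randDna(sample(8:30, 1))
        c1 <- totalCost(decomposeSequence(s, motifs))
        c2 <- totalCost(decomposeSequence(s, c(motifs, randDna(4))))
        expect_lte(c2, c1)
    }
})

test_that("motif-string edit distance agrees with a recursive oracle", {
    expect_identical(motifStringDist(c(1, 2, 1), c(1, 1)), 1L)
    expect_identical(motifStringDist(c(3, 3), c(3, 3)), 0L)
    expect_identical(motifStringDist(character(0), c("a", "b")), 2L)
    set.seed(36)
    for (rep in 1:40) {
        a <- sample(1:4, sample(0:6, 1), replace = TRUE)
        b <- sample(1:4, sample(0:6, 1), replace = TRUE)
        expect_identical(motifStringDist(a, b),
                         as.integer(recEdSymbols(a, b)))
    }
})

test_that("unique decodability is decided correctly", {
    # equal-length distinct motifs are prefix-free, hence decodable
    expect_true(uniquelyDecodable(c("ACGGT", "ACCGT", "TTAGC")))
    expect_true(uniquelyDecodable("ACGT"))
    # AGA = A + GA = AG + A
    expect_false(uniquelyDecodable(c("A", "AG", "GA")))
    # left- and right-extended variants of a core motif collide
    expect_false(uniquelyDecodable(c("TATTGTT", "TTATTGTT", "TATTGTTT")))
    # decodable despite mixed lengths
    expect_true(uniquelyDecodable(c("AC", "GT", "AGT")))
    # brute-force cross-check: a set is flagged ambiguous iff two distinct
    # short motif strings spell the same sequence
    set.seed(37)
    for (rep in 1:20) {
        mset <- unique(replicate(3, randDna(sample(2:4, 1))))
        ud <- uniquelyDecodable(mset)
        strings <- list(integer(0))
        spell <- function(ix) paste(mset[ix], collapse = "")
        combos <- expand.grid(rep(list(seq_along(mset)), 3))
        seqs <- apply(combos, 1, spell)
        # ambiguity among concatenations of up to 3 motifs implies not UD
        if (anyDuplicated(seqs)) expect_false(ud)
    }
})

test_that("annotation error normalizes by truth length", {
    expect_identical(annotationError(1:5, 1:5), 0)
    expect_identical(annotationError(c(1:49, 99), 1:50), 1 / 50)
    expect_identical(annotationError(integer(0), 1:7), 1)
    expect_error(annotationError(1:3, integer(0)), "non-empty")
})
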