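# Efficient motif selection: cost matrix, delta bound, exact optimizer vs
# brute-force oracle, greedy baseline, replacement annotation.

toySet <- function() MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"),
                              c(10L, 3L, 1L))

test_that("pairwise cost matrix is a unit-cost edit distance matrix", {
    d <- motifDistances(MotifSet(c("AAAG", "AAAC"), c(1L, 1L)))
    expect_identical(d["AAAG", "AAAC"], 1L)
    expect_identical(diag(d), c(AAAG = 0L, AAAC = 0L))
    d2 <- motifDistances(c("AAAG", "TGTGACCTGCAC"))
    expect_gte(d2[1, 2], 8L)              # length difference lower bound
    set.seed(21)
    ms <- randMotifSet(6)
    d3 <- motifDistances(ms)
    expect_true(isSymmetric(unname(d3)))
    # spot-check against a direct DP implementation
    for (k in 1:5) {
        ij <- sample(6, 2)
        expect_identical(d3[ij[1], ij[2]],
            .cpp <- VNTRmotifs:::.cpp_edit_distance(motifs(ms)[ij[1]],
                                                    motifs(ms)[ij[2]]))
    }
})

test_that("delta bound follows the quantile-times-multiset rule", {
    ms <- MotifSet("ACGGT", 4L)
    expect_identical(deltaBound(ms, 0.5)$delta, 0)
    expect_identical(deltaBound(toySet(), 0)$delta, 0)
    db <- deltaBound(toySet(), 0.6)
    expect_identical(db$quantile, 1)      # 55th of 91 sorted distances
    expect_equal(db$delta, 1 * 14 * 0.6)
    # distinct-pair mode ignores copy multiplicities
    dd <- deltaBound(toySet(), 0.3, pairs = "distinct")
    expect_identical(dd$quantile, 1)      # 1st of the 3 distinct-pair distances
    expect_identical(deltaBound(MotifSet("AC", 1L), 0.9)$delta, 0)
})

test_that("the optimizer reproduces the printed toy selection", {
    es <- selectEfficientMotifs(toySet(), delta = 4)
    expect_identical(efficientMotifs(es), c("AAAG", "TGTGACCTGCAC"))
    a <- assignment(es)
    expect_identical(motifs(es)[a[2]], "AAAG")   # AAAC -> AAAG
    expect_identical(totalCost(es), 3)
})

test_that("delta = 0 yields the identity plan", {
    ms <- toySet()
    es <- selectEfficientMotifs(ms, q = 0)
    expect_identical(efficientMotifs(es), motifs(ms))
    expect_identical(assignment(es), seq_len(3L))
    expect_identical(totalCost(es), 0)
    expect_identical(compressionRatio(es), 1)
})

test_that("tiny instance solved by hand: {A, AT} collapses onto A", {
    ms <- MotifSet(c("A", "AT"), c(5L, 1L))
    es <- selectEfficientMotifs(ms, delta = 2)
    expect_identical(efficientMotifs(es), "A")
    expect_identical(totalCost(es), 1)
})

test_that("exact optimizer equals the brute-force subset oracle", {
    set.seed(22)
    for (rep in 1:120) {
        p <- sample(2:7, 1)
        ms <- randMotifSet(p)
        q <- sample(c(0.1, 0.2, 0.3, 0.5, 0.8), 1)
        es <- selectEfficientMotifs(ms, q = q)
        bf <- bruteForceSelect(ms, q = q)
        expect_equal(replacementPlan(es)@objective,
                     replacementPlan(bf)@objective)
        expect_identical(efficientMotifs(es), efficientMotifs(bf))
        expect_identical(assignment(es), assignment(bf))
    }
})

test_that("no motif is assigned to a representative with smaller count", {
    set.seed(23)
    for (rep in 1:30) {
        ms <- randMotifSet(sample(2:9, 1))
        es <- selectEfficientMotifs(ms, q = runif(1))
        o <- unname(motifCounts(ms))
        expect_true(all(o[assignment(es)] >= o))
        d <- replacementPlan(es)@delta
        if (d > 0) expect_lt(totalCost(es), d)
        expect_lte(compressionRatio(es), 1)
    }
})

test_that("efficient set size is non-increasing in q", {
    set.seed(24)
    for (rep in 1:15) {
        ms <- randMotifSet(sample(3:8, 1), maxCount = 30)
        sizes <- vapply(c(0, 0.1, 0.2, 0.3, 0.5, 0.9), function(q)
            length(selectEfficientMotifs(ms, q = q)), integer(1))
        expect_true(all(diff(sizes) <= 0))
    }
})

test_that("the solver refuses loci above the exact-search cap", {
    ms <- randMotifSet(9)
    expect_error(selectEfficientMotifs(ms, q = 0.3, maxMotifs = 8),
                 "cap")
    expect_error(bruteForceSelect(randMotifSet(9), q = 0.1), "limited")
})

test_that("greedy baseline picks top counts and maps by distance", {
    g <- greedySelect(toySet(), 2)
    expect_identical(efficientMotifs(g), c("AAAG", "AAAC"))
    gAll <- greedySelect(toySet(), 3)
    expect_identical(efficientMotifs(gAll), motifs(toySet()))
    # count tie at k = 1 resolved lexicographically
    tie <- MotifSet(c("GGGG", "CCCC"), c(2L, 2L))
    expect_identical(efficientMotifs(greedySelect(tie, 1)), "CCCC")
})

test_that("replacement annotation substitutes per occurrence", {
    es <- selectEfficientMotifs(toySet(), delta = 4)
    expect_identical(replacementAnnotation(c("AAAC", "AAAG"), es),
                     c("AAAG", "AAAG"))
    idn <- selectEfficientMotifs(toySet(), q = 0)
    expect_identical(replacementAnnotation(c("AAAC", "AAAG"), idn),
                     c("AAAC", "AAAG"))
    expect_error(replacementAnnotation("TTTT", es), "unknown motif")
})

test_that("replacement divergence is bounded by the plan cost (small panel)", {
    set.seed(25)
    for (rep in 1:20) {
        ms <- randMotifSet(sample(2:6, 1), maxCount = 5)
        occ <- sample(motifs(ms), 30, replace = TRUE,
                      prob = unname(motifCounts(ms)))
        panelSet <- buildMotifSet(list(occ), normalize = FALSE)
        es <- selectEfficientMotifs(panelSet, q = 0.4)
        seqv <- paste(occ, collapse = "")
        repl <- paste(replacementAnnotation(occ, es), collapse = "")
        expect_lte(drop(adist(repl, seqv)), totalCost(es))
    }
})
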