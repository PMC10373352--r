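# Locus sequence extraction, haplotype partitioning, locus calling and
# whole-sample annotation on programmatically built alignments.

test_that("CIGAR walking extracts the query interval mapped to the locus", {
    ext <- VNTRmotifs:::.extractByCigar
    q <- strrep("ACGT", 25)                       # 100 bp, all matches
    # locus covering reference bases 11..20 of a pos-1 100M alignment
    expect_identical(ext(1L, "100M", q, 11L, 20L), substr(q, 11, 20))
    # 5-base reference deletion before the locus shifts the query window
    expect_identical(ext(1L, "5M5D90M", q, 11L, 20L), substr(q, 6, 15))
    # alignment ending inside the locus is not spanning
    expect_identical(ext(1L, "15M", q, 11L, 20L), NA_character_)
    # alignment starting after the locus start is not spanning
    expect_identical(ext(12L, "50M", q, 11L, 20L), NA_character_)
    # insertion inside the locus is included in the extracted sequence
    expect_identical(ext(1L, "15M3I85M", q, 11L, 20L),
                     substr(q, 11, 23))
    # deletion spanning the whole locus yields an empty allele
    expect_identical(ext(1L, "10M10D90M", q, 11L, 20L), "")
})

test_that("read partitioning follows tags, then the max-cut heuristic", {
    ids <- paste0("r", 1:4)
    # phase tags take precedence
    pt <- partitionReads(ids, hp = c(1L, 2L, 1L, 2L))
    expect_identical(pt$method, "tag-based")
    expect_identical(pt$partitions, list(c("r1", "r3"), c("r2", "r4")))
    expect_identical(pt$phasedFraction, 1)
    # single-site A,A,G,G split
    al <- matrix(c("A", "A", "G", "G"), ncol = 1,
                 dimnames = list(ids, "500"))
    pt2 <- partitionReads(ids, alleles = al)
    expect_identical(pt2$method, "maxcut")
    expect_setequal(pt2$partitions[[1]], c("r1", "r2"))
    expect_setequal(pt2$partitions[[2]], c("r3", "r4"))
    # no heterozygous evidence -> single partition
    pt3 <- partitionReads(ids)
    expect_identical(pt3$method, "unphased")
    expect_identical(pt3$partitions, list(ids))
})

test_that("partitioning is invariant to read input order", {
    set.seed(41)
    ids <- paste0("r", 1:8)
    al <- matrix(sample(c("A", "G"), 16, replace = TRUE), ncol = 2,
                 dimnames = list(ids, c("10", "20")))
    ref <- partitionReads(ids, alleles = al)
    for (k in 1:5) {
        perm <- sample(ids)
        pt <- partitionReads(perm, alleles = al[perm, , drop = FALSE])
        expect_setequal(pt$partitions[[1]], ref$partitions[[1]])
        if (length(ref$partitions) > 1)
            expect_setequal(pt$partitions[[2]], ref$partitions[[2]])
    }
})

test_that("locus calling is consensus + decomposition, robust to one bad read", {
    cl <- callLocus(list(rep("ACGGTACGGT", 3), rep("ACGGTACGGT", 3)),
                    "ACGGT")
    expect_identical(cl$h1, c(0L, 0L))
    expect_identical(cl$h2, c(0L, 0L))
    expect_identical(cl$zygosity, "het")
    # single partition duplicates to both haplotypes as homozygous
    clh <- callLocus(list("ACGGTACGGT"), "ACGGT")
    expect_identical(clh$zygosity, "hom")
    # medoid ignores a minority read carrying an error
    clr <- callLocus(list(c("ACGGTACGGT", "ACGGTACGGT", "ACGTTACGGT")),
                     "ACGGT")
    expect_identical(clr$h1, c(0L, 0L))
    expect_identical(clr$cost1, 0)
})

test_that("contig-mode annotation recovers exact motif concatenations", {
    set.seed(42)
    cfg <- SimConfig(nLoci = 6, motifCountRange = c(10L, 20L),
                     flank = 200L)
    g <- simulateDiploidGenome(cfg)
    db <- motifSetsToDb(g$motifSets, g$loci)
    bam <- tempBam(contigAlignments(g), nchar(g$ref))
    res <- annotateSample(bam, db, mode = "contig", sample = "s1")
    expect_identical(nrow(res$calls), 6L)
    expect_identical(length(res$uncovered), 0L)
    expect_true(all(res$calls$cost1 == 0) && all(res$calls$cost2 == 0))
    for (k in 1:6) {
        expect_identical(res$calls$h1[k],
                         paste(g$truth[[k]][[1]] - 1L, collapse = ","))
        expect_identical(res$calls$h2[k],
                         paste(g$truth[[k]][[2]] - 1L, collapse = ","))
    }
})

test_that("error-free phased reads reproduce the contig-mode calls", {
    set.seed(43)
    cfg <- SimConfig(nLoci = 5, motifCountRange = c(10L, 20L),
                     flank = 300L, readLength = 900L, readDepth = 30)
    g <- simulateDiploidGenome(cfg)
    db <- motifSetsToDb(g$motifSets, g$loci)
    cres <- annotateSample(tempBam(contigAlignments(g), nchar(g$ref)),
                           db, mode = "contig")
    rres <- annotateSample(tempBam(simulateReads(g, cfg), nchar(g$ref)),
                           db, mode = "read")
    expect_identical(as.data.frame(cres$calls[, c("locusId", "h1", "h2")]),
                     as.data.frame(rres$calls[, c("locusId", "h1", "h2")]))
    expect_true(all(rres$calls$method == "tag-based"))
    expect_true(all(rres$calls$phasedFraction == 1))
})

test_that("untagged reads are phased through flank SNVs by max-cut", {
    set.seed(44)
    cfg <- SimConfig(nLoci = 3, motifCountRange = c(8L, 14L),
                     flank = 400L, readLength = 1200L, readDepth = 30)
    g <- simulateDiploidGenome(cfg, flankSnvs = 4L)
    db <- motifSetsToDb(g$motifSets, g$loci)
    cres <- annotateSample(tempBam(contigAlignments(g), nchar(g$ref)),
                           db, mode = "contig")
    reads <- simulateReads(g, cfg, hpTags = FALSE)
    rres <- annotateSample(tempBam(reads, nchar(g$ref)), db, mode = "read",
                           flank = 400L)
    expect_true(all(rres$calls$method %in% c("maxcut", "unphased")))
    # allele sets must agree per locus (partition order is arbitrary)
    for (k in seq_len(nrow(cres$calls))) {
        expect_setequal(c(rres$calls$h1[k], rres$calls$h2[k]),
                        c(cres$calls$h1[k], cres$calls$h2[k]))
    }
})

test_that("uncovered loci are reported", {
    set.seed(45)
    cfg <- SimConfig(nLoci = 2, motifCountRange = c(8L, 12L), flank = 150L)
    g <- simulateDiploidGenome(cfg)
    db <- motifSetsToDb(g$motifSets, g$loci)
    aln <- contigAlignments(g)
    # truncate contigs so they end before the second locus
    cut <- GenomicRanges::start(g$loci)[2] - 50L
    aln$seq <- substr(aln$seq, 1, cut)
    aln$cigar <- paste0(cut, "M")
    bam <- tempBam(aln, nchar(g$ref))
    res <- annotateSample(bam, db, mode = "contig")
    expect_identical(nrow(res$calls), 1L)
    expect_identical(res$uncovered,
                     GenomicRanges::mcols(g$loci)$locusId[2])
})
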