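# Synthetic VNTR loci, panels, divergence and read-like errors with known
# ground truth. All functions draw from R's RNG; set.seed() before calling
# for reproducible output.

.randBase <- function(n, exclude = NULL) {
    bases <- c("A", "C", "G", "T")
    if (!is.null(exclude)) bases <- setdiff(bases, exclude)
    sample(bases, n, replace = TRUE)
}

.randMotif <- function(len) paste(.randBase(len), collapse = "")

# Derive a variant of `base` by per-base mutation at rate `div`.
.variantMotif <- function(base, div) {
    ch <- strsplit(base, "", fixed = TRUE)[[1L]]
    hit <- runif(length(ch)) < div
    for (i in which(hit)) {
        ev <- sample(c("sub", "del", "dup"), 1L)
        ch[i] <- switch(ev,
            sub = .randBase(1L, exclude = ch[i]),
            del = "",
            dup = strrep(ch[i], 2L))
    }
    paste(ch, collapse = "")
}

#' Simulate a locus motif set
#'
#' Draws a random base motif and derives the remaining motifs as diverged
#' variants of it, emulating a VNTR locus where most motifs arose by
#' mutation from a common unit. Motif sampling weights decay geometrically
#' with rank (one or two dominant motifs, a tail of rare ones), matching the
#' skewed occurrence counts of real loci. The set is constrained to be a
#' uniquely decodable code (see \code{\link{uniquelyDecodable}}) so that the
#' ground-truth motif string of a simulated sequence is identifiable.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param locusId optional identifier.
#' @return A \code{\linkS4class{MotifSet}} whose counts encode the sampling
#'   frequencies.
#' @export
simulateMotifSet <- function(config = SimConfig(), locusId = NA_character_) {
    stopifnot(is(config, "SimConfig"))
    nM <- sample(seq(config@nMotifRange[1L], config@nMotifRange[2L]), 1L)
    len <- sample(seq(config@motifLengthRange[1L],
                      config@motifLengthRange[2L]), 1L)
    base <- .randMotif(len)
    ms <- base
    tries <- 0L
    while (length(ms) < nM && tries < 300L) {
        v <- .variantMotif(base, config@motifDivergence)
        # keep the motif set a uniquely decodable code so that simulated
        # ground-truth motif strings are identifiable from the sequence
        if (nchar(v) >= 1L && !(v %in% ms) && uniquelyDecodable(c(ms, v)))
            ms <- c(ms, v)
        tries <- tries + 1L
    }
    w <- config@freqDecay^(seq_along(ms) - 1L)
    counts <- pmax(1L, as.integer(round(w / sum(w) * 100L)))
    MotifSet(ms, counts, locusId = locusId)
}

#' Simulate one VNTR sequence from a motif set
#'
#' Draws the motif count uniformly from the configured range and samples
#' motifs i.i.d. with probability proportional to their counts, recording
#' the ground-truth motif string. Motif sets with a single motif are
#' refused (variation introduced downstream would be concealed by motif
#' homogeneity).
#'
#' @param motifSet a \code{\linkS4class{MotifSet}} with at least 2 motifs.
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with \code{sequence}, \code{truthIdx} (motif indices into
#'   \code{motifs(motifSet)}), and \code{truthMotifs}.
#' @export
simulateLocus <- function(motifSet, config = SimConfig()) {
    stopifnot(is(motifSet, "MotifSet"))
    if (length(motifSet) < 2L)
        stop("motif sets with a single motif are excluded from simulation")
    n <- sample(seq(config@motifCountRange[1L], config@motifCountRange[2L]),
                1L)
    idx <- sample(length(motifSet), n, replace = TRUE,
                  prob = motifSet@counts)
    list(sequence = paste(motifs(motifSet)[idx], collapse = ""),
         truthIdx = idx,
         truthMotifs = motifs(motifSet)[idx])
}

#' Add point mutations and short insertions to a sequence
#'
#' Each base is independently mutated with probability \code{pointRate}; the
#' event type is uniform over substitution (to a different base), deletion,
#' and duplication. Independently, with probability \code{insRate} per base a
#' uniform-random 2--4 bp string is inserted before the base. Events are
#' applied left-to-right on the original coordinates.
#'
#' @param sequence DNA string.
#' @param pointRate,insRate per-base event rates in \code{[0, 1]}.
#' @return The mutated DNA string.
#' @export
mutateSequence <- function(sequence, pointRate = 0, insRate = 0) {
    stopifnot(pointRate >= 0, pointRate <= 1, insRate >= 0, insRate <= 1)
    if (pointRate == 0 && insRate == 0) return(sequence)
    ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    out <- ch
    hit <- runif(n) < pointRate
    for (i in which(hit)) {
        ev <- sample(c("sub", "del", "dup"), 1L)
        out[i] <- switch(ev,
            sub = .randBase(1L, exclude = ch[i]),
            del = "",
            dup = strrep(ch[i], 2L))
    }
    insHit <- runif(n) < insRate
    for (i in which(insHit)) {
        k <- sample(2:4, 1L)
        out[i] <- paste0(paste(.randBase(k), collapse = ""), out[i])
    }
    paste(out, collapse = "")
}

#' Simulate a panel of loci with per-haplotype sequences
#'
#' For each locus, draws a motif set and generates one sequence per panel
#' haplotype (optionally mutated), returning ground truth throughout. The
#' per-locus \code{motifSet} is rebuilt from the occurrences actually
#' observed in the panel, so its counts are the panel occurrence counts.
#'
#' @param config a \code{\linkS4class{SimConfig}}; \code{pointRate} and
#'   \code{insRate} apply to the emitted sequences (truth motif strings
#'   refer to the pre-mutation sequences).
#' @return list of loci, each a list with \code{seedSet}, \code{motifSet}
#'   (panel-derived counts), \code{sequences} (mutated, one per haplotype),
#'   \code{cleanSequences}, and \code{truth} (list of index vectors into
#'   \code{motifs(motifSet)}).
#' @export
simulatePanel <- function(config = SimConfig()) {
    stopifnot(is(config, "SimConfig"))
    lapply(seq_len(config@nLoci), function(li) {
        seed <- simulateMotifSet(config, locusId = paste0("locus", li))
        haps <- lapply(seq_len(config@nHaplotypes), function(h)
            simulateLocus(seed, config))
        occ <- lapply(haps, `[[`, "truthMotifs")
        ms <- buildMotifSet(occ, normalize = FALSE,
                            locusId = paste0("locus", li))
        truth <- lapply(occ, match, table = motifs(ms))
        clean <- vapply(haps, `[[`, character(1), "sequence")
        seqs <- vapply(clean, mutateSequence, character(1),
                       pointRate = config@pointRate,
                       insRate = config@insRate, USE.NAMES = FALSE)
        list(seedSet = seed, motifSet = ms, sequences = seqs,
             cleanSequences = clean, truth = truth)
    })
}

# ---------------------------------------------------------------------------
# Diploid genome + read simulation with emitted alignments.

# run-length alignment ops (M/I/D) of a haplotype against the reference
.collapseOps <- function(op) {
    r <- rle(op)
    data.frame(op = r$values, len = r$lengths)
}

#' Simulate a diploid genome containing VNTR loci
#'
#' Builds a reference chromosome of loci separated by flanks; haplotype 1
#' equals the reference, haplotype 2 carries an independently drawn allele
#' at each locus plus heterozygous SNVs planted in the flanks (phase
#' evidence for read partitioning). Alignment operations of haplotype 2
#' against the reference are recorded so that contig and read alignments can
#' be emitted exactly.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param flankSnvs heterozygous SNVs planted per flank.
#' @return list with \code{ref}, \code{hap} (character vector of the two
#'   haplotype sequences), \code{ops} (per-haplotype alignment op tables),
#'   \code{loci} (\code{GRanges} with \code{locusId}), \code{motifSets},
#'   and \code{truth} (per locus, list of the two haplotype motif-index
#'   strings).
#' @export
simulateDiploidGenome <- function(config = SimConfig(), flankSnvs = 2L) {
    stopifnot(is(config, "SimConfig"))
    flank <- config@flank
    refParts <- hap2Parts <- character()
    op2 <- character()
    starts <- ends <- integer()
    motifSets <- list()
    truth <- list()
    refPos <- 0L
    mkFlank <- function() paste(.randBase(flank), collapse = "")
    for (li in seq_len(config@nLoci)) {
        fl <- mkFlank()
        fl2 <- fl
        if (flankSnvs > 0L) {
            at <- sample(flank, min(flankSnvs, flank))
            ch <- strsplit(fl2, "", fixed = TRUE)[[1L]]
            for (i in at) ch[i] <- .randBase(1L, exclude = ch[i])
            fl2 <- paste(ch, collapse = "")
        }
        seed <- simulateMotifSet(config, locusId = paste0("locus", li))
        a1 <- simulateLocus(seed, config)
        a2 <- simulateLocus(seed, config)
        refParts <- c(refParts, fl, a1$sequence)
        hap2Parts <- c(hap2Parts, fl2, a2$sequence)
        L1 <- nchar(a1$sequence); L2 <- nchar(a2$sequence)
        Lm <- min(L1, L2)
        op2 <- c(op2, rep("M", flank), rep("M", Lm),
                 if (L2 > L1) rep("I", L2 - L1) else rep("D", L1 - L2))
        starts <- c(starts, refPos + flank)
        ends <- c(ends, refPos + flank + L1)
        refPos <- refPos + flank + L1
        motifSets[[li]] <- seed
        truth[[li]] <- list(a1$truthIdx, a2$truthIdx)
    }
    tailFl <- mkFlank()
    refParts <- c(refParts, tailFl)
    hap2Parts <- c(hap2Parts, tailFl)
    op2 <- c(op2, rep("M", flank))
    ref <- paste(refParts, collapse = "")
    hap2 <- paste(hap2Parts, collapse = "")
    loci <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = starts + 1L, end = ends))
    GenomicRanges::mcols(loci)$locusId <-
        paste0("locus", seq_len(config@nLoci))
    list(ref = ref,
         hap = c(h1 = ref, h2 = hap2),
         ops = list(h1 = data.frame(op = "M", len = nchar(ref)),
                    h2 = .collapseOps(op2)),
         loci = loci, motifSets = motifSets, truth = truth)
}

# Slice a haplotype-vs-reference op table to a haplotype interval [a, b)
# (0-based). Returns list(pos = 1-based ref start, ops = data.frame).
# Leading/trailing insertions are trimmed from the slice.
.sliceOps <- function(ops, a, b) {
    hapPos <- 0L; refPos <- 0L
    out <- character(0)
    refStart <- NA_integer_
    for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        hapConsume <- if (op %in% c("M", "I")) len else 0L
        if (op == "D") {
            if (hapPos > a && hapPos < b) out <- c(out, rep("D", len))
            refPos <- refPos + len
            next
        }
        s <- max(a, hapPos); e <- min(b, hapPos + hapConsume)
        if (s < e) {
            if (op == "M" && is.na(refStart))
                refStart <- refPos + (s - hapPos)
            out <- c(out, rep(op, e - s))
        }
        hapPos <- hapPos + hapConsume
        if (op == "M") refPos <- refPos + len
        if (hapPos >= b) break
    }
    # trim leading/trailing I/D (an alignment must start and end with M)
    keepFrom <- 1L
    while (keepFrom <= length(out) && out[keepFrom] != "M")
        keepFrom <- keepFrom + 1L
    keepTo <- length(out)
    while (keepTo >= 1L && out[keepTo] != "M") keepTo <- keepTo - 1L
    if (keepFrom > keepTo || is.na(refStart))
        return(list(pos = NA_integer_, ops = NULL, qtrimLead = 0L))
    nTrimLead <- sum(out[seq_len(keepFrom - 1L)] == "I")
    out <- out[seq(keepFrom, keepTo)]
    list(pos = refStart + 1L, ops = .collapseOps(out), qtrimLead = nTrimLead)
}

# Apply per-base read errors to an aligned read, keeping CIGAR consistent.
# cols: per-aligned-column op ("M","I","D"); bases: query base per M/I column.
.applyReadErrors <- function(cols, bases, rates) {
    if (all(rates == 0)) return(list(cols = cols, bases = bases))
    qIdx <- which(cols != "D")
    newCols <- as.list(cols)
    newBase <- character(length(cols))
    newBase[qIdx] <- bases
    for (ci in qIdx) {
        u <- runif(3L)
        if (u[1L] < rates[1L])                        # substitution
            newBase[ci] <- .randBase(1L, exclude = newBase[ci])
        if (u[3L] < rates[3L]) {                      # deletion of query base
            if (cols[ci] == "M") { newCols[[ci]] <- "D"; newBase[ci] <- "" }
            else { newCols[[ci]] <- character(0); newBase[ci] <- "" }
        } else if (u[2L] < rates[2L]) {               # insertion after base
            newCols[[ci]] <- c(newCols[[ci]], "I")
            newBase[ci] <- paste0(newBase[ci], .randBase(1L))
        }
    }
    colsOut <- unlist(newCols, use.names = FALSE)
    basesOut <- strsplit(paste(newBase, collapse = ""), "", fixed = TRUE)[[1L]]
    list(cols = colsOut, bases = basesOut)
}

#' Simulate aligned long reads from a diploid genome
#'
#' Samples reads uniformly along both haplotypes at the configured depth,
#' applies per-base errors from the read profile, and emits alignment
#' records against the reference (positions and CIGAR derived from the known
#' haplotype-to-reference alignment composed with the error process). Reads
#' carry an \code{HP} tag with their source haplotype by default, emulating
#' a phased run; drop the tags to exercise the phasing heuristic.
#'
#' @param genome result of \code{\link{simulateDiploidGenome}}.
#' @param config a \code{\linkS4class{SimConfig}} (depth, read length, error
#'   rates).
#' @param hpTags attach source-haplotype \code{HP} tags.
#' @return \code{data.frame} of alignment records (one per read): qname,
#'   rname, pos, cigar, seq, hp.
#' @export
simulateReads <- function(genome, config = SimConfig(), hpTags = TRUE) {
    stopifnot(is(config, "SimConfig"))
    rl <- config@readLength
    out <- list()
    rid <- 0L
    for (h in 1:2) {
        hapSeq <- genome$hap[h]
        hapLen <- nchar(hapSeq)
        # placement allows partial overlap at the ends, so inflate the read
        # count to keep per-base coverage at depth/2 per haplotype
        nReads <- max(1L, round(config@readDepth / 2 *
                                (hapLen + rl - 1L) / rl))
        # uniform placement incl. partial overlap at ends
        startPos <- sample(seq(-rl + 2L, hapLen - 1L), nReads, replace = TRUE)
        for (s in startPos) {
            a <- max(0L, s); b <- min(hapLen, s + rl)
            if (b - a < 50L) next
            sl <- .sliceOps(genome$ops[[h]], a, b)
            if (is.na(sl$pos)) next
            cols <- rep(sl$ops$op, sl$ops$len)
            nq <- sum(cols != "D")
            bases <- strsplit(substr(hapSeq, a + 1L + sl$qtrimLead,
                                     a + sl$qtrimLead + nq), "",
                              fixed = TRUE)[[1L]]
            err <- .applyReadErrors(cols, bases, config@readError)
            cig <- .collapseOps(err$cols)
            # drop leading/trailing deletions introduced by errors
            while (nrow(cig) && cig$op[1L] == "D") {
                sl$pos <- sl$pos + cig$len[1L]
                cig <- cig[-1L, , drop = FALSE]
            }
            while (nrow(cig) && cig$op[nrow(cig)] == "D")
                cig <- cig[-nrow(cig), , drop = FALSE]
            if (!nrow(cig)) next
            rid <- rid + 1L
            out[[rid]] <- data.frame(
                qname = sprintf("read%05d_h%d", rid, h),
                rname = "chrS", pos = sl$pos,
                cigar = paste0(cig$len, cig$op, collapse = ""),
                seq = paste(err$bases, collapse = ""),
                hp = if (hpTags) h else NA_integer_)
        }
    }
    do.call(rbind, out)
}

#' Alignment records for the two haplotype contigs
#'
#' One full-length alignment per haplotype (contig mode input).
#'
#' @param genome result of \code{\link{simulateDiploidGenome}}.
#' @return \code{data.frame} in the same shape as
#'   \code{\link{simulateReads}}.
#' @export
contigAlignments <- function(genome) {
    data.frame(
        qname = c("h1", "h2"), rname = "chrS", pos = 1L,
        cigar = vapply(genome$ops, function(o)
            paste0(o$len, o$op, collapse = ""), character(1)),
        seq = unname(genome$hap),
        hp = c(1L, 2L))
}
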