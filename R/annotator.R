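# End-to-end annotation of samples from aligned contigs or long reads:
# locus sequence extraction by CIGAR walking, haplotype partitioning (phase
# tags or a max-cut heuristic over heterozygous SNVs), per-partition
# consensus and decomposition against the locus motif database.

.cigarOps <- function(cigar) {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
    data.frame(op = ops, len = lens)
}

# Query subsequence mapped to reference interval [start, end] (1-based,
# inclusive) by walking alignment operations. Returns NA unless the
# alignment fully spans the interval. Insertions inside the interval are
# included; the interval's query end is the first query base aligned at a
# reference position past `end`.
.extractByCigar <- function(pos, cigar, seq, start, end) {
    if (pos > start) return(NA_character_)
    ops <- .cigarOps(cigar)
    refC <- pos              # next reference position to consume
    qC <- 1L                 # next query position to consume
    qs <- NA_integer_; qe <- NA_integer_
    target <- end + 1L
    for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        if (op %in% c("M", "=", "X")) {
            if (is.na(qs) && start >= refC && start < refC + len)
                qs <- qC + (start - refC)
            if (is.na(qe) && target >= refC && target < refC + len)
                qe <- qC + (target - refC)
            refC <- refC + len; qC <- qC + len
        } else if (op %in% c("I", "S")) {
            qC <- qC + len
        } else if (op %in% c("D", "N")) {
            if (is.na(qs) && start >= refC && start < refC + len)
                qs <- qC
            if (is.na(qe) && target >= refC && target < refC + len)
                qe <- qC
            refC <- refC + len
        }
        if (!is.na(qs) && !is.na(qe)) break
    }
    if (is.na(qs)) return(NA_character_)
    if (is.na(qe)) {
        if (refC == target) qe <- qC else return(NA_character_)
    }
    if (qe <= qs) return("")
    substr(seq, qs, qe - 1L)
}

#' Extract locus sequences from an alignment file
#'
#' For every alignment fully spanning the locus, returns the query
#' subsequence mapped to the locus interval via alignment-operation walking
#' (BAM stores query sequences in reference orientation, so reverse-strand
#' alignments need no further handling). Non-spanning alignments are
#' skipped.
#'
#' @param bamFile path to a coordinate-sorted, indexed BAM.
#' @param locus a length-1 \code{GRanges}.
#' @return \code{data.frame} with columns \code{id}, \code{seq}, \code{hp}
#'   (phase tag or \code{NA}); zero rows when no alignment spans the locus.
#' @export
extractLocusSequences <- function(bamFile, locus) {
    stopifnot(is(locus, "GRanges"), length(locus) == 1L)
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "pos", "cigar", "seq"),
        tag = "HP", which = locus)
    res <- Rsamtools::scanBam(bamFile, param = param)[[1L]]
    n <- length(res$qname)
    if (n == 0L)
        return(data.frame(id = character(), seq = character(),
                          hp = integer()))
    hp <- res$tag$HP
    if (is.null(hp)) hp <- rep(NA_integer_, n)
    s <- GenomicRanges::start(locus)
    e <- GenomicRanges::end(locus)
    seqs <- vapply(seq_len(n), function(i)
        .extractByCigar(res$pos[i], res$cigar[i],
                        as.character(res$seq[i]), s, e), character(1))
    keep <- !is.na(seqs)
    data.frame(id = res$qname[keep], seq = seqs[keep], hp = hp[keep])
}

#' Find heterozygous sites and per-read alleles around a locus
#'
#' Builds a read-by-site allele matrix over the locus plus flank: a position
#' is heterozygous when at least two alleles are each supported by at least
#' \code{minFrac} of the covering reads.
#'
#' @param bamFile path to BAM.
#' @param region a length-1 \code{GRanges} (locus plus flank).
#' @param minFrac minimum supporting fraction per allele (default 0.25).
#' @return character matrix (reads x sites, \code{NA} where uncovered), with
#'   read ids as rownames; zero columns when no site qualifies.
#' @export
findHetSites <- function(bamFile, region, minFrac = 0.25) {
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "pos", "cigar", "seq"), which = region)
    res <- Rsamtools::scanBam(bamFile, param = param)[[1L]]
    n <- length(res$qname)
    empty <- matrix(NA_character_, 0L, 0L)
    if (n == 0L) return(empty)
    # per-read aligned (refpos, base) pairs over M ops
    perRead <- lapply(seq_len(n), function(i) {
        ops <- .cigarOps(res$cigar[i])
        refC <- res$pos[i]; qC <- 1L
        posv <- integer(0); basev <- character(0)
        sq <- as.character(res$seq[i])
        for (k in seq_len(nrow(ops))) {
            op <- ops$op[k]; len <- ops$len[k]
            if (op %in% c("M", "=", "X")) {
                posv <- c(posv, seq(refC, length.out = len))
                basev <- c(basev,
                           strsplit(substr(sq, qC, qC + len - 1L), "",
                                    fixed = TRUE)[[1L]])
                refC <- refC + len; qC <- qC + len
            } else if (op %in% c("I", "S")) qC <- qC + len
            else if (op %in% c("D", "N")) refC <- refC + len
        }
        setNames(basev, posv)
    })
    allPos <- sort(unique(unlist(lapply(perRead, names))))
    het <- character(0)
    for (p in allPos) {
        al <- unlist(lapply(perRead, function(x) x[p]), use.names = FALSE)
        al <- al[!is.na(al)]
        if (length(al) < 2L) next
        tab <- table(al) / length(al)
        if (sum(tab >= minFrac) >= 2L) het <- c(het, p)
    }
    if (!length(het)) return(empty)
    mat <- matrix(NA_character_, n, length(het),
                  dimnames = list(res$qname, het))
    for (i in seq_len(n)) {
        hits <- intersect(het, names(perRead[[i]]))
        mat[i, hits] <- perRead[[i]][hits]
    }
    mat
}

#' Partition reads into haplotypes
#'
#' Phase tags take precedence: when present, reads are grouped by tag.
#' Otherwise a max-cut heuristic is used over the heterozygous-site allele
#' matrix: the two reads with the most disagreeing alleles seed the two
#' partitions (ties by lexicographic read-id pair), and every remaining read
#' joins the seed it shares more alleles with (ties to partition 1, counted
#' as unphased). Without any heterozygous evidence a single partition is
#' returned and the locus is called homozygous downstream.
#'
#' @param readIds character vector of read identifiers.
#' @param hp optional integer phase tags parallel to \code{readIds}.
#' @param alleles optional read-by-site allele matrix (rownames = read ids),
#'   e.g. from \code{\link{findHetSites}}.
#' @return list with \code{partitions} (list of read-id vectors),
#'   \code{method} (\code{"tag-based"}, \code{"maxcut"} or
#'   \code{"unphased"}) and \code{phasedFraction}.
#' @export
partitionReads <- function(readIds, hp = NULL, alleles = NULL) {
    stopifnot(length(readIds) >= 1L)
    if (!is.null(hp) && any(!is.na(hp))) {
        tagged <- !is.na(hp)
        parts <- split(readIds[tagged], hp[tagged])
        names(parts) <- NULL
        return(list(partitions = parts, method = "tag-based",
                    phasedFraction = mean(tagged)))
    }
    if (!is.null(alleles) && ncol(alleles) >= 1L && nrow(alleles) >= 2L) {
        ids <- rownames(alleles)
        nr <- nrow(alleles)
        disag <- function(i, j) {
            both <- !is.na(alleles[i, ]) & !is.na(alleles[j, ])
            sum(alleles[i, both] != alleles[j, both])
        }
        best <- c(0L, 0L); bestD <- -1L
        ordIds <- order(ids)
        for (ii in seq_len(nr - 1L)) for (jj in seq(ii + 1L, nr)) {
            i <- ordIds[ii]; j <- ordIds[jj]
            d <- disag(i, j)
            if (d > bestD) { bestD <- d; best <- c(i, j) }
        }
        if (bestD >= 1L) {
            s1 <- best[1L]; s2 <- best[2L]
            if (ids[s2] < ids[s1]) { tmp <- s1; s1 <- s2; s2 <- tmp }
            assignTo <- integer(nr)
            phased <- logical(nr)
            for (i in seq_len(nr)) {
                if (i == s1) { assignTo[i] <- 1L; phased[i] <- TRUE; next }
                if (i == s2) { assignTo[i] <- 2L; phased[i] <- TRUE; next }
                m1 <- sum(!is.na(alleles[i, ]) & !is.na(alleles[s1, ]) &
                          alleles[i, ] == alleles[s1, ])
                m2 <- sum(!is.na(alleles[i, ]) & !is.na(alleles[s2, ]) &
                          alleles[i, ] == alleles[s2, ])
                assignTo[i] <- if (m2 > m1) 2L else 1L
                phased[i] <- m1 != m2
            }
            keyed <- match(readIds, ids)
            parts <- list(readIds[assignTo[keyed] == 1L],
                          readIds[assignTo[keyed] == 2L])
            return(list(partitions = parts, method = "maxcut",
                        phasedFraction = mean(phased[keyed])))
        }
    }
    list(partitions = list(readIds), method = "unphased",
         phasedFraction = 0)
}

#' Call a locus from partitioned sequences
#'
#' For each partition, forms the consensus (deterministic medoid, see
#' \code{\link{consensusMotif}}) of the member sequences and decomposes it
#' against the locus motifs. A single partition yields a homozygous call
#' duplicated to both haplotypes.
#'
#' @param partitionSeqs list of 1 or 2 character vectors of locus
#'   sequences (one vector per partition; empty partitions are dropped).
#' @param dbMotifs character vector: the locus's motif list (annotation
#'   indices are 0-based positions in this list).
#' @return list with \code{h1}, \code{h2} (0-based motif index vectors),
#'   \code{cost1}, \code{cost2}, \code{zygosity} (\code{"het"} or
#'   \code{"hom"}); \code{NULL} when all partitions are empty.
#' @export
callLocus <- function(partitionSeqs, dbMotifs) {
    partitionSeqs <- Filter(length, partitionSeqs)
    if (!length(partitionSeqs)) return(NULL)
    calls <- lapply(partitionSeqs, function(seqs) {
        cons <- .medoid(seqs)
        d <- decomposeSequence(cons, dbMotifs)
        list(idx = blocks(d)$motif - 1L, cost = totalCost(d))
    })
    if (length(calls) == 1L)
        return(list(h1 = calls[[1L]]$idx, h2 = calls[[1L]]$idx,
                    cost1 = calls[[1L]]$cost, cost2 = calls[[1L]]$cost,
                    zygosity = "hom"))
    list(h1 = calls[[1L]]$idx, h2 = calls[[2L]]$idx,
         cost1 = calls[[1L]]$cost, cost2 = calls[[2L]]$cost,
         zygosity = "het")
}

#' Annotate a sample across all loci of a motif database
#'
#' Extracts locus sequences from the alignments, partitions reads by
#' haplotype (read mode), builds per-partition consensus and decomposes it
#' against each locus's motif list.
#'
#' @param bamFile coordinate-sorted, indexed BAM of aligned contigs or
#'   reads.
#' @param motifDb motif database \code{data.frame} from
#'   \code{\link{readMotifDb}} (or built in code): columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and list-column
#'   \code{motifs}.
#' @param mode \code{"contig"} (one spanning sequence per haplotype
#'   assembly) or \code{"read"}.
#' @param sample sample name recorded in the calls.
#' @param flank flank (bp) around the locus searched for heterozygous
#'   sites in read mode (default 5000).
#' @param minAlleleFrac heterozygous-site allele support fraction.
#' @return list with \code{calls} (a \code{DataFrame}: locusId, sample,
#'   h1/h2 comma-separated 0-based motif indices, len1/len2 motif counts,
#'   zygosity, method, phasedFraction, cost1, cost2) and \code{uncovered}
#'   (locus ids with no spanning sequence).
#' @export
annotateSample <- function(bamFile, motifDb, mode = c("contig", "read"),
                           sample = "sample", flank = 5000L,
                           minAlleleFrac = 0.25) {
    mode <- match.arg(mode)
    loci <- motifDbRanges(motifDb)
    rows <- list(); uncovered <- character()
    for (k in seq_along(loci)) {
        locus <- loci[k]
        lid <- GenomicRanges::mcols(loci)$locusId[k]
        dbMotifs <- motifDb$motifs[[k]]
        ext <- extractLocusSequences(bamFile, locus)
        if (nrow(ext) == 0L) { uncovered <- c(uncovered, lid); next }
        if (mode == "contig") {
            ext <- ext[order(ext$id), , drop = FALSE]
            ext <- ext[seq_len(min(2L, nrow(ext))), , drop = FALSE]
            parts <- as.list(ext$seq)
            method <- "contig"
            pf <- 1
        } else {
            alleles <- NULL
            if (all(is.na(ext$hp))) {
                region <- GenomicRanges::resize(locus,
                    GenomicRanges::width(locus) + 2L * flank, fix = "center")
                region <- GenomicRanges::trim(region)
                alleles <- findHetSites(bamFile, region,
                                        minFrac = minAlleleFrac)
                alleles <- alleles[rownames(alleles) %in% ext$id, ,
                                   drop = FALSE]
            }
            pt <- partitionReads(ext$id, hp = ext$hp, alleles = alleles)
            parts <- lapply(pt$partitions, function(idv)
                ext$seq[ext$id %in% idv])
            method <- pt$method
            pf <- pt$phasedFraction
        }
        cl <- callLocus(parts, dbMotifs)
        if (is.null(cl)) { uncovered <- c(uncovered, lid); next }
        rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
            locusId = lid, sample = sample,
            h1 = paste(cl$h1, collapse = ","),
            h2 = paste(cl$h2, collapse = ","),
            len1 = length(cl$h1), len2 = length(cl$h2),
            zygosity = cl$zygosity, method = method,
            phasedFraction = pf, cost1 = cl$cost1, cost2 = cl$cost2)
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
        S4Vectors::DataFrame(locusId = character(), sample = character(),
            h1 = character(), h2 = character(), len1 = integer(),
            len2 = integer(), zygosity = character(), method = character(),
            phasedFraction = numeric(), cost1 = numeric(),
            cost2 = numeric())
    list(calls = calls, uncovered = uncovered)
}

#' Write alignment records as SAM and prepare a sorted, indexed BAM
#'
#' Minimal SAM emission for the alignment tables produced by
#' \code{\link{simulateReads}} / \code{\link{contigAlignments}}, plus
#' conversion to a coordinate-sorted, indexed BAM via Rsamtools.
#'
#' @param aln \code{data.frame} with columns qname, rname, pos, cigar, seq
#'   and optionally hp.
#' @param refLengths named integer vector of reference sequence lengths.
#' @param samPath output SAM path.
#' @return \code{writeSam}: the SAM path, invisibly. \code{prepareBam}: the
#'   path of the sorted, indexed BAM.
#' @export
writeSam <- function(aln, refLengths, samPath) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                     as.integer(refLengths)))
    recs <- vapply(seq_len(nrow(aln)), function(i) {
        base <- paste(aln$qname[i], 0L, aln$rname[i], aln$pos[i], 60L,
                      aln$cigar[i], "*", 0L, 0L, aln$seq[i], "*",
                      sep = "\t")
        if (!is.null(aln$hp) && !is.na(aln$hp[i]))
            base <- paste0(base, "\tHP:i:", aln$hp[i])
        base
    }, character(1))
    writeLines(c(hdr, recs), samPath)
    invisible(samPath)
}

#' @rdname writeSam
#' @param samFile path to a SAM file.
#' @export
prepareBam <- function(samFile) {
    base <- sub("\\.sam$", "", samFile)
    bam <- Rsamtools::asBam(samFile, destination = paste0(base, "_raw"),
                            overwrite = TRUE, indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam, paste0(base, "_sorted"))
    Rsamtools::indexBam(sorted)
    sorted
}
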