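# Readers and writers: motif database TSV, Tandem-Repeats-Finder output,
# locus BED, and the VCF dialect used for annotation output.

.dbCols <- c("chrom", "start", "end", "motifs", "counts", "replacement")

#' Read and write the motif database TSV
#'
#' One row per locus: \code{chrom}, \code{start}, \code{end} (0-based
#' half-open), \code{motifs} (comma-separated, distinct), optional
#' \code{counts} (parallel comma-separated integers) and optional
#' \code{replacement} (comma-separated representative motif per original
#' motif, recording an efficient-selection plan). Write then read is the
#' identity.
#'
#' @param path file path.
#' @return \code{readMotifDb}: \code{data.frame} with list-columns
#'   \code{motifs}, \code{counts}, \code{replacement} (\code{NULL} entries
#'   when absent).
#' @export
readMotifDb <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    body <- lines[!startsWith(lines, "#")]
    rows <- strsplit(body, "\t", fixed = TRUE)
    parseRow <- function(i) {
        f <- rows[[i]]
        if (length(f) < 4L)
            stop("motif db line ", i, ": expected >= 4 tab-separated fields")
        start <- suppressWarnings(as.integer(f[2L]))
        end <- suppressWarnings(as.integer(f[3L]))
        if (is.na(start) || is.na(end) || start >= end)
            stop("motif db line ", i, ": invalid interval [", f[2L], ", ",
                 f[3L], ")")
        m <- strsplit(f[4L], ",", fixed = TRUE)[[1L]]
        if (length(m) == 0L || any(!nzchar(m)))
            stop("motif db line ", i, ": empty motif list")
        if (anyDuplicated(m))
            stop("motif db line ", i, ": duplicate motifs")
        cnt <- NULL
        if (length(f) >= 5L && f[5L] != ".") {
            cnt <- suppressWarnings(as.integer(
                strsplit(f[5L], ",", fixed = TRUE)[[1L]]))
            if (length(cnt) != length(m) || anyNA(cnt))
                stop("motif db line ", i, ": counts do not match motifs")
        }
        rep <- NULL
        if (length(f) >= 6L && f[6L] != ".") {
            rep <- strsplit(f[6L], ",", fixed = TRUE)[[1L]]
            if (length(rep) != length(m))
                stop("motif db line ", i,
                     ": replacement does not match motifs")
        }
        list(chrom = f[1L], start = start, end = end, motifs = m,
             counts = cnt, replacement = rep)
    }
    parsed <- lapply(seq_along(rows), parseRow)
    data.frame(
        chrom = vapply(parsed, `[[`, character(1), "chrom"),
        start = vapply(parsed, `[[`, integer(1), "start"),
        end = vapply(parsed, `[[`, integer(1), "end"),
        motifs = I(lapply(parsed, `[[`, "motifs")),
        counts = I(lapply(parsed, `[[`, "counts")),
        replacement = I(lapply(parsed, `[[`, "replacement")))
}

#' @rdname readMotifDb
#' @param db motif database \code{data.frame} (as from
#'   \code{readMotifDb}).
#' @export
writeMotifDb <- function(db, path) {
    stopifnot(all(c("chrom", "start", "end", "motifs") %in% names(db)))
    join <- function(x) if (is.null(x)) "." else paste(x, collapse = ",")
    for (i in seq_len(nrow(db))) {
        m <- db$motifs[[i]]
        if (length(m) == 0L || anyDuplicated(m))
            stop("row ", i, ": motifs must be non-empty and distinct")
        if (db$start[i] >= db$end[i])
            stop("row ", i, ": zero-length interval")
        cnt <- if ("counts" %in% names(db)) db$counts[[i]] else NULL
        if (!is.null(cnt) && length(cnt) != length(m))
            stop("row ", i, ": counts length mismatch")
    }
    lines <- c(paste0("#", paste(.dbCols, collapse = "\t")),
        vapply(seq_len(nrow(db)), function(i) {
            paste(db$chrom[i], db$start[i], db$end[i],
                  join(db$motifs[[i]]),
                  join(if ("counts" %in% names(db)) db$counts[[i]]),
                  join(if ("replacement" %in% names(db))
                      db$replacement[[i]]),
                  sep = "\t")
        }, character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' GRanges view of a motif database
#'
#' @param db motif database \code{data.frame}.
#' @return \code{GRanges} (1-based) with a \code{locusId} column
#'   (\code{chrom:start-end} on the 0-based coordinates).
#' @export
motifDbRanges <- function(db) {
    gr <- GenomicRanges::GRanges(db$chrom,
        IRanges::IRanges(start = db$start + 1L, end = db$end))
    GenomicRanges::mcols(gr)$locusId <-
        if ("locusId" %in% names(db)) db$locusId else
        sprintf("%s:%d-%d", db$chrom, db$start, db$end)
    gr
}

#' Convert a MotifSet collection to a motif database
#'
#' @param motifSets list of \code{\linkS4class{MotifSet}}.
#' @param loci \code{GRanges} parallel to \code{motifSets}.
#' @param plans optional list of \code{\linkS4class{EfficientMotifSet}}; when
#'   given, motifs are restricted to the efficient set and the replacement
#'   column records each original motif's representative.
#' @return motif database \code{data.frame}.
#' @export
motifSetsToDb <- function(motifSets, loci, plans = NULL) {
    stopifnot(length(motifSets) == length(loci))
    n <- length(motifSets)
    lid <- GenomicRanges::mcols(loci)$locusId
    if (is.null(lid))
        lid <- sprintf("%s:%d-%d",
                       as.character(GenomicRanges::seqnames(loci)),
                       GenomicRanges::start(loci) - 1L,
                       GenomicRanges::end(loci))
    data.frame(
        chrom = as.character(GenomicRanges::seqnames(loci)),
        start = GenomicRanges::start(loci) - 1L,
        end = GenomicRanges::end(loci),
        locusId = lid,
        motifs = I(lapply(seq_len(n), function(i) {
            if (is.null(plans)) motifs(motifSets[[i]])
            else efficientMotifs(plans[[i]])
        })),
        counts = I(lapply(seq_len(n), function(i) {
            if (is.null(plans)) unname(motifSets[[i]]@counts)
            else NULL
        })),
        replacement = I(lapply(seq_len(n), function(i) {
            if (is.null(plans)) NULL
            else {
                es <- plans[[i]]
                motifs(es@original)[assignment(es)]
            }
        })))
}

#' Read Tandem-Repeats-Finder output
#'
#' Supports the native \code{.dat} format (\code{Sequence:} headers followed
#' by whitespace-separated annotation records) and a TSV dialect with
#' columns locus_id, start, end, consensus, copy_number.
#'
#' @param path file path.
#' @param format \code{"dat"} or \code{"tsv"} (default: by file
#'   extension).
#' @return \code{data.frame} with columns \code{locusId}, \code{start},
#'   \code{end} (as in the file), \code{consensus}, \code{copies}.
#' @export
readTrf <- function(path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.dat$", path)) "dat" else "tsv"
    if (format == "tsv") {
        tab <- read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("locusId", "start", "end",
                                        "consensus", "copies"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric"))
        return(tab)
    }
    lines <- readLines(path)
    cur <- NA_character_
    out <- list()
    for (ln in lines) {
        if (startsWith(ln, "Sequence:")) {
            cur <- trimws(sub("^Sequence:", "", ln))
            cur <- strsplit(cur, "\\s+")[[1L]][1L]
            next
        }
        f <- strsplit(trimws(ln), "\\s+")[[1L]]
        if (length(f) < 14L || is.na(suppressWarnings(as.integer(f[1L]))))
            next
        out[[length(out) + 1L]] <- data.frame(
            locusId = cur, start = as.integer(f[1L]),
            end = as.integer(f[2L]), consensus = f[14L],
            copies = as.numeric(f[4L]))
    }
    if (!length(out))
        return(data.frame(locusId = character(), start = integer(),
                          end = integer(), consensus = character(),
                          copies = numeric()))
    do.call(rbind, out)
}

#' Read a locus (or mask) BED file
#'
#' @param path BED path.
#' @return \code{GRanges} with a \code{locusId} column (BED name when
#'   present, else \code{chrom:start-end}).
#' @export
readLociBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- GenomicRanges::mcols(gr)$name
    GenomicRanges::mcols(gr)$locusId <-
        if (!is.null(nm) && all(!is.na(nm)) && all(nzchar(nm))) nm else
        sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    gr
}

#' Write annotation calls as VCF
#'
#' One record per covered locus. The motif list is stored in INFO
#' (\code{RU}), with \code{SVTYPE=VNTR} and \code{END}; distinct annotation
#' strings across all sample haplotypes become symbolic ALT alleles and each
#' sample's GT references them. In single-sample output the two haplotype
#' annotations are additionally spelled out as \code{ALTANNO_H1/H2} and
#' \code{LEN_H1/H2}.
#'
#' @param calls \code{DataFrame} of calls from \code{\link{annotateSample}}
#'   (rows from several samples may be combined with \code{rbind}).
#' @param motifDb the motif database the calls were made against.
#' @param path output path (plain-text VCF).
#' @param refBase reference base placeholder used in REF (default
#'   \code{"N"}).
#' @return the path, invisibly.
#' @export
writeVntrVcf <- function(calls, motifDb, path, refBase = "N") {
    samples <- sort(unique(calls$sample))
    single <- length(samples) == 1L
    gr <- motifDbRanges(motifDb)
    lids <- GenomicRanges::mcols(gr)$locusId
    hdr <- c("##fileformat=VCFv4.2",
        "##source=VNTRmotifs",
        sprintf("##contig=<ID=%s>",
                unique(as.character(GenomicRanges::seqnames(gr)))),
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
        "##INFO=<ID=RU,Number=.,Type=String,Description=\"Efficient motif list of the locus\">",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
        "##INFO=<ID=ALTANNO,Number=A,Type=String,Description=\"Motif-index annotation of each ALT allele (indices joined by '-')\">",
        if (single) c(
        "##INFO=<ID=ALTANNO_H1,Number=.,Type=String,Description=\"Motif-index annotation of haplotype 1\">",
        "##INFO=<ID=ALTANNO_H2,Number=.,Type=String,Description=\"Motif-index annotation of haplotype 2\">",
        "##INFO=<ID=LEN_H1,Number=1,Type=Integer,Description=\"Motif count of haplotype 1\">",
        "##INFO=<ID=LEN_H2,Number=1,Type=Integer,Description=\"Motif count of haplotype 2\">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype over the distinct annotation alleles\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    recs <- character()
    for (k in seq_along(gr)) {
        lid <- lids[k]
        sub <- calls[calls$locusId == lid, , drop = FALSE]
        if (nrow(sub) == 0L) next
        annos <- unique(c(sub$h1, sub$h2))
        if (any(!(idxOk <- vapply(strsplit(annos, ",", fixed = TRUE),
            function(ix) all(as.integer(ix) >= 0L &
                as.integer(ix) < length(motifDb$motifs[[k]])),
            logical(1)))))
            stop("locus ", lid, ": motif index out of database range")
        alt <- paste0("<VNTR_", seq_along(annos), ">", collapse = ",")
        gts <- vapply(samples, function(sm) {
            r <- sub[sub$sample == sm, , drop = FALSE]
            if (nrow(r) == 0L) return("./.")
            paste(match(r$h1[1L], annos), match(r$h2[1L], annos),
                  sep = "/")
        }, character(1))
        info <- sprintf("END=%d;RU=%s;SVTYPE=VNTR;ALTANNO=%s",
            GenomicRanges::end(gr)[k],
            paste(motifDb$motifs[[k]], collapse = ","),
            paste(gsub(",", "-", annos, fixed = TRUE), collapse = ","))
        if (single && nrow(sub) >= 1L)
            info <- paste0(info,
                sprintf(";ALTANNO_H1=%s;ALTANNO_H2=%s;LEN_H1=%d;LEN_H2=%d",
                        sub$h1[1L], sub$h2[1L], sub$len1[1L], sub$len2[1L]))
        recs <- c(recs, paste(
            as.character(GenomicRanges::seqnames(gr))[k],
            GenomicRanges::start(gr)[k], lid, refBase, alt, ".", "PASS",
            info, "GT", paste(gts, collapse = "\t"), sep = "\t"))
    }
    writeLines(c(hdr, recs), path)
    invisible(path)
}

#' Read annotation alleles back from a VCF written by writeVntrVcf
#'
#' Uses VariantAnnotation to parse the file and reconstructs, per locus, the
#' annotation string of each sample haplotype.
#'
#' @param path VCF path.
#' @return list per locus (named by ID) of character vectors: the
#'   annotation (comma-separated motif indices) of every sample haplotype.
#' @export
readVntrVcf <- function(path) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("VariantAnnotation is required to read VCF")
    vcf <- VariantAnnotation::readVcf(path)
    info <- VariantAnnotation::info(vcf)
    gtm <- VariantAnnotation::geno(vcf)$GT
    out <- list()
    for (i in seq_len(nrow(gtm))) {
        annos <- gsub("-", ",", unlist(info$ALTANNO[i]), fixed = TRUE)
        hapAnnos <- character()
        for (g in gtm[i, ]) {
            if (g %in% c("./.", ".")) next
            idx <- as.integer(strsplit(g, "[/|]")[[1L]])
            hapAnnos <- c(hapAnnos, annos[idx])
        }
        out[[rownames(gtm)[i]]] <- hapAnnos
    }
    out
}
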