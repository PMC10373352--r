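# Population-level summaries: allele counting under motif-string / length
# definitions, edit-distance allele grouping, annotation-quality comparison
# (the 80 percent superiority rule) and motif-count curves across panel
# sizes and compression levels.

.asAnnoStrings <- function(annotations) {
    if (is.list(annotations))
        vapply(annotations, paste, character(1), collapse = ",")
    else as.character(annotations)
}

#' Count alleles at a locus with edit-distance grouping
#'
#' Distinct annotation strings are grouped into one allele when their
#' motif-string edit distance is at most \code{k}: alleles are the connected
#' components (single linkage) of the graph on distinct annotations with
#' edges where the distance is \code{<= k}. With \code{k = 0} this is the
#' number of distinct annotations.
#'
#' @param annotations the locus's haplotype annotations: a list of motif
#'   index vectors, or a character vector of comma-separated index strings.
#' @param k edit-distance grouping threshold (motifs), \code{>= 0}.
#' @return integer allele count (0 for an empty locus).
#' @examples
#' countAlleles(list(c(1, 1, 1), c(1, 1, 1), c(1, 1)), k = 0)  # 2
#' countAlleles(list(c(1, 1, 1), c(1, 1)), k = 1)              # 1
#' @export
countAlleles <- function(annotations, k = 0) {
    stopifnot(k >= 0)
    ann <- unique(.asAnnoStrings(annotations))
    ann <- ann[nzchar(ann) | ann == ""]
    n <- length(ann)
    if (n == 0L) return(0L)
    if (k == 0 || n == 1L) return(n)
    idx <- strsplit(ann, ",", fixed = TRUE)
    edges <- integer(0)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (motifStringDist(idx[[i]], idx[[j]]) <= k)
            edges <- c(edges, i, j)
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    as.integer(igraph::components(g)$no)
}

#' Per-locus allele table
#'
#' Summarizes a combined call set: distinct-annotation and distinct-length
#' allele counts plus grouped counts for each edit threshold.
#'
#' @param perLocus named list: per locus, the haplotype annotations (as in
#'   \code{\link{countAlleles}}).
#' @param k integer vector of grouping thresholds (default \code{0:3}).
#' @return \code{data.frame} with one row per locus: \code{locusId},
#'   \code{nHaplotypes}, \code{byLength}, and one \code{k<value>} column per
#'   threshold (\code{k0} equals the distinct-annotation count).
#' @export
alleleTable <- function(perLocus, k = 0:3) {
    rows <- lapply(names(perLocus), function(lid) {
        ann <- .asAnnoStrings(perLocus[[lid]])
        lens <- lengths(strsplit(ann, ",", fixed = TRUE))
        cnt <- vapply(k, function(kk) as.integer(countAlleles(ann, kk)),
                      integer(1))
        out <- data.frame(locusId = lid, nHaplotypes = length(ann),
                          byLength = length(unique(lens)))
        out[paste0("k", k)] <- as.list(cnt)
        out
    })
    do.call(rbind, rows)
}

#' Compare the quality of two annotations of the same sequence
#'
#' Each annotation is translated back to nucleotides and scored by edit
#' distance to the raw sequence. An annotation is significantly better when
#' its edit distance is less than 80 percent of the other's.
#'
#' @param sequence the raw locus sequence.
#' @param annotationA,annotationB motif index vectors (1-based into
#'   \code{motifs}).
#' @param motifs the shared motif list.
#' @return list with \code{edA}, \code{edB} and \code{verdict} in
#'   \code{a_better}, \code{a_significantly_better}, \code{b_better},
#'   \code{b_significantly_better}, \code{tie}.
#' @export
compareAnnotationQuality <- function(sequence, annotationA, annotationB,
                                     motifs) {
    edA <- as.integer(.ed(translateAnnotation(annotationA, motifs), sequence))
    edB <- as.integer(.ed(translateAnnotation(annotationB, motifs), sequence))
    verdict <- if (edA == edB) "tie"
        else if (edA < 0.8 * edB) "a_significantly_better"
        else if (edA < edB) "a_better"
        else if (edB < 0.8 * edA) "b_significantly_better"
        else "b_better"
    list(edA = edA, edB = edB, verdict = verdict)
}

#' Motif-count curve across panel sizes and compression levels
#'
#' Rebuilds per-locus original motif sets from growing subsets of the panel
#' and runs efficient selection at each q, reporting the total motif count
#' and mean compression ratio. The q = 0 curve is the number of original
#' motifs and is non-decreasing in panel size.
#'
#' @param panel list over loci; each element a list over haplotypes of
#'   ordered motif-occurrence character vectors.
#' @param q numeric vector of compression levels.
#' @param sizes integer vector of panel subsample sizes (default: 1 to the
#'   full panel).
#' @param normalize passed to \code{\link{buildMotifSet}}.
#' @param pairs quantile mode passed to \code{\link{selectEfficientMotifs}}.
#' @return \code{data.frame} with columns \code{size}, \code{q},
#'   \code{totalMotifs}, \code{meanCompression}.
#' @export
motifCountCurve <- function(panel, q = c(0, 0.1, 0.2, 0.3), sizes = NULL,
                            normalize = FALSE,
                            pairs = c("multiset", "distinct")) {
    pairs <- match.arg(pairs)
    nHap <- length(panel[[1L]])
    if (is.null(sizes)) sizes <- seq_len(nHap)
    rows <- list()
    for (s in sizes) {
        sets <- lapply(panel, function(hapOcc)
            buildMotifSet(hapOcc[seq_len(s)], normalize = normalize))
        sets <- Filter(Negate(is.null), sets)
        for (qq in q) {
            sel <- lapply(sets, function(ms)
                selectEfficientMotifs(ms, q = qq, pairs = pairs))
            rows[[length(rows) + 1L]] <- data.frame(
                size = s, q = qq,
                totalMotifs = sum(vapply(sel, length, integer(1))),
                meanCompression = mean(vapply(sel, compressionRatio,
                                              numeric(1))))
        }
    }
    do.call(rbind, rows)
}
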