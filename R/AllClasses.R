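#' MotifSet: the original motif set of a VNTR locus
#'
#' Holds the distinct motifs observed across a panel of haplotype sequences at
#' one VNTR locus, together with their occurrence counts. The occurrence
#' multiset M (all observed motif copies) is represented implicitly: motif i
#' occurs \code{counts[i]} times, so \code{sum(counts)} is the multiset size
#' ||M||.
#'
#' @slot motifs character vector of distinct uppercase DNA motifs.
#' @slot counts integer vector of per-motif occurrence counts (>= 1).
#' @slot locusId single character locus identifier (may be \code{NA}).
#'
#' @seealso \code{\link{buildMotifSet}}, \code{\link{selectEfficientMotifs}}
#' @exportClass MotifSet
setClass("MotifSet",
    representation(motifs = "character", counts = "integer",
                   locusId = "character"),
    prototype(motifs = character(), counts = integer(),
              locusId = NA_character_))

setValidity("MotifSet", function(object) {
    msg <- NULL
    if (length(object@motifs) != length(object@counts))
        msg <- c(msg, "motifs and counts must have the same length")
    if (anyDuplicated(object@motifs))
        msg <- c(msg, "motifs must be distinct")
    if (length(object@counts) && any(object@counts < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (length(object@motifs) && any(!grepl("^[ACGTN]+$", object@motifs)))
        msg <- c(msg, "motifs must be uppercase DNA (A/C/G/T/N)")
    if (length(object@locusId) != 1L)
        msg <- c(msg, "locusId must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MotifSet
#'
#' @param motifs character vector of distinct motifs.
#' @param counts integer occurrence counts, parallel to \code{motifs}.
#' @param locusId optional locus identifier.
#' @return A \code{\linkS4class{MotifSet}}.
#' @examples
#' ms <- MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"), c(10L, 3L, 1L))
#' motifs(ms)
#' occurrenceTotal(ms)
#' @export
MotifSet <- function(motifs, counts = rep(1L, length(motifs)),
                     locusId = NA_character_) {
    new("MotifSet", motifs = toupper(as.character(motifs)),
        counts = as.integer(counts), locusId = as.character(locusId)[1L])
}

#' ReplacementPlan: solution of the efficient motif selection problem
#'
#' Maps every original motif to its surviving representative. Produced by
#' \code{\link{selectEfficientMotifs}}, \code{\link{bruteForceSelect}} or
#' \code{\link{greedySelect}}.
#'
#' @slot assignment integer vector: \code{assignment[i]} is the index of the
#'   representative of original motif i.
#' @slot selected sorted integer indices of the selected motifs (the image of
#'   \code{assignment}).
#' @slot totalCost numeric, the total weighted replacement cost
#'   \eqn{\sum_i o_i \delta_{i,a(i)}}.
#' @slot delta numeric, the replacement-cost bound used (\code{NA} when a
#'   budget was not applied, e.g. greedy selection).
#' @slot lambda numeric, the set-size weight in the objective.
#' @slot objective numeric, achieved objective value.
#' @exportClass ReplacementPlan
setClass("ReplacementPlan",
    representation(assignment = "integer", selected = "integer",
                   totalCost = "numeric", delta = "numeric",
                   lambda = "numeric", objective = "numeric"))

setValidity("ReplacementPlan", function(object) {
    msg <- NULL
    if (!length(object@assignment))
        msg <- c(msg, "assignment must be non-empty")
    if (!identical(sort(unique(object@assignment)), object@selected))
        msg <- c(msg, "selected must equal the sorted image of assignment")
    if (length(object@totalCost) != 1L || object@totalCost < 0)
        msg <- c(msg, "totalCost must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
})

#' EfficientMotifSet: a compressed motif set with its replacement plan
#'
#' @slot original the \code{\linkS4class{MotifSet}} that was compressed.
#' @slot plan the \code{\linkS4class{ReplacementPlan}} mapping every original
#'   motif to its representative.
#' @exportClass EfficientMotifSet
setClass("EfficientMotifSet",
    representation(original = "MotifSet", plan = "ReplacementPlan"))

setValidity("EfficientMotifSet", function(object) {
    p <- length(object@original@motifs)
    sel <- object@plan@selected
    if (length(object@plan@assignment) != p)
        return("plan assignment length must match the original motif count")
    if (length(sel) < 1L || any(sel < 1L) || any(sel > p))
        return("selected indices out of range")
    o <- object@original@counts
    a <- object@plan@assignment
    if (any(o[a] < o))
        return("a motif is assigned to a representative with smaller count")
    TRUE
})

#' MotifDecomposition: a sequence tiled into motif-assigned blocks
#'
#' The blocks partition the sequence exactly (contiguous, non-overlapping,
#' covering \code{[0, nchar(sequence))}), each block assigned one motif and
#' carrying its edit cost against that motif.
#'
#' @slot sequence the decomposed DNA string.
#' @slot motifs the motif list the sequence was decomposed against.
#' @slot blocks \code{data.frame} with columns \code{start}, \code{end}
#'   (0-based half-open), \code{motif} (index into \code{motifs}) and
#'   \code{cost}.
#' @slot totalCost numeric, sum of block costs (minimal over all tilings).
#' @exportClass MotifDecomposition
setClass("MotifDecomposition",
    representation(sequence = "character", motifs = "character",
                   blocks = "data.frame", totalCost = "numeric"))

setValidity("MotifDecomposition", function(object) {
    b <- object@blocks
    n <- nchar(object@sequence)
    msg <- NULL
    if (!all(c("start", "end", "motif", "cost") %in% names(b)))
        return("blocks must have columns start, end, motif, cost")
    if (nrow(b)) {
        if (b$start[1L] != 0L || b$end[nrow(b)] != n)
            msg <- c(msg, "blocks must cover the whole sequence")
        if (nrow(b) > 1L && any(b$start[-1L] != b$end[-nrow(b)]))
            msg <- c(msg, "blocks must be contiguous and non-overlapping")
        if (any(b$motif < 1L | b$motif > length(object@motifs)))
            msg <- c(msg, "block motif indices out of range")
        if (sum(b$cost) != object@totalCost)
            msg <- c(msg, "totalCost must equal the sum of block costs")
    } else if (n > 0L) {
        msg <- c(msg, "non-empty sequence with no blocks")
    }
    if (is.null(msg)) TRUE else msg
})

#' SimConfig: parameters of the VNTR locus/read simulator
#'
#' Defaults encode the simulation conditions used throughout the package's
#' evaluation: sequences of 50--100 motifs sampled by frequency, point
#' mutation rates of 0/1/2 percent with event type uniform over substitution,
#' deletion and duplication, an optional 1 percent rate of 2--4 bp insertions,
#' and a parametric long-read error model.
#'
#' @slot nLoci number of loci to simulate.
#' @slot nHaplotypes panel haplotypes per locus.
#' @slot motifCountRange integer range of motif copies per sequence.
#' @slot nMotifRange integer range of distinct motifs per locus motif set.
#' @slot motifLengthRange integer range of motif lengths (bp).
#' @slot motifDivergence per-base mutation probability used when deriving
#'   variant motifs from a locus base motif.
#' @slot freqDecay geometric decay of motif sampling weights (rank r has
#'   weight \code{freqDecay^(r-1)}).
#' @slot pointRate per-base point mutation rate (events uniform over
#'   substitution / deletion / duplication).
#' @slot insRate per-base rate of 2--4 bp insertion events.
#' @slot readDepth target sequencing depth for read simulation.
#' @slot readLength read length (bp).
#' @slot readError per-base read error rates (substitution, insertion,
#'   deletion).
#' @slot flank flank length (bp) placed around each locus in the simulated
#'   reference.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(nLoci = "integer", nHaplotypes = "integer",
                   motifCountRange = "integer", nMotifRange = "integer",
                   motifLengthRange = "integer", motifDivergence = "numeric",
                   freqDecay = "numeric", pointRate = "numeric",
                   insRate = "numeric", readDepth = "numeric",
                   readLength = "integer", readError = "numeric",
                   flank = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    rng <- function(x) length(x) == 2L && x[1L] <= x[2L] && x[1L] >= 1L
    if (!rng(object@motifCountRange)) msg <- c(msg, "bad motifCountRange")
    if (!rng(object@nMotifRange)) msg <- c(msg, "bad nMotifRange")
    if (!rng(object@motifLengthRange)) msg <- c(msg, "bad motifLengthRange")
    rates <- c(object@pointRate, object@insRate, object@readError,
               object@motifDivergence)
    if (any(rates < 0 | rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (object@nMotifRange[1L] < 2L)
        msg <- c(msg, "nMotifRange minimum must be >= 2 (single-motif loci are excluded from simulation)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimConfig
#'
#' @param nLoci,nHaplotypes,motifCountRange,nMotifRange,motifLengthRange
#'   see \code{\linkS4class{SimConfig}}.
#' @param motifDivergence,freqDecay,pointRate,insRate see
#'   \code{\linkS4class{SimConfig}}.
#' @param readDepth,readLength,readError,flank see
#'   \code{\linkS4class{SimConfig}}. Preset read error profiles:
#'   \code{readErrorProfile("hifi-like")} (about 1.9 percent total error) and
#'   \code{readErrorProfile("ont-like")} (about 11 percent).
#' @return A \code{\linkS4class{SimConfig}}.
#' @examples
#' cfg <- SimConfig(nLoci = 5, pointRate = 0.01)
#' @export
SimConfig <- function(nLoci = 10L, nHaplotypes = 8L,
                      motifCountRange = c(50L, 100L),
                      nMotifRange = c(3L, 10L),
                      motifLengthRange = c(6L, 15L),
                      motifDivergence = 0.2, freqDecay = 0.6,
                      pointRate = 0, insRate = 0,
                      readDepth = 30, readLength = 3000L,
                      readError = c(0, 0, 0), flank = 1000L) {
    new("SimConfig", nLoci = as.integer(nLoci),
        nHaplotypes = as.integer(nHaplotypes),
        motifCountRange = as.integer(motifCountRange),
        nMotifRange = as.integer(nMotifRange),
        motifLengthRange = as.integer(motifLengthRange),
        motifDivergence = motifDivergence, freqDecay = freqDecay,
        pointRate = pointRate, insRate = insRate, readDepth = readDepth,
        readLength = as.integer(readLength), readError = readError,
        flank = as.integer(flank))
}

#' Preset read error profiles
#'
#' Aggregate per-base error rates emulating the accuracy of current long-read
#' platforms (high-fidelity circular consensus at roughly 98 percent accuracy,
#' nanopore at roughly 89 percent). Only the aggregate rates are modelled, not
#' instrument-specific error structure.
#'
#' @param name \code{"hifi-like"}, \code{"ont-like"} or \code{"error-free"}.
#' @return numeric length-3 vector (substitution, insertion, deletion rates).
#' @export
readErrorProfile <- function(name = c("error-free", "hifi-like", "ont-like")) {
    switch(match.arg(name),
        "error-free" = c(0, 0, 0),
        "hifi-like"  = c(0.007, 0.006, 0.006),   # ~1.9% total
        "ont-like"   = c(0.04, 0.035, 0.035))    # ~11% total
}
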