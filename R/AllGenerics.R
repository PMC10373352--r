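#' @rdname MotifSet
#' @param x,object a \code{MotifSet}, \code{EfficientMotifSet} or
#'   \code{MotifDecomposition}.
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))

#' @rdname MotifSet
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @rdname MotifSet
#' @export
setGeneric("occurrenceTotal", function(x) standardGeneric("occurrenceTotal"))

#' @rdname EfficientMotifSet-accessors
#' @export
setGeneric("efficientMotifs", function(x) standardGeneric("efficientMotifs"))

#' @rdname EfficientMotifSet-accessors
#' @export
setGeneric("replacementPlan", function(x) standardGeneric("replacementPlan"))

#' @rdname EfficientMotifSet-accessors
#' @export
setGeneric("compressionRatio", function(x) standardGeneric("compressionRatio"))

#' @rdname EfficientMotifSet-accessors
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))

#' @rdname EfficientMotifSet-accessors
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' @rdname decomposeSequence
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

# ---- MotifSet methods ----

#' @rdname MotifSet
#' @export
setMethod("motifs", "MotifSet", function(x) x@motifs)

#' @rdname MotifSet
#' @export
setMethod("motifCounts", "MotifSet", function(x)
    setNames(x@counts, x@motifs))

#' @rdname MotifSet
#' @export
setMethod("occurrenceTotal", "MotifSet", function(x) sum(x@counts))

#' @rdname MotifSet
#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))

setMethod("show", "MotifSet", function(object) {
    cat(sprintf("MotifSet%s with %d motif(s), ||M|| = %d\n",
        if (is.na(object@locusId)) "" else paste0(" [", object@locusId, "]"),
        length(object@motifs), sum(object@counts)))
    n <- min(length(object@motifs), 6L)
    if (n) {
        for (i in seq_len(n))
            cat(sprintf("  %s (o = %d)\n", object@motifs[i], object@counts[i]))
        if (length(object@motifs) > n) cat("  ...\n")
    }
})

# ---- EfficientMotifSet / ReplacementPlan methods ----

#' Accessors for EfficientMotifSet and ReplacementPlan
#'
#' @param x an \code{EfficientMotifSet} or \code{ReplacementPlan}.
#' @return \code{efficientMotifs}: character vector of selected motifs;
#'   \code{replacementPlan}: the \code{ReplacementPlan}; \code{assignment}:
#'   named integer vector mapping original motif index to representative
#'   index; \code{totalCost}: the achieved replacement cost;
#'   \code{compressionRatio}: selected / original motif count.
#' @name EfficientMotifSet-accessors
NULL

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("efficientMotifs", "EfficientMotifSet", function(x)
    x@original@motifs[x@plan@selected])

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("replacementPlan", "EfficientMotifSet", function(x) x@plan)

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("compressionRatio", "EfficientMotifSet", function(x)
    length(x@plan@selected) / length(x@original@motifs))

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("totalCost", "EfficientMotifSet", function(x) x@plan@totalCost)

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("totalCost", "ReplacementPlan", function(x) x@totalCost)

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("assignment", "ReplacementPlan", function(x) x@assignment)

#' @rdname EfficientMotifSet-accessors
#' @export
setMethod("assignment", "EfficientMotifSet", function(x) x@plan@assignment)

#' @rdname MotifSet
#' @export
setMethod("motifs", "EfficientMotifSet", function(x) x@original@motifs)

#' @rdname MotifSet
#' @export
setMethod("length", "EfficientMotifSet", function(x)
    length(x@plan@selected))

setMethod("show", "EfficientMotifSet", function(object) {
    p <- length(object@original@motifs)
    k <- length(object@plan@selected)
    cat(sprintf("EfficientMotifSet: %d / %d motifs (ratio %.2f), cost %g",
                k, p, k / p, object@plan@totalCost))
    if (!is.na(object@plan@delta))
        cat(sprintf(", delta %g", object@plan@delta))
    cat("\n  selected:", paste(efficientMotifs(object), collapse = ", "), "\n")
})

setMethod("show", "ReplacementPlan", function(object) {
    cat(sprintf("ReplacementPlan: %d motif(s) -> %d representative(s), cost %g\n",
        length(object@assignment), length(object@selected), object@totalCost))
})

# ---- MotifDecomposition methods ----

#' @rdname decomposeSequence
#' @export
setMethod("blocks", "MotifDecomposition", function(x) x@blocks)

#' @rdname decomposeSequence
#' @export
setMethod("totalCost", "MotifDecomposition", function(x) x@totalCost)

#' @rdname decomposeSequence
#' @export
setMethod("motifs", "MotifDecomposition", function(x) x@motifs)

#' @rdname decomposeSequence
#' @export
setMethod("length", "MotifDecomposition", function(x) nrow(x@blocks))

setMethod("show", "MotifDecomposition", function(object) {
    cat(sprintf("MotifDecomposition: %d bp into %d block(s), total cost %g\n",
        nchar(object@sequence), nrow(object@blocks), object@totalCost))
    cat("  motif string:",
        paste(object@motifs[object@blocks$motif], collapse = " "), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d loci x %d haplotypes, %d-%d motifs/seq, ",
                       "point %.3f, ins %.3f, depth %gx\n"),
        object@nLoci, object@nHaplotypes, object@motifCountRange[1L],
        object@motifCountRange[2L], object@pointRate, object@insRate,
        object@readDepth))
})
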