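# Efficient motif selection: replacement cost matrix, the locus-specific
# bound Delta = Q(q) * ||M|| * q, the exact optimizer (branch-and-bound over
# representative subsets, equivalent to the integer program), a brute-force
# subset oracle, and the greedy frequency baseline.

#' Pairwise motif replacement cost matrix
#'
#' The cost of replacing motif i by motif j is the unit-cost Levenshtein
#' distance between them.
#'
#' @param x a \code{\linkS4class{MotifSet}} or character vector of motifs.
#' @return A symmetric integer matrix with zero diagonal, dimnames the
#'   motifs.
#' @export
motifDistances <- function(x) {
    m <- if (is(x, "MotifSet")) motifs(x) else as.character(x)
    .stopifempty(m, "motif set")
    d <- adist(m)
    storage.mode(d) <- "integer"
    dimnames(d) <- list(m, m)
    d
}

#' Locus-specific replacement-cost bound
#'
#' Computes \eqn{\Delta = Q(q) \times ||M|| \times q}, where Q(q) is the
#' lower empirical q-quantile (no interpolation) of the pairwise edit
#' distances over all unordered index pairs of the occurrence multiset M.
#' By default identical copies of a motif contribute zero-distance pairs
#' (\code{pairs = "multiset"}); \code{pairs = "distinct"} restricts to pairs
#' of distinct motifs. \code{q = 0} always yields \eqn{\Delta = 0} (no
#' compression), as does a multiset with fewer than two occurrences.
#'
#' @param motifSet a \code{\linkS4class{MotifSet}} (counts define the
#'   multiset M).
#' @param q compression strength in \code{[0, 1]}.
#' @param pairs \code{"multiset"} (default) or \code{"distinct"}.
#' @param costs optional precomputed \code{\link{motifDistances}} matrix.
#' @return list with \code{quantile} (Q(q)) and \code{delta}.
#' @examples
#' ms <- MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"), c(10L, 3L, 1L))
#' deltaBound(ms, 0.6)  # Q = 1, delta = 8.4
#' @export
deltaBound <- function(motifSet, q, pairs = c("multiset", "distinct"),
                       costs = NULL) {
    stopifnot(is(motifSet, "MotifSet"), q >= 0, q <= 1)
    pairs <- match.arg(pairs)
    o <- motifSet@counts
    M <- sum(o)
    if (is.null(costs)) costs <- motifDistances(motifSet)
    p <- length(o)
    # pair distances with multiplicities
    if (pairs == "multiset") {
        vals <- 0                                   # within-motif pairs
        wts <- sum(choose(o, 2))
        if (p > 1L) {
            ut <- upper.tri(costs)
            vals <- c(vals, costs[ut])
            wts <- c(wts, (o %o% o)[ut])
        }
        N <- choose(M, 2)
    } else {
        if (p > 1L) {
            ut <- upper.tri(costs)
            vals <- costs[ut]
            wts <- rep(1, length(vals))
        } else {
            vals <- numeric(0)
            wts <- numeric(0)
        }
        N <- choose(p, 2)
    }
    keep <- wts > 0
    vals <- vals[keep]
    wts <- wts[keep]
    if (N < 1 || length(vals) == 0L)
        return(list(quantile = 0, delta = 0))
    ordv <- order(vals)
    vals <- vals[ordv]
    wts <- wts[ordv]
    k <- max(1, ceiling(q * N))
    Q <- vals[which(cumsum(wts) >= k)[1L]]
    delta <- if (q == 0) 0 else Q * M * q
    list(quantile = as.numeric(Q), delta = as.numeric(delta))
}

# integer budget implementing the strict bound `cost < delta` on integer
# replacement costs; negative when even the identity plan is out of budget
.deltaBudget <- function(delta) {
    if (abs(delta - round(delta)) < 1e-9) round(delta) - 1 else floor(delta)
}

.identityPlan <- function(motifSet, delta, lambda) {
    p <- length(motifSet)
    plan <- new("ReplacementPlan", assignment = seq_len(p),
                selected = seq_len(p), totalCost = 0,
                delta = as.numeric(delta), lambda = as.numeric(lambda),
                objective = as.numeric(lambda) * p)
    new("EfficientMotifSet", original = motifSet, plan = plan)
}

.resolveLambda <- function(lambda, o, d) {
    if (identical(lambda, "set-size-dominant"))
        1 + sum(as.numeric(o) * apply(d, 1L, max))
    else as.numeric(lambda)
}

#' Select the efficient motif set of a locus
#'
#' Finds the subset of the original motif set, and an assignment of every
#' original motif to a representative in that subset, minimizing
#' \eqn{\lambda \cdot |\tilde\Sigma| + \sum_i o_i \delta_{i,a(i)}} subject to
#' the total replacement cost being strictly below \eqn{\Delta}, each motif
#' having exactly one representative, and representatives never having a
#' smaller count than the motifs they replace. The optimum is computed
#' exactly by branch-and-bound over representative subsets (for a fixed
#' subset, each motif's optimal representative is its nearest admissible
#' subset member, so the search over subsets is equivalent to the full
#' integer program). Ties among optima are broken by the lexicographically
#' smallest selected-motif list.
#'
#' With the default \code{lambda = "set-size-dominant"}
#' (\eqn{\lambda = 1 + \sum_i o_i \max_j \delta_{ij}}) the objective is
#' lexicographic: minimize the efficient set size first, replacement cost
#' second, making \code{q} the single user knob.
#'
#' When \eqn{\Delta \le 0} (in particular \code{q = 0}) the identity plan is
#' returned: no compression. The strict bound is implemented on integer
#' costs as \code{cost <= ceiling(delta) - 1} for integral \eqn{\Delta},
#' \code{cost <= floor(delta)} otherwise.
#'
#' @param motifSet a \code{\linkS4class{MotifSet}}.
#' @param q compression strength; used to derive \code{delta} via
#'   \code{\link{deltaBound}} when \code{delta} is not given.
#' @param delta explicit replacement-cost bound (overrides \code{q}).
#' @param lambda \code{"set-size-dominant"} or a non-negative number.
#' @param costs optional precomputed cost matrix.
#' @param pairs quantile mode passed to \code{\link{deltaBound}}.
#' @param maxMotifs refuse loci with more motifs than this (such loci should
#'   have been filtered; the exact search is exponential in the motif
#'   count).
#' @param nodeCap search-node budget before the solver aborts with an error
#'   naming the locus.
#' @return An \code{\linkS4class{EfficientMotifSet}} (the replacement plan is
#'   available via \code{\link{replacementPlan}}).
#' @examples
#' ms <- MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"), c(10L, 3L, 1L))
#' es <- selectEfficientMotifs(ms, delta = 4)
#' efficientMotifs(es)   # AAAG and TGTGACCTGCAC; AAAC is replaced by AAAG
#' @export
selectEfficientMotifs <- function(motifSet, q = NULL, delta = NULL,
                                  lambda = "set-size-dominant",
                                  costs = NULL,
                                  pairs = c("multiset", "distinct"),
                                  maxMotifs = 30L, nodeCap = 5e7) {
    stopifnot(is(motifSet, "MotifSet"), length(motifSet) >= 1L)
    pairs <- match.arg(pairs)
    if (is.null(costs)) costs <- motifDistances(motifSet)
    o <- motifSet@counts
    lam <- .resolveLambda(lambda, o, costs)
    if (is.null(delta)) {
        if (is.null(q)) stop("provide either q or delta")
        delta <- deltaBound(motifSet, q, pairs = pairs, costs = costs)$delta
    }
    B <- .deltaBudget(delta)
    if (delta <= 0 || B < 0)
        return(.identityPlan(motifSet, delta, lam))
    p <- length(motifSet)
    if (p > maxMotifs)
        stop("locus ", motifSet@locusId, " has ", p, " motifs; exceeds the ",
             "exact-solver cap (", maxMotifs, ") - it should have been ",
             "filtered upstream")
    res <- tryCatch(
        .cpp_select_bnb(o, costs, motifs(motifSet), B, lam, nodeCap),
        error = function(e) stop("efficient motif selection failed for ",
                                 "locus ", motifSet@locusId, ": ",
                                 conditionMessage(e), call. = FALSE))
    plan <- new("ReplacementPlan",
                assignment = as.integer(res$assignment),
                selected = sort(unique(as.integer(res$assignment))),
                totalCost = res$cost, delta = as.numeric(delta),
                lambda = lam, objective = res$objective)
    new("EfficientMotifSet", original = motifSet, plan = plan)
}

#' Brute-force oracle for efficient motif selection
#'
#' Exhaustively enumerates every nonempty subset of the motif set as the
#' candidate selected set; for each subset every motif is assigned to its
#' nearest admissible member (count no smaller than its own; ties by larger
#' count, then lexicographically smaller motif), which is optimal for a
#' fixed subset since the objective sums independently over motifs. Feasible
#' subsets are ranked by the same objective and tie rules as
#' \code{\link{selectEfficientMotifs}}. Intended as an independent oracle on
#' small instances.
#'
#' @inheritParams selectEfficientMotifs
#' @param maxMotifs refuse instances with more than this many motifs
#'   (default 8).
#' @return An \code{\linkS4class{EfficientMotifSet}}.
#' @export
bruteForceSelect <- function(motifSet, q = NULL, delta = NULL,
                             lambda = "set-size-dominant", costs = NULL,
                             pairs = c("multiset", "distinct"),
                             maxMotifs = 8L) {
    stopifnot(is(motifSet, "MotifSet"))
    pairs <- match.arg(pairs)
    p <- length(motifSet)
    if (p > maxMotifs)
        stop("brute-force oracle limited to ", maxMotifs, " motifs")
    if (is.null(costs)) costs <- motifDistances(motifSet)
    o <- motifSet@counts
    m <- motifs(motifSet)
    lam <- .resolveLambda(lambda, o, costs)
    if (is.null(delta)) {
        if (is.null(q)) stop("provide either q or delta")
        delta <- deltaBound(motifSet, q, pairs = pairs, costs = costs)$delta
    }
    B <- .deltaBudget(delta)
    if (delta <= 0 || B < 0)
        return(.identityPlan(motifSet, delta, lam))
    best <- NULL
    for (mask in seq_len(2^p - 1L)) {
        Tset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        assign <- integer(p)
        cost <- 0
        ok <- TRUE
        for (i in seq_len(p)) {
            valid <- Tset[o[Tset] >= o[i]]
            if (!length(valid)) { ok <- FALSE; break }
            dv <- costs[i, valid]
            cand <- valid[dv == min(dv)]
            cand <- cand[order(-o[cand], m[cand])]
            assign[i] <- cand[1L]
            cost <- cost + o[i] * costs[i, assign[i]]
        }
        if (!ok || cost > B) next
        sel <- sort(unique(assign))
        obj <- lam * length(sel) + cost
        lst <- sort(m[sel])
        if (is.null(best) || obj < best$obj - 1e-9 ||
            (abs(obj - best$obj) <= 1e-9 &&
             paste(lst, collapse = "\r") < paste(best$lst, collapse = "\r"))) {
            best <- list(obj = obj, assign = assign, sel = sel,
                         cost = cost, lst = lst)
        }
    }
    if (is.null(best)) stop("no feasible selection (budget too small)")
    plan <- new("ReplacementPlan", assignment = best$assign,
                selected = best$sel, totalCost = as.numeric(best$cost),
                delta = as.numeric(delta), lambda = lam,
                objective = best$obj)
    new("EfficientMotifSet", original = motifSet, plan = plan)
}

#' Greedy frequency baseline for motif selection
#'
#' Selects the k most frequent motifs (ties by lexicographic order) and maps
#' every remaining motif to its nearest selected motif by edit distance
#' (ties by higher count, then lexicographic order).
#'
#' @param motifSet a \code{\linkS4class{MotifSet}}.
#' @param k number of motifs to keep, \code{1 <= k <= length(motifSet)}.
#' @return An \code{\linkS4class{EfficientMotifSet}} (with \code{delta} and
#'   \code{lambda} unset).
#' @examples
#' ms <- MotifSet(c("AAAG", "AAAC", "TGTGACCTGCAC"), c(10L, 3L, 1L))
#' efficientMotifs(greedySelect(ms, 2))  # AAAG, AAAC
#' @export
greedySelect <- function(motifSet, k) {
    stopifnot(is(motifSet, "MotifSet"),
              k >= 1L, k <= length(motifSet))
    o <- motifSet@counts
    m <- motifs(motifSet)
    sel <- order(-o, m)[seq_len(k)]
    costs <- motifDistances(motifSet)
    assign <- vapply(seq_along(m), function(i) {
        dv <- costs[i, sel]
        cand <- sel[dv == min(dv)]
        cand <- cand[order(-o[cand], m[cand])]
        cand[1L]
    }, integer(1))
    cost <- sum(as.numeric(o) * costs[cbind(seq_along(m), assign)])
    plan <- new("ReplacementPlan", assignment = assign,
                selected = sort(unique(assign)), totalCost = cost,
                delta = NA_real_, lambda = NA_real_, objective = NA_real_)
    new("EfficientMotifSet", original = motifSet, plan = plan)
}

#' Replacement annotation of an occurrence list
#'
#' Substitutes every motif occurrence by its representative under a
#' replacement plan; the length in motifs is preserved. The translated
#' replacement annotation diverges from the raw sequence by at most the
#' plan's total replacement cost (summed over the panel).
#'
#' @param occ character vector of motif occurrences (each must be in the
#'   original motif set).
#' @param efficientSet an \code{\linkS4class{EfficientMotifSet}}.
#' @return character vector of representative motifs, same length as
#'   \code{occ}.
#' @export
replacementAnnotation <- function(occ, efficientSet) {
    stopifnot(is(efficientSet, "EfficientMotifSet"))
    m <- motifs(efficientSet@original)
    idx <- match(occ, m)
    if (anyNA(idx))
        stop("unknown motif(s): ",
             paste(unique(occ[is.na(idx)]), collapse = ", "))
    m[efficientSet@plan@assignment[idx]]
}
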