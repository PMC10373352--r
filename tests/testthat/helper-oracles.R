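# Fixture generators and independent oracles used across the suite.

randDna <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random MotifSet with distinct motifs.
randMotifSet <- function(p, lenRange = c(3L, 8L), maxCount = 20L) {
    ms <- character(0)
    while (length(ms) < p) {
        m <- randDna(sample(seq(lenRange[1L], lenRange[2L]), 1L))
        if (!(m %in% ms)) ms <- c(ms, m)
    }
    MotifSet(ms, sample(maxCount, p, replace = TRUE))
}

# Unbounded decomposition cost oracle: bottom-up over suffixes, vectorized
# edit distances via adist. Independent of the package's C++ tiling DP
# (different language, no block-length bound, cost only).
oracleDecomposeCost <- function(s, motifs) {
    n <- nchar(s)
    memo <- rep(NA_real_, n + 1L)
    memo[n + 1L] <- 0
    for (i in n:1) {
        subs <- substring(s, i, i:n)
        d <- adist(subs, motifs)            # (n-i+1) x K
        memo[i] <- min(apply(d, 1L, min) + memo[(i + 1L):(n + 1L)])
    }
    memo[1L]
}

# Pure recursive enumeration over all partitions and motif assignments,
# no memoization; tractable only for very short sequences.
enumDecomposeCost <- function(s, motifs) {
    n <- nchar(s)
    if (n == 0L) return(0)
    best <- Inf
    for (L in seq_len(n)) {
        block <- substr(s, 1L, L)
        rest <- enumDecomposeCost(substring(s, L + 1L), motifs)
        for (m in motifs)
            best <- min(best, drop(adist(block, m)) + rest)
    }
    best
}

# Recursive symbol-level Levenshtein (for motif strings of length <= 6).
recEdSymbols <- function(a, b) {
    if (!length(a)) return(length(b))
    if (!length(b)) return(length(a))
    min(recEdSymbols(a[-1L], b) + 1L,
        recEdSymbols(a, b[-1L]) + 1L,
        recEdSymbols(a[-1L], b[-1L]) + (a[1L] != b[1L]))
}

# Connected components of distinct annotation strings under a distance
# threshold, by breadth-first search over an explicit adjacency matrix.
componentsOracle <- function(annList, k) {
    ann <- unique(vapply(annList, paste, character(1), collapse = ","))
    n <- length(ann)
    if (n == 0L) return(0L)
    idx <- strsplit(ann, ",", fixed = TRUE)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        adj[i, j] <- motifStringDist(idx[[i]], idx[[j]]) <= k
    seen <- logical(n)
    comps <- 0L
    for (i in seq_len(n)) {
        if (seen[i]) next
        comps <- comps + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (seen[v]) next
            seen[v] <- TRUE
            queue <- c(queue, which(adj[v, ] & !seen))
        }
    }
    comps
}

# Build a sorted, indexed BAM from alignment records in a temp dir.
tempBam <- function(aln, refLen) {
    sam <- tempfile(fileext = ".sam")
    writeSam(aln, c(chrS = refLen), sam)
    prepareBam(sam)
}
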