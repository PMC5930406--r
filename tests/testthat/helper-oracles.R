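# Independent brute-force oracles. Deliberately written in a different style
# from the package code (plain loops, no shared helpers) so that agreement is
# informative.

# Single-pass reimplementation of the per-array calling chain: floored F/B
# ratios, block-median scaling, mean/SD (or median/MAD) threshold, both-spot
# duplicate rule. `spots` is the design spot table; `fg`, `bg`, `flag` are
# aligned vectors.
oracle_call_array <- function(spots, fg, bg, flag, k = 5, floor = 0.1,
                              estimator = "mean_sd") {
    medB <- median(bg)
    ratio <- numeric(length(fg))
    for (i in seq_along(fg)) {
        den <- bg[i]
        if (den < floor * medB) den <- floor * medB
        r <- fg[i] / den
        if (r < floor) r <- floor
        ratio[i] <- r
    }
    included <- spots$role == "substrate" & flag == "ok"
    for (b in unique(spots$block)) {
        sel <- spots$block == b
        med <- median(ratio[sel & included])
        ratio[sel] <- ratio[sel] / med
    }
    vals <- ratio[included]
    if (estimator == "median_mad") {
        center <- median(vals); spread <- mad(vals)
    } else {
        center <- mean(vals); spread <- sd(vals)
    }
    thr <- center + k * spread
    called <- character(0)
    for (dg in unique(spots$dup_group[included])) {
        if (is.na(dg)) next
        idx <- which(spots$dup_group == dg & !is.na(spots$dup_group))
        if (!all(included[idx]) || length(idx) != 2) next
        if (ratio[idx[1]] > thr && ratio[idx[2]] > thr)
            called <- c(called, spots$gene_symbol[idx[1]])
    }
    sort(unique(called))
}

# Full-pipeline oracle: per-replicate oracle calls, indicator-matrix
# consensus, then set subtractions.
oracle_pipeline <- function(spots, reps, neg = character(0),
                            fifty = character(0), k = 5, min_support = 2,
                            estimator = "mean_sd") {
    per <- lapply(reps, function(r)
        oracle_call_array(spots, r$fg, r$bg, r$flag, k = k,
                          estimator = estimator))
    universe <- sort(unique(unlist(per)))
    out <- character(0)
    for (s in universe) {
        cnt <- 0
        for (p in per) if (s %in% p) cnt <- cnt + 1
        if (cnt >= min_support) out <- c(out, s)
    }
    out <- out[!(out %in% neg)]
    out[!(out %in% fifty)]
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from N
# elements of which the first K are marked.
oracle_hypergeom_sf <- function(k, K, n, N) {
    if (n == 0) return(if (k <= 0) 1 else 0)
    draws <- combn(N, n)
    hits <- colSums(draws <= K)
    mean(hits >= k)
}

# Regex-based motif oracles (perl lookahead reports overlapping matches).
oracle_positions <- function(sequence, pattern, offset = 0L) {
    m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) + offset
}
oracle_forward <- function(seq, psi = "AILMPFV")
    oracle_positions(seq, sprintf("(?=[%s]K.[ED])", psi), 1L)
oracle_inverted <- function(seq, psi = "AILMPFV")
    oracle_positions(seq, sprintf("(?=[ED].K[%s])", psi), 2L)
oracle_sim <- function(seq)
    oracle_positions(seq, "(?=[VIL][VIL].[VIL][VIL])", 0L)
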