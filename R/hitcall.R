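#' @include AllClasses.R conditions.R array-io.R
NULL

#' Hit-calling parameters
#'
#' Bundles the tunable parameters of the calling pipeline with their
#' defaults: the duplicate-spot threshold of mean + 5 SD on normalized F/B
#' ratios, 2-of-3 replicate consensus, a background floor of 0.1 x the median
#' background, array-wide mean/SD statistics, matched-isoform 50x
#' subtraction, and a 25% whole-array saturation limit above which a scan is
#' unusable.
#'
#' @param kSd number of standard deviations above the mean both duplicate
#'   spots must exceed.
#' @param minSupport minimum number of replicates calling a substrate.
#' @param floor dimensionless background/ratio floor (fraction of the median
#'   background).
#' @param statPopulation `"array"` (default) or `"block"`: population over
#'   which the mean and SD are computed.
#' @param subtract50x `"matched"` (matched-isoform 50x set) or `"union"`
#'   (union of both isoforms' 50x sets).
#' @param estimator `"mean_sd"` (default) or `"median_mad"` (robust variant).
#' @param maxSaturation saturated-spot fraction above which a scan is dropped.
#' @return A named list of parameters.
#' @export
hitcallParams <- function(kSd = 5, minSupport = 2L, floor = 0.1,
                          statPopulation = c("array", "block"),
                          subtract50x = c("matched", "union"),
                          estimator = c("mean_sd", "median_mad"),
                          maxSaturation = 0.25) {
    list(kSd = kSd, minSupport = as.integer(minSupport), floor = floor,
         statPopulation = match.arg(statPopulation),
         subtract50x = match.arg(subtract50x),
         estimator = match.arg(estimator), maxSaturation = maxSaturation)
}

#' Compute foreground/background ratios for one scan
#'
#' The signal intensity of a spot is its foreground divided by its local
#' background. Zero or near-zero backgrounds are floored at
#' `floor * median(background)` to keep ratios finite, and the ratio itself is
#' floored at `floor` so downstream logs are defined; both events are counted.
#' Control spots and spots flagged `bad` or `saturated` are excluded from all
#' statistics but retained in the table.
#'
#' @param scan an [ArrayScan-class].
#' @param design the matching [ArrayDesign-class].
#' @param floor small positive dimensionless floor (default 0.1).
#' @return A raw (un-normalized) [RatioMatrix-class] with attribute
#'   `n_floored` (spots whose ratio was floored).
#' @export
computeRatios <- function(scan, design, floor = 0.1) {
    validateScan(scan, design)
    stopifnot(floor > 0)
    m <- scan@measurements
    sp <- design@spots
    idx <- match(.addr_key(m$block, m$row, m$col),
                 .addr_key(sp$block, sp$row, sp$col))
    medB <- stats::median(m$background)
    if (medB <= 0 && all(m$background == 0))
        stop("degenerate scan: all backgrounds zero")
    denom <- pmax(m$background, floor * medB)
    ratio <- m$foreground / denom
    n_floored <- sum(ratio < floor)
    if (n_floored)
        .sa_log(n_floored, " ratio(s) raised to the floor value ", floor)
    ratio <- pmax(ratio, floor)
    r <- data.frame(block = m$block, row = m$row, col = m$col,
                    protein_id = sp$protein_id[idx],
                    gene_symbol = sp$gene_symbol[idx],
                    dup_group = sp$dup_group[idx],
                    ratio = ratio,
                    included = sp$role[idx] == "substrate" & m$flag == "ok",
                    stringsAsFactors = FALSE)
    out <- new("RatioMatrix", ratios = r, normalized = FALSE,
               condition = scan@condition, replicate = scan@replicate)
    attr(out, "n_floored") <- n_floored
    out
}

#' Block-median normalization
#'
#' True reactions are rare and roughly evenly dispersed over blocks, so each
#' block is forced to a median signal intensity of one: every ratio in a
#' block is divided by that block's median over included spots. Applying the
#' function twice equals applying it once (the medians are already 1).
#'
#' @param ratios a [RatioMatrix-class].
#' @param design the matching [ArrayDesign-class] (block structure).
#' @return The block-normalized [RatioMatrix-class].
#' @export
normalizeBlocks <- function(ratios, design) {
    stopifnot(is(ratios, "RatioMatrix"), is(design, "ArrayDesign"))
    r <- ratios@ratios
    for (b in sort(unique(r$block))) {
        in_b <- r$block == b
        incl <- in_b & r$included
        if (!any(incl))
            stop("block ", b, " has no included spots; cannot normalize")
        med <- stats::median(r$ratio[incl])
        # floor rule guarantees med > 0
        r$ratio[in_b] <- r$ratio[in_b] / med
    }
    new("RatioMatrix", ratios = r, normalized = TRUE,
        condition = ratios@condition, replicate = ratios@replicate)
}

.call_stats <- function(vals, estimator) {
    if (estimator == "median_mad")
        c(stats::median(vals), stats::mad(vals))
    else
        c(mean(vals), stats::sd(vals))
}

#' Call substrates on a single normalized array
#'
#' A substrate is a positive on one array when both spots of a duplicate pair
#' have normalized ratios strictly greater than mean + `kSd` x SD of all
#' included ratios (array-wide by default). Pairs containing an excluded
#' (flagged or control) spot are not callable; a protein printed more than
#' twice is called if at least one full duplicate pair passes. When the SD is
#' zero no spot strictly exceeds the mean and the result is empty.
#'
#' @param ratios a normalized [RatioMatrix-class].
#' @param design the matching [ArrayDesign-class].
#' @param kSd threshold multiplier (default 5).
#' @param statPopulation `"array"` or `"block"` statistic population.
#' @param estimator `"mean_sd"` or `"median_mad"`.
#' @return Sorted character vector of called substrate gene symbols, with the
#'   per-substrate mean pair ratio in attribute `pair_means`.
#' @export
callSingleArray <- function(ratios, design, kSd = 5,
                            statPopulation = c("array", "block"),
                            estimator = c("mean_sd", "median_mad")) {
    statPopulation <- match.arg(statPopulation)
    estimator <- match.arg(estimator)
    if (!isTRUE(ratios@normalized))
        stop("ratios must be block-normalized before calling")
    r <- ratios@ratios
    incl <- r[r$included, , drop = FALSE]
    if (!nrow(incl)) return(character(0))
    if (statPopulation == "array") {
        st <- .call_stats(incl$ratio, estimator)
        thr <- rep(st[1] + kSd * st[2], nrow(incl))
    } else {
        thr <- numeric(nrow(incl))
        for (b in unique(incl$block)) {
            st <- .call_stats(incl$ratio[incl$block == b], estimator)
            thr[incl$block == b] <- st[1] + kSd * st[2]
        }
    }
    above <- incl$ratio > thr
    called <- character(0)
    pair_means <- numeric(0)
    groups <- split(seq_len(nrow(incl)), incl$dup_group)
    for (g in groups) {
        if (length(g) != 2L) next      # partner excluded: pair not callable
        if (all(above[g])) {
            sym <- incl$gene_symbol[g[1]]
            pm <- mean(incl$ratio[g])
            if (!sym %in% called) {
                called <- c(called, sym)
                pair_means <- c(pair_means, pm)
            } else {
                pair_means[match(sym, called)] <-
                    max(pair_means[match(sym, called)], pm)
            }
        }
    }
    ord <- order(called)
    out <- called[ord]
    attr(out, "pair_means") <- stats::setNames(pair_means[ord], out)
    out
}

#' Replicate consensus
#'
#' A substrate is retained when it is called in at least `minSupport` of the
#' replicate hit sets (2 of 3 in the standard screen design).
#'
#' @param replicateSets list of character vectors (one per replicate).
#' @param minSupport minimum number of supporting replicates.
#' @return `data.frame` with columns `substrate`, `replicate_support`, sorted
#'   by substrate.
#' @export
consensusHits <- function(replicateSets, minSupport = 2L) {
    stopifnot(is.list(replicateSets), length(replicateSets) >= 1L)
    if (minSupport > length(replicateSets))
        stop("minSupport (", minSupport, ") exceeds the number of replicates (",
             length(replicateSets), ")")
    all_sub <- unlist(lapply(replicateSets, unique), use.names = FALSE)
    if (!length(all_sub))
        return(data.frame(substrate = character(),
                          replicate_support = integer()))
    tab <- table(all_sub)
    keep <- names(tab)[tab >= minSupport]
    out <- data.frame(substrate = sort(keep),
                      replicate_support = as.integer(tab[sort(keep)]))
    rownames(out) <- NULL
    out
}

#' Remove substrates also called on the negative-control arrays
#'
#' @param hits character vector of called substrates.
#' @param negativeHits consensus-called substrates of the matching-isoform
#'   limiting-enzyme negative control.
#' @return `setdiff(hits, negativeHits)`, sorted; removals are logged.
#' @export
subtractNegative <- function(hits, negativeHits) {
    removed <- intersect(hits, negativeHits)
    if (length(removed))
        .sa_log("removed by negative control: ",
                paste(removed, collapse = ", "))
    sort(setdiff(hits, negativeHits))
}

#' Derive E3 ligase-dependent substrates by 50x subtraction
#'
#' Removing the hits of the saturating-enzyme (50x) reaction from those of an
#' E3-supplemented limiting-enzyme reaction leaves the substrates whose
#' modification depends on the added E3 ligase.
#'
#' @param e3Hits substrates called in the E3 reaction (after negative-control
#'   removal).
#' @param hits50x consensus hit set of the matching 50x condition (or the
#'   union of both isoforms' sets under the union policy).
#' @return `setdiff(e3Hits, hits50x)`, sorted.
#' @export
e3Dependent <- function(e3Hits, hits50x) {
    sort(setdiff(e3Hits, hits50x))
}

.usable_scans <- function(scans, params) {
    keep <- vapply(scans, function(s)
        mean(s@measurements$flag == "saturated") <= params$maxSaturation,
        logical(1))
    if (any(!keep))
        warning(sum(!keep), " scan(s) dropped: saturated fraction above ",
                params$maxSaturation)
    scans[keep]
}

#' Run the full calling pipeline for one condition
#'
#' Fixed pipeline order: F/B ratios, block-median normalization, per-array
#' duplicate-spot calling, replicate consensus, negative-control removal,
#' and (for E3 conditions) 50x subtraction. Scans with a saturated fraction
#' above `maxSaturation` are unusable; at least two usable replicates are
#' required. Replicate input order does not affect the result.
#'
#' @param scans list of [ArrayScan-class] replicates of one condition.
#' @param design the [ArrayDesign-class].
#' @param negativeTable [HitTable-class] of the matching-isoform negative
#'   control, or `NULL` (e.g. for the negative condition itself).
#' @param table50x [HitTable-class] (or character vector) of 50x hits to
#'   subtract, or `NULL` for non-E3 conditions.
#' @param params a [hitcallParams()] list.
#' @return A [HitTable-class] with filter provenance per substrate.
#' @export
runCondition <- function(scans, design, negativeTable = NULL,
                         table50x = NULL, params = hitcallParams()) {
    stopifnot(is.list(scans), length(scans) >= 1L)
    cond <- scans[[1]]@condition
    cn <- conditionName(cond)
    if (!all(vapply(scans, function(s) conditionName(s@condition) == cn,
                    logical(1))))
        stop("scans belong to different conditions")
    scans <- .usable_scans(scans, params)
    if (length(scans) < 2L)
        stop("insufficient replication: fewer than 2 usable replicates for ",
             cn)
    scans <- scans[order(vapply(scans, function(s) s@replicate, integer(1)))]
    per_rep <- lapply(scans, function(s) {
        rm <- normalizeBlocks(computeRatios(s, design, params$floor), design)
        callSingleArray(rm, design, kSd = params$kSd,
                        statPopulation = params$statPopulation,
                        estimator = params$estimator)
    })
    cons <- consensusHits(per_rep, params$minSupport)
    filters <- "ksd,consensus"
    kept <- cons$substrate
    if (!is.null(negativeTable)) {
        neg <- if (is(negativeTable, "HitTable")) substrates(negativeTable)
               else as.character(negativeTable)
        kept <- subtractNegative(kept, neg)
        filters <- paste0(filters, ",negctrl")
    }
    is_e3 <- cond@e1e2Level == "x1" && cond@e3 != "none"
    if (is_e3 && !is.null(table50x)) {
        fifty <- if (is(table50x, "HitTable")) substrates(table50x)
                 else as.character(table50x)
        kept <- e3Dependent(kept, fifty)
        filters <- paste0(filters, ",e3dep")
    }
    cons <- cons[cons$substrate %in% kept, , drop = FALSE]
    ## mean normalized pair ratio over supporting replicates
    mean_ratio <- vapply(cons$substrate, function(s) {
        v <- unlist(lapply(per_rep, function(p) {
            pm <- attr(p, "pair_means")
            if (s %in% names(pm)) pm[[s]] else NULL
        }))
        mean(v)
    }, numeric(1))
    n <- nrow(cons)
    h <- data.frame(substrate = cons$substrate,
                    replicate_support = cons$replicate_support,
                    mean_ratio = unname(mean_ratio),
                    passed_negative_filter = rep(!is.null(negativeTable), n),
                    e3_dependent = rep(is_e3 && !is.null(table50x), n),
                    filters_passed = rep(filters, n),
                    stringsAsFactors = FALSE)
    rownames(h) <- NULL
    new("HitTable", condition = cond, hits = h)
}

#' Run the calling pipeline for a whole study
#'
#' Groups scans by condition and applies [runCondition()] in dependency
#' order: negative controls first, then the 50x conditions (negative-control
#' removal only), then the E3 conditions (negative-control removal plus
#' matched-isoform or union 50x subtraction per `params$subtract50x`).
#'
#' @param scans list of [ArrayScan-class] objects covering all conditions.
#' @param design the [ArrayDesign-class].
#' @param params a [hitcallParams()] list.
#' @return Named list of [HitTable-class] objects, one per condition, in
#'   sorted name order.
#' @export
runStudy <- function(scans, design, params = hitcallParams()) {
    nm <- vapply(scans, function(s) conditionName(s@condition), character(1))
    groups <- split(scans, nm)
    labels <- lapply(groups, function(g) g[[1]]@condition)
    is_neg <- vapply(labels, isNegativeControl, logical(1))
    is_50x <- vapply(labels, function(l) l@e1e2Level == "x50", logical(1))
    tables <- list()
    for (cn in names(groups)[is_neg])
        tables[[cn]] <- runCondition(groups[[cn]], design, params = params)
    neg_for <- function(iso) tables[[paste0("NEG-", iso)]]
    for (cn in names(groups)[is_50x])
        tables[[cn]] <- runCondition(groups[[cn]], design,
                                     negativeTable = neg_for(labels[[cn]]@sumoIsoform),
                                     params = params)
    for (cn in names(groups)[!is_neg & !is_50x]) {
        iso <- labels[[cn]]@sumoIsoform
        fifty <- if (params$subtract50x == "union")
            unique(unlist(lapply(.ISO_LEVELS, function(i) {
                t <- tables[[paste0("50X-", i)]]
                if (is.null(t)) character(0) else substrates(t)
            })))
        else tables[[paste0("50X-", iso)]]
        tables[[cn]] <- runCondition(groups[[cn]], design,
                                     negativeTable = neg_for(iso),
                                     table50x = fifty, params = params)
    }
    tables[sort(names(tables))]
}
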