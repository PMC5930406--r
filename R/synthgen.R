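#' @include AllClasses.R conditions.R
NULL

#' Construct simulation parameters
#'
#' See [SimParams-class] for the meaning and rationale of the defaults.
#' Randomness uses R's default Mersenne-Twister generator throughout, so a
#' seed fully determines every drawn value; scans are additionally
#' deterministic given `(seed, condition, replicate)`.
#'
#' @param nProteins number of distinct proteins printed in duplicate.
#' @param nBlocks,blockRows,blockCols print-grid geometry.
#' @param backgroundMeanlog,backgroundSdlog log-normal background intensity.
#' @param nullRatioSd log-scale dispersion of non-substrate F/B ratios
#'   around 1.
#' @param hitRatioMean multiplicative F/B effect of a true substrate.
#' @param hitRatioSd log-scale dispersion of the effect.
#' @param blockEffectSd log-scale dispersion of per-block factors applied to
#'   foregrounds.
#' @param replicateDropout per-replicate failure probability of a
#'   limiting-enzyme true signal (both duplicate spots drop together).
#' @param crossreactiveFraction fraction of proteins that light up on every
#'   array, including the enzyme-free negative controls.
#' @param seed integer master seed.
#' @return A validated [SimParams-class].
#' @export
simParams <- function(nProteins = 2000L, nBlocks = 16L, blockRows = 17L,
                      blockCols = 16L, backgroundMeanlog = 7,
                      backgroundSdlog = 0.5, nullRatioSd = 0.15,
                      hitRatioMean = 20, hitRatioSd = 0.2,
                      blockEffectSd = 0.3, replicateDropout = 0.1,
                      crossreactiveFraction = 0.02, seed = 1L) {
    new("SimParams", nProteins = as.integer(nProteins),
        nBlocks = as.integer(nBlocks), blockRows = as.integer(blockRows),
        blockCols = as.integer(blockCols),
        backgroundMeanlog = backgroundMeanlog,
        backgroundSdlog = backgroundSdlog, nullRatioSd = nullRatioSd,
        hitRatioMean = hitRatioMean, hitRatioSd = hitRatioSd,
        blockEffectSd = blockEffectSd, replicateDropout = replicateDropout,
        crossreactiveFraction = crossreactiveFraction,
        seed = as.integer(seed))
}

.protein_symbols <- function(params)
    sprintf("SG%05d", seq_len(params@nProteins))

## deterministic sub-seed per (seed, condition, replicate), < 2^31
.subseed <- function(seed, cname, replicate) {
    h <- sum(utf8ToInt(cname) * seq_along(utf8ToInt(cname))) %% 100003
    as.integer((as.numeric(seed) * 7919 + h * 131 + replicate) %%
               .Machine$integer.max)
}

#' Generate a synthetic array design
#'
#' Each protein is assigned one duplicate pair of spots; control spots
#' (negative, positive, landmark, cycling) are interleaved evenly through the
#' grid. Deterministic given the seed.
#'
#' @param params a [SimParams-class].
#' @return An [ArrayDesign-class].
#' @export
makeDesign <- function(params) {
    stopifnot(is(params, "SimParams"))
    capacity <- params@nBlocks * params@blockRows * params@blockCols
    n_sub <- 2L * params@nProteins
    if (capacity < n_sub)
        stop("grid capacity (", capacity, ") below 2 * nProteins (", n_sub, ")")
    set.seed(params@seed)
    n_ctrl <- capacity - n_sub
    grid <- expand.grid(col = seq_len(params@blockCols),
                        row = seq_len(params@blockRows),
                        block = seq_len(params@nBlocks))
    ctrl_idx <- if (n_ctrl > 0)
        unique(as.integer(round(seq(1, capacity, length.out = n_ctrl))))
    else integer(0)
    if (length(ctrl_idx) < n_ctrl) {      # rounding collisions: pad
        extra <- setdiff(rev(seq_len(capacity)), ctrl_idx)
        ctrl_idx <- sort(c(ctrl_idx, extra[seq_len(n_ctrl - length(ctrl_idx))]))
    }
    sub_idx <- setdiff(seq_len(capacity), ctrl_idx)
    syms <- sample(.protein_symbols(params))
    role <- character(capacity)
    pid <- character(capacity)
    gene <- character(capacity)
    dup <- rep(NA_character_, capacity)
    ctrl_roles <- rep(c("negative_control", "positive_control", "landmark"),
                      length.out = n_ctrl)
    role[ctrl_idx] <- ctrl_roles
    pid[ctrl_idx] <- toupper(ctrl_roles)
    gene[ctrl_idx] <- toupper(ctrl_roles)
    prot_at <- rep(syms, each = 2L)          # pairs on consecutive cells
    role[sub_idx] <- "substrate"
    pid[sub_idx] <- prot_at
    gene[sub_idx] <- prot_at
    dup[sub_idx] <- rep(paste0("DG", seq_len(params@nProteins)), each = 2L)
    spots <- data.frame(block = grid$block, row = grid$row, col = grid$col,
                        protein_id = pid, gene_symbol = gene, role = role,
                        dup_group = dup, stringsAsFactors = FALSE)
    new("ArrayDesign", nBlocks = params@nBlocks, blockRows = params@blockRows,
        blockCols = params@blockCols, spots = spots)
}

#' Plant ground-truth substrate sets
#'
#' Samples per-condition true substrate sets without replacement from the
#' non-cross-reactive protein universe, honoring requested pairwise
#' intersections exactly: each specified overlap is drawn from the earlier
#' set's exclusive region, so triple overlaps are zero by construction.
#' Negative-control conditions receive the cross-reactive set as their
#' expected called set. Deterministic given the seed.
#'
#' @param params a [SimParams-class].
#' @param conditions list of [ConditionLabel-class] objects.
#' @param sizes named numeric vector (by condition name) of planted set
#'   sizes; negative-control conditions may be omitted or zero.
#' @param overlapSpec optional `data.frame` with columns `a`, `b`, `shared`
#'   (condition names and requested pairwise intersection size).
#' @return A [SimTruth-class] (with empty `shared50x`; see
#'   [simulateStudy()]).
#' @export
plantTruth <- function(params, conditions, sizes, overlapSpec = NULL) {
    stopifnot(is(params, "SimParams"), is.list(conditions))
    cn <- vapply(conditions, conditionName, character(1))
    if (anyDuplicated(cn)) stop("duplicate conditions")
    set.seed(.subseed(params@seed, "plant_truth", 0L))
    syms <- .protein_symbols(params)
    n_cr <- as.integer(round(params@crossreactiveFraction * params@nProteins))
    cross <- if (n_cr > 0) sort(sample(syms, n_cr)) else character(0)
    pool <- setdiff(syms, cross)
    sets <- list()
    for (name in cn) {
        s <- if (name %in% names(sizes)) as.integer(sizes[[name]]) else 0L
        lbl <- conditions[[match(name, cn)]]
        if (isNegativeControl(lbl)) {
            if (s != 0L) stop("negative-control conditions take no planted set")
            sets[[name]] <- cross
            next
        }
        chosen <- character(0)
        if (!is.null(overlapSpec)) {
            rel <- overlapSpec[(overlapSpec$a == name &
                                overlapSpec$b %in% names(sets)) |
                               (overlapSpec$b == name &
                                overlapSpec$a %in% names(sets)), , drop = FALSE]
            for (i in seq_len(nrow(rel))) {
                other <- if (rel$a[i] == name) rel$b[i] else rel$a[i]
                if (isNegativeControl(conditions[[match(other, cn)]])) next
                o <- as.integer(rel$shared[i])
                if (o > min(s, length(sets[[other]])))
                    stop("infeasible overlap: ", o, " shared between ", name,
                         " and ", other)
                exclusive <- setdiff(sets[[other]],
                                     unlist(sets[names(sets) != other],
                                            use.names = FALSE))
                exclusive <- setdiff(exclusive, chosen)
                if (length(exclusive) < o)
                    stop("infeasible overlap spec: exclusive region of ",
                         other, " too small for ", name)
                chosen <- c(chosen, sample(exclusive, o))
            }
        }
        fresh_pool <- setdiff(pool, c(chosen,
                                      unlist(sets, use.names = FALSE)))
        need <- s - length(chosen)
        if (need < 0) stop("overlap spec exceeds requested size for ", name)
        if (length(fresh_pool) < need)
            stop("protein universe exhausted while planting ", name)
        chosen <- c(chosen, if (need > 0) sample(fresh_pool, need))
        sets[[name]] <- sort(chosen)
    }
    new("SimTruth", conditions = conditions, truth = sets[cn],
        shared50x = list(), crossReactive = cross, params = params)
}

#' Simulate one scanned array
#'
#' Backgrounds are log-normal; a per-block log-normal factor multiplies all
#' foregrounds in the block; per-spot F/B ratios are log-normal around 1 for
#' inactive spots and around `hitRatioMean` for active ones. Active spots
#' are: the condition's planted set, plus (on E3-condition arrays) the
#' matched 50x substrates recorded in `shared50x`, plus the cross-reactive
#' set on every array; positive-control and landmark spots always light up.
#' Replicate dropout applies to the limiting-enzyme (E3-condition) enzymatic
#' signals only — saturating-enzyme and cross-reactive signals are robust —
#' and drops both duplicate spots of a substrate together. Deterministic
#' given `(seed, condition, replicate)`.
#'
#' @param design an [ArrayDesign-class] from [makeDesign()].
#' @param truth a [SimTruth-class].
#' @param condition a [ConditionLabel-class] present in `truth`.
#' @param replicate replicate index.
#' @param params a [SimParams-class].
#' @return An [ArrayScan-class].
#' @export
simulateScan <- function(design, truth, condition, replicate, params) {
    stopifnot(is(design, "ArrayDesign"), is(truth, "SimTruth"),
              is(condition, "ConditionLabel"))
    cname <- conditionName(condition)
    if (!cname %in% names(truth@truth))
        stop("condition not in truth: ", cname)
    set.seed(.subseed(params@seed, cname, replicate))
    planted <- truth@truth[[cname]]
    is_e3 <- condition@e1e2Level == "x1" && condition@e3 != "none"
    shared <- if (is_e3 && cname %in% names(truth@shared50x))
        truth@shared50x[[cname]] else character(0)
    enzymatic <- if (is_e3) sort(unique(c(planted, shared))) else character(0)
    dropped <- enzymatic[stats::runif(length(enzymatic)) <
                         params@replicateDropout]
    active <- setdiff(unique(c(planted, shared, truth@crossReactive)),
                      dropped)
    sp <- design@spots
    n <- nrow(sp)
    background <- stats::rlnorm(n, params@backgroundMeanlog,
                                params@backgroundSdlog)
    blockfac <- stats::rlnorm(params@nBlocks, 0, params@blockEffectSd)
    hot <- (sp$role == "substrate" & sp$gene_symbol %in% active) |
        sp$role %in% c("positive_control", "landmark")
    ratio <- numeric(n)
    ratio[!hot] <- stats::rlnorm(sum(!hot), 0, params@nullRatioSd)
    ratio[hot] <- stats::rlnorm(sum(hot), log(params@hitRatioMean),
                                params@hitRatioSd)
    m <- data.frame(block = sp$block, row = sp$row, col = sp$col,
                    foreground = background * ratio * blockfac[sp$block],
                    background = background,
                    flag = rep("ok", n), stringsAsFactors = FALSE)
    new("ArrayScan", condition = condition, replicate = as.integer(replicate),
        measurements = m)
}

#' Default study plan
#'
#' The enumerable condition set of the screen design: for each SUMO isoform a
#' saturating-enzyme (50x) control and a limiting-enzyme negative control,
#' plus all six E3 ligases crossed with both isoforms — 16 conditions, each
#' in triplicate. Planted sizes default to 250/200 substrates for the two 50x
#' conditions and 50 E3-dependent substrates per E3 condition; half of the
#' matched-isoform 50x set also reacts on each E3-condition array
#' (`shared50xFraction`), which is what the 50x subtraction must remove.
#'
#' @param params a [SimParams-class].
#' @param e3Size planted E3-dependent substrates per E3 condition; defaults
#'   to 2.5% of the proteome (50 at the default 2000 proteins).
#' @param size50x length-2 vector: planted sizes of the SUMO1 and SUMO2 50x
#'   conditions; defaults to 12.5% and 10% of the proteome (250/200 at the
#'   default 2000 proteins), mirroring the real screen's proportions.
#' @param shared50xFraction fraction of the matched 50x set reacting on E3
#'   arrays.
#' @return A plan list with elements `conditions`, `sizes`, `overlapSpec`,
#'   `shared50xFraction`.
#' @export
defaultStudyPlan <- function(params,
                             e3Size = max(1L, round(0.025 * params@nProteins)),
                             size50x = round(c(0.125, 0.1) *
                                             params@nProteins),
                             shared50xFraction = 0.5) {
    e3s <- setdiff(.E3_LEVELS, "none")
    conditions <- list()
    sizes <- numeric(0)
    for (iso in .ISO_LEVELS) {
        conditions <- c(conditions, list(conditionLabel("x50", "none", iso),
                                         conditionLabel("x1", "none", iso)))
        sizes[paste0("50X-", iso)] <-
            size50x[[match(iso, .ISO_LEVELS)]]
        for (e3 in e3s) {
            conditions <- c(conditions, list(conditionLabel("x1", e3, iso)))
            sizes[paste0(e3, "-", iso)] <- e3Size
        }
    }
    list(conditions = conditions, sizes = sizes, overlapSpec = NULL,
         shared50xFraction = shared50xFraction)
}

#' Simulate a complete study
#'
#' Generates the design, plants the ground truth, records which matched 50x
#' substrates react on each E3 array, and simulates every condition in
#' triplicate. The plan must contain the 50x and negative-control conditions
#' the calling pipeline needs for each isoform used by an E3 condition.
#'
#' @param params a [SimParams-class].
#' @param plan a plan list as from [defaultStudyPlan()].
#' @param nReplicates replicates per condition.
#' @return A list with `design` ([ArrayDesign-class]), `scans` (flat list of
#'   [ArrayScan-class]), and `truth` ([SimTruth-class]).
#' @export
simulateStudy <- function(params, plan = defaultStudyPlan(params),
                          nReplicates = 3L) {
    stopifnot(is(params, "SimParams"))
    cn <- vapply(plan$conditions, conditionName, character(1))
    isos <- unique(vapply(Filter(function(l) l@e1e2Level == "x1" &&
                                     l@e3 != "none", plan$conditions),
                          function(l) l@sumoIsoform, character(1)))
    for (iso in isos) {
        if (!paste0("50X-", iso) %in% cn)
            stop("plan missing required 50x control for ", iso)
        if (!paste0("NEG-", iso) %in% cn)
            stop("plan missing required negative control for ", iso)
    }
    design <- makeDesign(params)
    truth <- plantTruth(params, plan$conditions, plan$sizes, plan$overlapSpec)
    frac <- plan$shared50xFraction %||% 0.5
    shared <- list()
    set.seed(.subseed(params@seed, "shared50x", 0L))
    for (lbl in plan$conditions) {
        if (lbl@e1e2Level != "x1" || lbl@e3 == "none") next
        fifty <- truth@truth[[paste0("50X-", lbl@sumoIsoform)]]
        k <- as.integer(floor(frac * length(fifty)))
        shared[[conditionName(lbl)]] <-
            if (k > 0) sort(sample(fifty, k)) else character(0)
    }
    truth <- new("SimTruth", conditions = truth@conditions,
                 truth = truth@truth, shared50x = shared,
                 crossReactive = truth@crossReactive, params = params)
    scans <- list()
    for (lbl in plan$conditions)
        for (r in seq_len(nReplicates))
            scans[[length(scans) + 1L]] <-
                simulateScan(design, truth, lbl, r, params)
    list(design = design, scans = scans, truth = truth)
}

#' Score recovery of planted substrate sets
#'
#' Compares called substrate sets against the planted truth per condition.
#' Precision is 1 by convention when nothing was called; recall is 1 when
#' the truth set is empty.
#'
#' @param called named list (by condition name) of character vectors or
#'   [HitTable-class] objects.
#' @param truth a [SimTruth-class].
#' @return List with `conditions` (a `data.frame` of tp/fp/fn, precision,
#'   recall, f1 per condition) and `macro` (macro-averaged precision, recall,
#'   f1).
#' @export
evaluateRecovery <- function(called, truth) {
    stopifnot(is(truth, "SimTruth"), is.list(called),
              !is.null(names(called)))
    rows <- lapply(names(called), function(cn) {
        if (!cn %in% names(truth@truth))
            stop("condition absent from truth: ", cn)
        got <- called[[cn]]
        if (is(got, "HitTable")) got <- substrates(got)
        got <- unique(got)
        want <- truth@truth[[cn]]
        tp <- length(intersect(got, want))
        fp <- length(setdiff(got, want))
        fn <- length(setdiff(want, got))
        precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
        recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
        f1 <- if (precision + recall == 0) 0 else
            2 * precision * recall / (precision + recall)
        data.frame(condition = cn, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    list(conditions = df,
         macro = list(precision = mean(df$precision),
                      recall = mean(df$recall), f1 = mean(df$f1)))
}
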