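test_that("computeRatios divides F by B with floor and exclusion rules", {
    d <- toy_design(nProteins = 3, nBlocks = 1, blockRows = 3, blockCols = 3,
                    controls = 2)
    s <- scan_from_ratios(d, rep(1, 8))
    s@measurements$foreground <- c(500, 450, 0, 120, 100, 100, 100, 100)
    s@measurements$background <- c(100, 100, 100, 100, 100, 0, 100, 100)
    s@measurements$flag[4] <- "bad"
    rm <- computeRatios(s, d, floor = 0.1)
    r <- ratioTable(rm)
    expect_false(isNormalized(rm))
    expect_equal(r$ratio[1], 5.0)
    # F=0: ratio floored at the floor value, spot retained
    expect_equal(r$ratio[3], 0.1)
    expect_true(all(r$ratio > 0))
    # zero background floored to 0.1 * median background
    expect_equal(r$ratio[6], 100 / (0.1 * 100))
    # flagged and control spots excluded from statistics
    expect_false(r$included[4])
    expect_false(any(r$included[7:8]))
    expect_equal(attr(rm, "n_floored"), 1L)

    s@measurements$background <- rep(0, 8)
    expect_error(computeRatios(s, d), "degenerate scan")
})

test_that("block-median normalization forces every block median to one", {
    d <- toy_design(nProteins = 3, nBlocks = 1, blockRows = 3, blockCols = 2)
    rm <- computeRatios(scan_from_ratios(d, c(1, 2, 3, 4, 5, 6)), d)
    rm@ratios$ratio <- c(1, 2, 3, 4, 5, 6)

    nb <- normalizeBlocks(rm, d)
    expect_true(isNormalized(nb))
    expect_equal(ratioTable(nb)$ratio[1:3] * 3.5, c(1, 2, 3))

    # {1,2,3} alone -> {0.5, 1, 1.5}; all-equal block -> all ones
    d1 <- toy_design(nProteins = 3, nBlocks = 2, blockRows = 1, blockCols = 3)
    rm1 <- computeRatios(scan_from_ratios(d1, c(1, 2, 3, 7, 7, 7)), d1)
    nb1 <- normalizeBlocks(rm1, d1)
    expect_equal(ratioTable(nb1)$ratio, c(0.5, 1, 1.5, 1, 1, 1))

    # idempotence and random-input block medians (spec invariant)
    set.seed(42)
    for (i in 1:20) {
        dd <- toy_design(nProteins = 12, nBlocks = 3, blockRows = 4,
                         blockCols = 2)
        rr <- computeRatios(scan_from_ratios(dd, rlnorm(24, 0, 0.5)), dd)
        n1 <- normalizeBlocks(rr, dd)
        tab <- ratioTable(n1)
        med <- tapply(tab$ratio[tab$included], tab$block[tab$included], median)
        expect_true(all(abs(med - 1) < 1e-9))
        n2 <- normalizeBlocks(n1, dd)
        expect_equal(ratioTable(n2)$ratio, tab$ratio, tolerance = 1e-12)
    }

    # block with no included spots is an error naming the block
    d2 <- toy_design(nProteins = 2, nBlocks = 2, blockRows = 1, blockCols = 2)
    s2 <- scan_from_ratios(d2, rep(1, 4), flags = c("ok", "ok", "bad", "bad"))
    expect_error(normalizeBlocks(computeRatios(s2, d2), d2), "block 2")
})

test_that("duplicate-spot calling requires both spots above mean + k*SD", {
    # all ratios identical: SD is zero, nothing strictly exceeds the mean
    d <- toy_design(nProteins = 4, nBlocks = 1, blockRows = 2, blockCols = 4)
    rm <- normalizeBlocks(computeRatios(scan_from_ratios(d, rep(2, 8)), d), d)
    expect_length(callSingleArray(rm, d), 0L)

    # 100 background pairs at ~1 plus one planted pair at 50
    d2 <- toy_design(nProteins = 101, nBlocks = 1, blockRows = 202,
                     blockCols = 1)
    set.seed(9)
    vals <- rlnorm(202, 0, 0.05)
    vals[201:202] <- 50
    rm2 <- normalizeBlocks(computeRatios(scan_from_ratios(d2, vals), d2), d2)
    tab <- ratioTable(rm2)
    thr <- mean(tab$ratio) + 5 * sd(tab$ratio)   # direct recomputation
    expect_true(all(tab$ratio[201:202] > thr))
    expect_equal(as.character(callSingleArray(rm2, d2)), "G101")

    # both-spot requirement: (50, just-above-1) pair is not called
    vals[202] <- 1.01
    rm3 <- normalizeBlocks(computeRatios(scan_from_ratios(d2, vals), d2), d2)
    expect_length(callSingleArray(rm3, d2), 0L)
})

test_that("consensus counts replicate support like brute-force counting", {
    expect_equal(consensusHits(list(c("A", "B"), "A", c("A", "C")))$substrate,
                 "A")
    cc <- consensusHits(list(c("A", "B"), c("A", "B"), character(0)))
    expect_equal(cc$substrate, c("A", "B"))
    expect_equal(cc$replicate_support, c(2L, 2L))
    expect_error(consensusHits(list("A"), minSupport = 2), "exceeds")

    set.seed(11)
    universe <- LETTERS
    for (i in 1:30) {
        sets <- lapply(1:3, function(j) sample(universe, rpois(1, 6)))
        for (ms in 1:3) {
            got <- consensusHits(sets, ms)$substrate
            want <- sort(Filter(function(s)
                sum(vapply(sets, function(x) s %in% x, logical(1))) >= ms,
                universe))
            expect_equal(got, want)
        }
    }
})

test_that("negative-control and 50x subtraction are logged set differences", {
    expect_equal(subtractNegative(c("A", "B", "C"), "B"), c("A", "C"))
    expect_equal(subtractNegative(c("A", "C"), c("X", "Y")), c("A", "C"))
    expect_equal(e3Dependent(c("A", "B", "C"), "B"), c("A", "C"))
    expect_length(e3Dependent(c("A", "B"), c("A", "B", "C")), 0L)
})

test_that("runCondition composes the pipeline and is replicate-order invariant", {
    p <- simParams(nProteins = 200L, nBlocks = 4L, blockRows = 10L,
                   blockCols = 11L, seed = 21L)
    d <- makeDesign(p)
    cond <- conditionLabel("x1", "RANBP2", "SUMO2")
    truth <- plantTruth(p, list(cond), c("RANBP2-SUMO2" = 10))
    scans <- lapply(1:3, function(r) simulateScan(d, truth, cond, r, p))
    params <- hitcallParams(estimator = "median_mad")

    ht <- runCondition(scans, d, params = params)
    expect_s4_class(ht, "HitTable")
    expect_gt(nrow(hitEvidence(ht)), 0)
    expect_true(all(hitEvidence(ht)$replicate_support >= 2))

    ht_perm <- runCondition(scans[c(3, 1, 2)], d, params = params)
    expect_equal(hitEvidence(ht_perm), hitEvidence(ht))

    expect_error(runCondition(scans[1], d, params = params),
                 "insufficient replication")

    # three identical null arrays yield an empty table
    dn <- toy_design(nProteins = 10, nBlocks = 1, blockRows = 5, blockCols = 4)
    null_scans <- lapply(1:3, function(r)
        scan_from_ratios(dn, rep(1, 20), replicate = r))
    expect_equal(nrow(hitEvidence(runCondition(null_scans, dn))), 0L)
})

test_that("hit sets are invariant to per-block rescaling", {
    p <- simParams(nProteins = 150L, nBlocks = 3L, blockRows = 10L,
                   blockCols = 10L, seed = 31L)
    d <- makeDesign(p)
    cond <- conditionLabel("x1", "PIAS1", "SUMO1")
    truth <- plantTruth(p, list(cond), c("PIAS1-SUMO1" = 8))
    s <- simulateScan(d, truth, cond, 1L, p)
    base <- callSingleArray(normalizeBlocks(computeRatios(s, d), d), d,
                            estimator = "median_mad")

    # scale every intensity of block 2 (foreground and background)
    s2 <- s
    sel <- s2@measurements$block == 2
    s2@measurements$foreground[sel] <- s2@measurements$foreground[sel] * 7.5
    s2@measurements$background[sel] <- s2@measurements$background[sel] * 7.5
    got2 <- callSingleArray(normalizeBlocks(computeRatios(s2, d), d), d,
                            estimator = "median_mad")
    expect_equal(got2, base, ignore_attr = TRUE)

    # scale only the foregrounds of block 3 (a pure block effect)
    s3 <- s
    sel <- s3@measurements$block == 3
    s3@measurements$foreground[sel] <- s3@measurements$foreground[sel] * 0.2
    got3 <- callSingleArray(normalizeBlocks(computeRatios(s3, d), d), d,
                            estimator = "median_mad")
    expect_equal(got3, base, ignore_attr = TRUE)
})

test_that("hit sets shrink monotonically in k_sd and min_support", {
    set.seed(51)
    for (i in 1:10) {
        p <- simParams(nProteins = 120L, nBlocks = 2L, blockRows = 11L,
                       blockCols = 11L, seed = 100L + i)
        d <- makeDesign(p)
        cond <- conditionLabel("x1", "TOPORS", "SUMO1")
        truth <- plantTruth(p, list(cond), c("TOPORS-SUMO1" = 6))
        rms <- lapply(1:3, function(r)
            normalizeBlocks(computeRatios(
                simulateScan(d, truth, cond, r, p), d), d))
        sets5 <- lapply(rms, callSingleArray, design = d, kSd = 5)
        sets6 <- lapply(rms, callSingleArray, design = d, kSd = 6)
        for (j in 1:3)
            expect_true(all(sets6[[j]] %in% sets5[[j]]))
        c1 <- consensusHits(sets5, 1)$substrate
        c2 <- consensusHits(sets5, 2)$substrate
        c3 <- consensusHits(sets5, 3)$substrate
        expect_true(all(c3 %in% c2) && all(c2 %in% c1))
    }
})

test_that("the modular pipeline matches the brute-force oracle", {
    set.seed(61)
    for (i in 1:25) {
        n_prot <- sample(20:60, 1)
        p <- simParams(nProteins = n_prot, nBlocks = sample(1:3, 1),
                       blockRows = 10L, blockCols = 15L,
                       seed = 200L + i)
        d <- makeDesign(p)
        sp <- designSpots(d)
        est <- sample(c("mean_sd", "median_mad"), 1)
        reps <- lapply(1:3, function(r) {
            fg <- rlnorm(nrow(sp), 5, 1)
            bg <- rlnorm(nrow(sp), 4, 0.3)
            flag <- sample(c("ok", "bad"), nrow(sp), replace = TRUE,
                           prob = c(0.97, 0.03))
            list(fg = fg, bg = bg, flag = flag)
        })
        scans <- lapply(1:3, function(r)
            new("ArrayScan", condition = conditionLabel("x1", "PIAS3", "SUMO2"),
                replicate = r,
                measurements = data.frame(block = sp$block, row = sp$row,
                                          col = sp$col,
                                          foreground = reps[[r]]$fg,
                                          background = reps[[r]]$bg,
                                          flag = reps[[r]]$flag,
                                          stringsAsFactors = FALSE)))
        neg <- sample(sp$gene_symbol, 3)
        fifty <- sample(sp$gene_symbol, 3)
        ht <- runCondition(scans, d, negativeTable = neg, table50x = fifty,
                           params = hitcallParams(kSd = 2, estimator = est))
        want <- oracle_pipeline(sp, reps, neg = neg, fifty = fifty, k = 2,
                                estimator = est)
        expect_equal(substrates(ht), want)
    }
})
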