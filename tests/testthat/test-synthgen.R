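test_that("design generation is deterministic and respects capacity", {
    p <- simParams(nProteins = 4L, nBlocks = 1L, blockRows = 4L,
                   blockCols = 4L, seed = 2L)
    d <- makeDesign(p)
    sp <- designSpots(d)
    expect_equal(sum(sp$role == "substrate"), 8L)
    expect_equal(sum(sp$role != "substrate"), 8L)
    expect_setequal(unique(sp$role[sp$role != "substrate"]),
                    c("negative_control", "positive_control", "landmark"))
    expect_identical(designSpots(makeDesign(p)), sp)

    expect_error(simParams(nProteins = 10L, nBlocks = 1L, blockRows = 4L,
                           blockCols = 4L), "capacity")
})

test_that("planted truth honors sizes and pairwise overlaps exactly", {
    p <- simParams(nProteins = 100L, nBlocks = 2L, blockRows = 10L,
                   blockCols = 10L, seed = 8L, crossreactiveFraction = 0.05)
    conds <- list(conditionLabel("x1", "PIAS1", "SUMO1"),
                  conditionLabel("x1", "PIAS2", "SUMO1"),
                  conditionLabel("x1", "none", "SUMO1"))
    spec <- data.frame(a = "PIAS1-SUMO1", b = "PIAS2-SUMO1", shared = 4)
    tr <- plantTruth(p, conds, c("PIAS1-SUMO1" = 10, "PIAS2-SUMO1" = 10),
                     overlapSpec = spec)
    sets <- truthSets(tr)
    expect_length(sets[["PIAS1-SUMO1"]], 10L)
    expect_length(sets[["PIAS2-SUMO1"]], 10L)
    expect_length(intersect(sets[["PIAS1-SUMO1"]], sets[["PIAS2-SUMO1"]]), 4L)
    expect_equal(sets[["NEG-SUMO1"]], crossReactive(tr))
    expect_length(crossReactive(tr), 5L)
    # planted sets avoid the cross-reactive proteins
    expect_length(intersect(sets[["PIAS1-SUMO1"]], crossReactive(tr)), 0L)

    # realized Jaccard equals the requested value
    expect_equal(sharedFraction(sets[["PIAS1-SUMO1"]], sets[["PIAS2-SUMO1"]]),
                 100 * 4 / 16)

    expect_error(plantTruth(p, conds, c("PIAS1-SUMO1" = 3, "PIAS2-SUMO1" = 3),
                            overlapSpec = data.frame(a = "PIAS1-SUMO1",
                                                     b = "PIAS2-SUMO1",
                                                     shared = 5)),
                 "infeasible")
})

test_that("simulated scans are deterministic and reach the noise-free limit", {
    p <- simParams(nProteins = 40L, nBlocks = 2L, blockRows = 7L,
                   blockCols = 7L, seed = 14L, nullRatioSd = 0,
                   hitRatioSd = 0, blockEffectSd = 0, replicateDropout = 0,
                   crossreactiveFraction = 0)
    d <- makeDesign(p)
    cond <- conditionLabel("x1", "PIAS4", "SUMO2")
    tr <- plantTruth(p, list(cond), c("PIAS4-SUMO2" = 5))
    s1 <- simulateScan(d, tr, cond, 1L, p)
    s2 <- simulateScan(d, tr, cond, 1L, p)
    expect_identical(scanMeasurements(s1), scanMeasurements(s2))
    s3 <- simulateScan(d, tr, cond, 2L, p)
    expect_false(identical(scanMeasurements(s1), scanMeasurements(s3)))

    # noise-free limit: both spots of every true substrate at exactly the
    # planted effect, every other substrate spot at exactly 1
    m <- scanMeasurements(s1)
    sp <- designSpots(d)
    ratio <- m$foreground / m$background
    hot <- sp$role == "substrate" &
        sp$gene_symbol %in% truthSets(tr)[["PIAS4-SUMO2"]]
    expect_equal(ratio[hot], rep(20, sum(hot)), tolerance = 1e-12)
    null_sub <- sp$role == "substrate" & !hot
    expect_equal(ratio[null_sub], rep(1, sum(null_sub)), tolerance = 1e-12)
})

test_that("non-substrate log-ratios center on zero at large n", {
    p <- simParams(seed = 19L)
    d <- makeDesign(p)
    cond <- conditionLabel("x1", "PIAS1", "SUMO1")
    tr <- plantTruth(p, list(cond), c("PIAS1-SUMO1" = 10))
    m <- scanMeasurements(simulateScan(d, tr, cond, 1L, p))
    sp <- designSpots(d)
    # block factors affect foregrounds; remove them per block before testing
    lr <- log(m$foreground / m$background)
    for (b in unique(sp$block))
        lr[sp$block == b] <- lr[sp$block == b] -
            median(lr[sp$block == b & sp$role == "substrate"])
    null_sub <- sp$role == "substrate" &
        !sp$gene_symbol %in% c(truthSets(tr)[["PIAS1-SUMO1"]],
                               crossReactive(tr))
    se <- sd(lr[null_sub]) / sqrt(sum(null_sub))
    expect_lt(abs(mean(lr[null_sub])), 3.5 * se + 0.01)
})

test_that("a full study produces 48 round-trippable scans with usable truth", {
    p <- simParams(nProteins = 300L, nBlocks = 4L, blockRows = 13L,
                   blockCols = 13L, seed = 23L)
    st <- simulateStudy(p, defaultStudyPlan(p, e3Size = 10L,
                                            size50x = c(30L, 25L)))
    expect_length(st$scans, 16L * 3L)
    cn <- vapply(st$scans, function(s) conditionName(scanCondition(s)),
                 character(1))
    expect_equal(sort(unique(cn)), sort(names(truthSets(st$truth))))

    # E3-dependent truth is disjoint from the matched 50x set by construction
    tr <- truthSets(st$truth)
    expect_length(intersect(tr[["PIAS1-SUMO1"]], tr[["50X-SUMO1"]]), 0L)

    # scans round-trip through the array IO layer
    tmp <- withr::local_tempfile(fileext = ".tsv")
    s <- st$scans[[7]]
    writeScan(s, st$design, tmp)
    s2 <- readScan(tmp, st$design, dialect = "tsv")
    expect_equal(scanMeasurements(s2)$foreground,
                 scanMeasurements(s)$foreground, tolerance = 1e-12)

    # a plan without the required controls is rejected
    bad_plan <- defaultStudyPlan(p, e3Size = 5L, size50x = c(10L, 10L))
    keep <- vapply(bad_plan$conditions,
                   function(l) conditionName(l) != "50X-SUMO1", logical(1))
    bad_plan$conditions <- bad_plan$conditions[keep]
    expect_error(simulateStudy(p, bad_plan), "missing required 50x")
})

test_that("recovery scoring matches a confusion-matrix oracle", {
    p <- simParams(nProteins = 60L, nBlocks = 1L, blockRows = 12L,
                   blockCols = 10L, seed = 29L)
    cond <- conditionLabel("x1", "TOPORS", "SUMO2")
    tr <- plantTruth(p, list(cond), c("TOPORS-SUMO2" = 8))
    want <- truthSets(tr)[["TOPORS-SUMO2"]]

    perfect <- evaluateRecovery(list("TOPORS-SUMO2" = want), tr)
    expect_equal(perfect$macro$precision, 1)
    expect_equal(perfect$macro$recall, 1)

    empty <- evaluateRecovery(list("TOPORS-SUMO2" = character(0)), tr)
    expect_equal(empty$macro$precision, 1)   # convention: no calls
    expect_equal(empty$macro$recall, 0)

    expect_error(evaluateRecovery(list("PIAS1-SUMO1" = "X"), tr), "absent")

    set.seed(101)
    pool <- sprintf("SG%05d", 1:60)
    for (i in 1:20) {
        called <- sample(pool, sample(0:15, 1))
        ev <- evaluateRecovery(list("TOPORS-SUMO2" = called), tr)$conditions
        tp <- sum(called %in% want)
        expect_equal(ev$tp, tp)
        expect_equal(ev$fp, length(called) - tp)
        expect_equal(ev$fn, length(want) - tp)
        if (length(called))
            expect_equal(ev$precision, tp / length(called))
        expect_equal(ev$recall, tp / length(want))
    }
})

test_that("recovery is monotone in effect size and removes cross-reactives", {
    recalls <- vapply(c(2, 10, 50), function(eff) {
        p <- simParams(nProteins = 300L, nBlocks = 4L, blockRows = 13L,
                       blockCols = 13L, seed = 37L, hitRatioMean = eff)
        st <- simulateStudy(p, defaultStudyPlan(p, e3Size = 10L,
                                                size50x = c(30L, 25L)))
        tabs <- runStudy(st$scans, st$design,
                         hitcallParams(estimator = "median_mad"))
        evaluateRecovery(lapply(tabs, substrates), st$truth)$macro$recall
    }, numeric(1))
    expect_true(recalls[1] <= recalls[2] && recalls[2] <= recalls[3])

    # no cross-reactive protein survives into any final E3-dependent set
    p <- simParams(nProteins = 300L, nBlocks = 4L, blockRows = 13L,
                   blockCols = 13L, seed = 43L, crossreactiveFraction = 0.05)
    st <- simulateStudy(p, defaultStudyPlan(p, e3Size = 10L,
                                            size50x = c(30L, 25L)))
    tabs <- runStudy(st$scans, st$design,
                     hitcallParams(estimator = "median_mad"))
    for (cn in names(tabs)) {
        lbl <- scanCondition(tabs[[cn]])
        if (lbl@e1e2Level == "x1" && lbl@e3 != "none")
            expect_length(intersect(substrates(tabs[[cn]]),
                                    crossReactive(st$truth)), 0L)
    }
})
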