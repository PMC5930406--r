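#' @include AllClasses.R conditions.R
NULL

#' Spot table of an array design
#' @param x an [ArrayDesign-class].
#' @return The spot `data.frame`.
#' @export
designSpots <- function(x) { stopifnot(is(x, "ArrayDesign")); x@spots }

#' Substrate (non-control) spots of a design
#' @param x an [ArrayDesign-class].
#' @return Subset of the spot table with `role == "substrate"`.
#' @export
substrateSpots <- function(x) {
    sp <- designSpots(x)
    sp[sp$role == "substrate", , drop = FALSE]
}

#' Number of print blocks
#' @param x an [ArrayDesign-class].
#' @return Integer.
#' @export
nBlocks <- function(x) { stopifnot(is(x, "ArrayDesign")); x@nBlocks }

#' Measurement table of a scan
#' @param x an [ArrayScan-class].
#' @return The measurement `data.frame`.
#' @export
scanMeasurements <- function(x) { stopifnot(is(x, "ArrayScan")); x@measurements }

#' Condition of a scan, ratio matrix or hit table
#' @param x an [ArrayScan-class], [RatioMatrix-class] or [HitTable-class].
#' @return A [ConditionLabel-class].
#' @export
scanCondition <- function(x) {
    stopifnot(is(x, "ArrayScan") || is(x, "RatioMatrix") || is(x, "HitTable"))
    x@condition
}

#' Ratio table of a RatioMatrix
#' @param x a [RatioMatrix-class].
#' @return The ratio `data.frame`.
#' @export
ratioTable <- function(x) { stopifnot(is(x, "RatioMatrix")); x@ratios }

#' Has block normalization been applied?
#' @param x a [RatioMatrix-class].
#' @return Logical.
#' @export
isNormalized <- function(x) { stopifnot(is(x, "RatioMatrix")); x@normalized }

#' Hit evidence table of a HitTable
#' @param x a [HitTable-class].
#' @return The hit `data.frame`.
#' @export
hitEvidence <- function(x) { stopifnot(is(x, "HitTable")); x@hits }

#' Called substrate symbols of a HitTable
#' @param x a [HitTable-class].
#' @return Character vector, sorted.
#' @export
substrates <- function(x) { stopifnot(is(x, "HitTable")); sort(x@hits$substrate) }

#' Condition node names of a network
#' @param x a [SubstrateNetwork-class].
#' @return Character vector.
#' @export
conditionNodes <- function(x) { stopifnot(is(x, "SubstrateNetwork")); x@conditions }

#' Substrate node names of a network
#' @param x a [SubstrateNetwork-class].
#' @return Character vector, sorted.
#' @export
substrateNodes <- function(x) {
    stopifnot(is(x, "SubstrateNetwork"))
    sort(unique(x@edges$substrate))
}

#' Edge list of a network
#' @param x a [SubstrateNetwork-class].
#' @return `data.frame` with columns `condition`, `substrate`, `e3_dependent`.
#' @export
networkEdges <- function(x) { stopifnot(is(x, "SubstrateNetwork")); x@edges }

#' Per-substrate degree (number of incident conditions)
#' @param x a [SubstrateNetwork-class].
#' @return Named integer vector over substrate nodes.
#' @export
substrateDegree <- function(x) {
    stopifnot(is(x, "SubstrateNetwork"))
    e <- x@edges
    if (!nrow(e)) return(integer(0))
    tab <- table(e$substrate)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(names(out))]
}

#' Planted truth sets of a simulation
#' @param x a [SimTruth-class].
#' @return Named list of character vectors, one per condition.
#' @export
truthSets <- function(x) { stopifnot(is(x, "SimTruth")); x@truth }

#' Cross-reactive proteins of a simulation
#' @param x a [SimTruth-class].
#' @return Character vector.
#' @export
crossReactive <- function(x) { stopifnot(is(x, "SimTruth")); x@crossReactive }

setMethod("show", "ArrayDesign", function(object) {
    sp <- object@spots
    cat("ArrayDesign:", object@nBlocks, "blocks of", object@blockRows, "x",
        object@blockCols, "\n  ", nrow(sp), "spots (",
        sum(sp$role == "substrate"), "substrate,",
        sum(sp$role != "substrate"), "control ),",
        length(unique(sp$protein_id[sp$role == "substrate"])),
        "proteins in duplicate\n")
})

setMethod("show", "ArrayScan", function(object) {
    cat("ArrayScan:", conditionName(object@condition), "replicate",
        object@replicate, "-", nrow(object@measurements), "spots (",
        sum(object@measurements$flag != "ok"), "flagged )\n")
})

setMethod("show", "RatioMatrix", function(object) {
    cat("RatioMatrix:", conditionName(object@condition), "replicate",
        object@replicate, "-", nrow(object@ratios), "spots,",
        sum(object@ratios$included), "included;",
        if (object@normalized) "block-normalized" else "raw", "\n")
})

setMethod("show", "HitTable", function(object) {
    cat("HitTable:", conditionName(object@condition), "-",
        nrow(object@hits), "substrates\n")
    if (nrow(object@hits))
        print(utils::head(object@hits[order(object@hits$substrate), ], 5L),
              row.names = FALSE)
})

setMethod("show", "SubstrateNetwork", function(object) {
    cat("SubstrateNetwork:", length(object@conditions), "condition nodes,",
        length(unique(object@edges$substrate)), "substrate nodes,",
        nrow(object@edges), "edges\n")
})

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nProteins, "proteins,", object@nBlocks,
        "blocks of", object@blockRows, "x", object@blockCols,
        "\n  hit effect", object@hitRatioMean, "(sdlog", object@hitRatioSd,
        "), null sdlog", object@nullRatioSd, ", block sdlog",
        object@blockEffectSd, "\n  dropout", object@replicateDropout,
        ", cross-reactive", object@crossreactiveFraction, ", seed",
        object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    sizes <- vapply(object@truth, length, integer(1))
    cat("SimTruth:", length(object@conditions), "conditions;",
        length(object@crossReactive), "cross-reactive proteins\n")
    print(sizes)
})
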