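#' @import methods
NULL

## controlled vocabularies used across the package
.E1E2_LEVELS <- c("x1", "x50")
.E3_LEVELS <- c("none", "PIAS1", "PIAS2", "PIAS3", "PIAS4", "RANBP2", "TOPORS")
.ISO_LEVELS <- c("SUMO1", "SUMO2")
.ROLE_LEVELS <- c("substrate", "negative_control", "positive_control", "landmark")
.FLAG_LEVELS <- c("ok", "saturated", "bad")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Label for one SUMOylation reaction condition
#'
#' A condition is the combination of the E1/E2 enzyme level (limiting `x1` or
#' saturating `x50`), the spiked E3 ligase (`none` for enzyme-only reactions)
#' and the SUMO isoform. `x50` reactions are E3-free by design, and the
#' `(x1, none, isoform)` combination is the negative control.
#'
#' @slot e1e2Level `"x1"` or `"x50"`.
#' @slot e3 one of `none`, `PIAS1`..`PIAS4`, `RANBP2`, `TOPORS`.
#' @slot sumoIsoform `"SUMO1"` or `"SUMO2"`.
#' @export
setClass("ConditionLabel",
    representation(e1e2Level = "character", e3 = "character",
                   sumoIsoform = "character"))

setValidity("ConditionLabel", function(object) {
    msg <- character()
    if (length(object@e1e2Level) != 1L || !object@e1e2Level %in% .E1E2_LEVELS)
        msg <- c(msg, "e1e2Level must be one of 'x1', 'x50'")
    if (length(object@e3) != 1L || !object@e3 %in% .E3_LEVELS)
        msg <- c(msg, paste0("e3 must be one of: ",
                             paste(.E3_LEVELS, collapse = ", ")))
    if (length(object@sumoIsoform) != 1L || !object@sumoIsoform %in% .ISO_LEVELS)
        msg <- c(msg, "sumoIsoform must be 'SUMO1' or 'SUMO2'")
    if (length(msg) == 0L && object@e1e2Level == "x50" && object@e3 != "none")
        msg <- c(msg, "x50 reactions are E3-free controls (e3 must be 'none')")
    if (length(msg)) msg else TRUE
})

#' Array design: grid geometry and spot-to-protein map
#'
#' Describes the printed layout of a protein microarray: the block grid and,
#' per spot, the printed protein, its gene symbol, its role (substrate or one
#' of the control classes) and the duplicate-pair grouping. Proteins are
#' printed in duplicate; `dup_group` ties the two spots of a pair together
#' explicitly so no adjacency assumption is needed.
#'
#' @slot nBlocks number of print blocks (one per pin pass).
#' @slot blockRows,blockCols within-block grid dimensions.
#' @slot spots `data.frame` with columns `block`, `row`, `col`, `protein_id`,
#'   `gene_symbol`, `role`, `dup_group` (`NA` for control spots).
#' @export
setClass("ArrayDesign",
    representation(nBlocks = "integer", blockRows = "integer",
                   blockCols = "integer", spots = "data.frame"))

setValidity("ArrayDesign", function(object) {
    sp <- object@spots
    need <- c("block", "row", "col", "protein_id", "gene_symbol", "role",
              "dup_group")
    if (!all(need %in% names(sp)))
        return(paste("spots must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    key <- paste(sp$block, sp$row, sp$col)
    if (anyDuplicated(key))
        msg <- c(msg, paste0("duplicate spot address: ",
                             key[duplicated(key)][1L]))
    if (any(sp$block < 1L | sp$block > object@nBlocks) ||
        any(sp$row < 1L | sp$row > object@blockRows) ||
        any(sp$col < 1L | sp$col > object@blockCols))
        msg <- c(msg, "spot address outside the block grid")
    if (!all(sp$role %in% .ROLE_LEVELS))
        msg <- c(msg, "invalid spot role")
    if (any(!nzchar(sp$protein_id)))
        msg <- c(msg, "empty protein_id")
    sub <- sp[sp$role == "substrate", , drop = FALSE]
    if (nrow(sub)) {
        if (any(is.na(sub$dup_group)))
            msg <- c(msg, "substrate spot without a dup_group")
        else {
            sizes <- table(sub$dup_group)
            if (any(sizes != 2L))
                msg <- c(msg, paste0("dup_group not a pair (unpaired substrate spot): ",
                                     names(sizes)[sizes != 2L][1L]))
            nprot <- vapply(split(sub$protein_id, sub$dup_group),
                            function(p) length(unique(p)), integer(1))
            if (any(nprot != 1L))
                msg <- c(msg, "dup_group spans more than one protein")
        }
    }
    if (length(msg)) msg else TRUE
})

#' One scanned array: per-spot measurements plus condition metadata
#'
#' @slot condition a [ConditionLabel-class].
#' @slot replicate replicate index (1-based).
#' @slot measurements `data.frame` with columns `block`, `row`, `col`,
#'   `foreground`, `background`, `flag` (`ok`, `saturated` or `bad`).
#' @export
setClass("ArrayScan",
    representation(condition = "ConditionLabel", replicate = "integer",
                   measurements = "data.frame"))

setValidity("ArrayScan", function(object) {
    m <- object@measurements
    need <- c("block", "row", "col", "foreground", "background", "flag")
    if (!all(need %in% names(m)))
        return(paste("measurements must have columns:",
                     paste(need, collapse = ", ")))
    msg <- character()
    if (length(object@replicate) != 1L || is.na(object@replicate) ||
        object@replicate < 1L)
        msg <- c(msg, "replicate index must be a positive integer")
    if (anyDuplicated(paste(m$block, m$row, m$col)))
        msg <- c(msg, "duplicate spot address in scan")
    if (!all(is.finite(m$foreground)) || !all(is.finite(m$background)) ||
        any(m$foreground < 0) || any(m$background < 0))
        msg <- c(msg, "intensities must be finite and non-negative")
    if (!all(m$flag %in% .FLAG_LEVELS))
        msg <- c(msg, "flags must be ok/saturated/bad")
    if (length(msg)) msg else TRUE
})

#' Per-spot foreground/background ratios for one array
#'
#' Produced by [computeRatios()]; `included` marks the substrate spots that
#' enter hit statistics (controls and flagged spots are excluded). After
#' [normalizeBlocks()] the median ratio of every block over included spots
#' is 1.
#'
#' @slot ratios `data.frame` with columns `block`, `row`, `col`, `protein_id`,
#'   `gene_symbol`, `dup_group`, `ratio`, `included`.
#' @slot normalized logical: has block-median normalization been applied?
#' @slot condition,replicate provenance from the scan.
#' @export
setClass("RatioMatrix",
    representation(ratios = "data.frame", normalized = "logical",
                   condition = "ConditionLabel", replicate = "integer"))

setValidity("RatioMatrix", function(object) {
    r <- object@ratios
    need <- c("block", "row", "col", "protein_id", "gene_symbol", "dup_group",
              "ratio", "included")
    if (!all(need %in% names(r)))
        return(paste("ratios must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (!all(is.finite(r$ratio)) || any(r$ratio <= 0))
        msg <- c(msg, "ratios must be finite and > 0 (floor rule)")
    if (isTRUE(object@normalized) && nrow(r)) {
        med <- vapply(split(r$ratio[r$included], r$block[r$included]),
                      stats::median, numeric(1))
        if (any(abs(med - 1) > 1e-9))
            msg <- c(msg, "normalized block medians must equal 1")
    }
    if (length(msg)) msg else TRUE
})

#' Called substrates for one condition, with filter provenance
#'
#' @slot condition a [ConditionLabel-class].
#' @slot hits `data.frame` with columns `substrate` (official gene symbol),
#'   `replicate_support` (replicates calling it), `mean_ratio` (mean
#'   normalized pair ratio over supporting replicates),
#'   `passed_negative_filter`, `e3_dependent`, `filters_passed`
#'   (comma-separated filter tags).
#' @export
setClass("HitTable",
    representation(condition = "ConditionLabel", hits = "data.frame"))

setValidity("HitTable", function(object) {
    h <- object@hits
    need <- c("substrate", "replicate_support", "mean_ratio",
              "passed_negative_filter", "e3_dependent", "filters_passed")
    if (!all(need %in% names(h)))
        return(paste("hits must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(h$substrate))
        return("duplicate substrate in hit table")
    TRUE
})

#' Bipartite condition-to-substrate network
#'
#' Condition nodes are named `"<E3>-<ISOFORM>"`, `"50X-<ISOFORM>"` or
#' `"NEG-<ISOFORM>"`; substrate nodes are gene symbols; an edge means the
#' substrate was called in that condition.
#'
#' @slot conditions character vector of condition node names.
#' @slot edges `data.frame` with columns `condition`, `substrate`,
#'   `e3_dependent`.
#' @export
setClass("SubstrateNetwork",
    representation(conditions = "character", edges = "data.frame"))

setValidity("SubstrateNetwork", function(object) {
    e <- object@edges
    if (!all(c("condition", "substrate", "e3_dependent") %in% names(e)))
        return("edges must have columns condition, substrate, e3_dependent")
    msg <- character()
    if (anyDuplicated(object@conditions))
        msg <- c(msg, "duplicate condition node")
    if (nrow(e) && !all(e$condition %in% object@conditions))
        msg <- c(msg, "edge references unknown condition node")
    if (anyDuplicated(paste(e$condition, e$substrate)))
        msg <- c(msg, "duplicate edge")
    if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic-array generator
#'
#' Defaults describe a desk-scale emulation of a HuProt-like screen: 2000
#' proteins printed in duplicate across 16 blocks of 17 x 16 spots, log-normal
#' backgrounds (meanlog 7, sdlog 0.5 on the natural-log scale of arbitrary
#' fluorescence units), null F/B ratios dispersed around 1 (sdlog 0.15), a
#' 20-fold multiplicative effect for true substrates (sdlog 0.2), per-block
#' multiplicative factors (sdlog 0.3), a 10% per-replicate dropout of
#' enzyme-limited true signals, and 2% cross-reactive proteins that light up
#' on every array including the negative controls.
#'
#' @slot nProteins,nBlocks,blockRows,blockCols layout counts.
#' @slot backgroundMeanlog,backgroundSdlog log-normal background parameters.
#' @slot nullRatioSd log-scale dispersion of non-substrate F/B ratios.
#' @slot hitRatioMean multiplicative F/B effect for true substrates (> 1).
#' @slot hitRatioSd log-scale dispersion of the substrate effect.
#' @slot blockEffectSd log-scale dispersion of per-block factors.
#' @slot replicateDropout probability a limiting-enzyme true signal fails in
#'   one replicate (both duplicate spots drop together).
#' @slot crossreactiveFraction fraction of proteins positive on negative
#'   control arrays (and all others).
#' @slot seed integer master seed.
#' @export
setClass("SimParams",
    representation(nProteins = "integer", nBlocks = "integer",
                   blockRows = "integer", blockCols = "integer",
                   backgroundMeanlog = "numeric", backgroundSdlog = "numeric",
                   nullRatioSd = "numeric", hitRatioMean = "numeric",
                   hitRatioSd = "numeric", blockEffectSd = "numeric",
                   replicateDropout = "numeric",
                   crossreactiveFraction = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
    if (any(c(object@backgroundSdlog, object@nullRatioSd, object@hitRatioSd,
              object@blockEffectSd) < 0))
        msg <- c(msg, "dispersions must be >= 0")
    if (object@hitRatioMean <= 1)
        msg <- c(msg, "hitRatioMean must be > 1")
    if (object@replicateDropout < 0 || object@replicateDropout > 1 ||
        object@crossreactiveFraction < 0 || object@crossreactiveFraction > 1)
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@nBlocks * object@blockRows * object@blockCols <
        2L * object@nProteins)
        msg <- c(msg, "grid capacity below 2 * nProteins")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of a simulated study
#'
#' @slot conditions list of [ConditionLabel-class] objects in the study.
#' @slot truth named list (by condition name) of the expected final substrate
#'   set per condition: the E3-dependent set for E3 conditions, the planted
#'   high-enzyme set for 50x conditions, the cross-reactive set for negatives.
#' @slot shared50x named list: for E3 conditions, the matched-isoform 50x
#'   substrates that also react on those arrays (removed by 50x subtraction).
#' @slot crossReactive character vector of cross-reactive gene symbols.
#' @slot params the [SimParams-class] used.
#' @export
setClass("SimTruth",
    representation(conditions = "list", truth = "list", shared50x = "list",
                   crossReactive = "character", params = "SimParams"))

setValidity("SimTruth", function(object) {
    msg <- character()
    nm <- vapply(object@conditions, conditionName, character(1))
    if (!setequal(nm, names(object@truth)))
        msg <- c(msg, "truth names must match condition names")
    for (cond in object@conditions) {
        cn <- conditionName(cond)
        if (cond@e1e2Level == "x1" && cond@e3 != "none") {
            fifty <- object@truth[[paste0("50X-", cond@sumoIsoform)]]
            if (!is.null(fifty) &&
                length(intersect(object@truth[[cn]], fifty)))
                msg <- c(msg, paste0("E3-dependent set overlaps matched 50x set: ", cn))
        }
    }
    if (length(msg)) msg else TRUE
})
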