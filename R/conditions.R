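#' Construct a condition label
#'
#' @param e1e2Level `"x1"` (limiting enzymes) or `"x50"` (saturating).
#' @param e3 E3 ligase spiked into the reaction; `"none"` for enzyme-only
#'   reactions. `x50` reactions must be E3-free.
#' @param sumoIsoform `"SUMO1"` or `"SUMO2"`.
#' @return A [ConditionLabel-class].
#' @examples
#' conditionLabel("x1", "PIAS1", "SUMO1")
#' conditionLabel("x50", sumoIsoform = "SUMO2")
#' @export
conditionLabel <- function(e1e2Level = c("x1", "x50"), e3 = "none",
                           sumoIsoform = c("SUMO1", "SUMO2")) {
    e1e2Level <- match.arg(e1e2Level)
    sumoIsoform <- match.arg(sumoIsoform)
    new("ConditionLabel", e1e2Level = e1e2Level, e3 = as.character(e3),
        sumoIsoform = sumoIsoform)
}

#' Canonical condition node name
#'
#' `"50X-<ISOFORM>"` for saturating-enzyme controls, `"NEG-<ISOFORM>"` for the
#' limiting-enzyme negative controls, `"<E3>-<ISOFORM>"` otherwise.
#'
#' @param x a [ConditionLabel-class].
#' @return A single character string.
#' @export
conditionName <- function(x) {
    stopifnot(is(x, "ConditionLabel"))
    if (x@e1e2Level == "x50") return(paste0("50X-", x@sumoIsoform))
    if (x@e3 == "none") return(paste0("NEG-", x@sumoIsoform))
    paste0(x@e3, "-", x@sumoIsoform)
}

#' Parse a condition node name back into a label
#'
#' @param name a name produced by [conditionName()].
#' @return A [ConditionLabel-class].
#' @export
parseConditionName <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    parts <- strsplit(name, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[2] %in% .ISO_LEVELS)
        stop("not a condition name: ", name)
    if (parts[1] == "50X") return(conditionLabel("x50", "none", parts[2]))
    if (parts[1] == "NEG") return(conditionLabel("x1", "none", parts[2]))
    conditionLabel("x1", parts[1], parts[2])
}

#' Is this condition the limiting-enzyme negative control?
#'
#' @param x a [ConditionLabel-class].
#' @return Logical.
#' @export
isNegativeControl <- function(x) {
    stopifnot(is(x, "ConditionLabel"))
    x@e1e2Level == "x1" && x@e3 == "none"
}

setMethod("show", "ConditionLabel", function(object) {
    cat("ConditionLabel:", conditionName(object),
        sprintf("(E1/E2 %s, E3 %s, %s)\n", object@e1e2Level, object@e3,
                object@sumoIsoform))
})
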