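#' @include AllClasses.R conditions.R
NULL

#' Build the condition-to-substrate bipartite network
#'
#' One condition node per hit table, one substrate node per distinct symbol,
#' and an edge wherever a substrate was called in a condition. Edge attribute
#' `e3_dependent` is carried over from the hit evidence.
#'
#' @param hitTables list of [HitTable-class] objects with distinct conditions.
#' @return A [SubstrateNetwork-class].
#' @export
buildNetwork <- function(hitTables) {
    stopifnot(is.list(hitTables),
              all(vapply(hitTables, is, logical(1), "HitTable")))
    conds <- vapply(hitTables, function(t) conditionName(t@condition),
                    character(1))
    if (anyDuplicated(conds))
        stop("duplicate condition labels: ",
             paste(unique(conds[duplicated(conds)]), collapse = ", "))
    edges <- do.call(rbind, lapply(hitTables, function(t) {
        h <- t@hits
        if (!nrow(h)) return(NULL)
        data.frame(condition = conditionName(t@condition),
                   substrate = h$substrate, e3_dependent = h$e3_dependent,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
        edges <- data.frame(condition = character(), substrate = character(),
                            e3_dependent = logical())
    edges <- edges[order(edges$condition, edges$substrate), , drop = FALSE]
    rownames(edges) <- NULL
    new("SubstrateNetwork", conditions = sort(conds), edges = edges)
}

#' Substrates unique to a single condition
#'
#' A substrate is unique when its network degree is exactly 1, i.e. it was
#' called in only one of all the reactions carried out.
#'
#' @param network a [SubstrateNetwork-class].
#' @return Named list over conditions of sorted character vectors; the union
#'   over conditions is exactly the set of degree-1 substrates.
#' @export
uniqueSubstrates <- function(network) {
    stopifnot(is(network, "SubstrateNetwork"))
    deg <- substrateDegree(network)
    singles <- names(deg)[deg == 1L]
    e <- network@edges
    out <- lapply(network@conditions, function(cn)
        sort(intersect(e$substrate[e$condition == cn], singles)))
    names(out) <- network@conditions
    out
}

#' SUMO isoform preference of an E3 ligase
#'
#' The fraction of an E3's total called substrates modified with SUMO1 versus
#' SUMO2. Substrates modified with both isoforms are counted in both totals
#' (no deduplication), so `pct_sumo1 = 100 * total_s1 / (total_s1 + total_s2)`.
#'
#' @param e3 E3 ligase name (or `"50X"` for the enzyme-only reactions).
#' @param totalS1,totalS2 total hit counts with SUMO1 and SUMO2.
#' @return `data.frame` with columns `e3`, `pct_sumo1`, `pct_sumo2`
#'   (percentages summing to 100).
#' @examples
#' isoformPreference("TOPORS", 197, 73)   # 73% SUMO1
#' @export
isoformPreference <- function(e3, totalS1, totalS2) {
    stopifnot(totalS1 >= 0, totalS2 >= 0)
    if (totalS1 + totalS2 == 0)
        stop("both totals are zero for ", e3)
    p1 <- 100 * totalS1 / (totalS1 + totalS2)
    data.frame(e3 = as.character(e3), pct_sumo1 = p1, pct_sumo2 = 100 - p1,
               stringsAsFactors = FALSE)
}

#' Shared-substrate percentage of two conditions
#'
#' The denominator behind a "share x% of their substrates" statement is a
#' reporting choice; three conventions are offered. `jaccard` (default):
#' `100 |A n B| / |A u B|`; `of_smaller`: `100 |A n B| / min(|A|, |B|)`;
#' `of_a`: `100 |A n B| / |A|`.
#'
#' @param setA,setB substrate sets (character vectors); at least one
#'   non-empty.
#' @param method `"jaccard"`, `"of_smaller"` or `"of_a"`.
#' @return Percentage in `[0, 100]`.
#' @export
sharedFraction <- function(setA, setB,
                           method = c("jaccard", "of_smaller", "of_a")) {
    method <- match.arg(method)
    setA <- unique(setA); setB <- unique(setB)
    if (!length(setA) && !length(setB))
        stop("both sets are empty")
    i <- length(intersect(setA, setB))
    denom <- switch(method,
        jaccard = length(union(setA, setB)),
        of_smaller = min(length(setA), length(setB)),
        of_a = length(setA))
    if (denom == 0) stop("denominator set is empty under method '", method, "'")
    100 * i / denom
}

#' Export a network for Cytoscape or re-import
#'
#' `sif`: lines `condition<TAB>sumoylates<TAB>substrate`. `graphml`: via
#' igraph, node attribute `node_type` (`condition`/`substrate`) and edge
#' attribute `e3_dependent`. `tsv`: edge list with header, re-importable via
#' [readNetwork()]. All outputs use deterministic ordering.
#'
#' @param network a [SubstrateNetwork-class].
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
exportNetwork <- function(network, format = c("tsv", "sif", "graphml"),
                          path) {
    stopifnot(is(network, "SubstrateNetwork"))
    format <- match.arg(format)
    e <- network@edges
    e <- e[order(e$condition, e$substrate), , drop = FALSE]
    if (format == "sif") {
        writeLines(if (nrow(e)) paste(e$condition, "sumoylates", e$substrate,
                                      sep = "\t") else character(0), path)
    } else if (format == "tsv") {
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, eol = "\n",
                           fileEncoding = "UTF-8")
    } else {
        verts <- data.frame(
            name = c(sort(network@conditions), sort(unique(e$substrate))),
            node_type = c(rep("condition", length(network@conditions)),
                          rep("substrate", length(unique(e$substrate)))),
            stringsAsFactors = FALSE)
        g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                           vertices = verts)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Re-import a TSV edge list as a network
#'
#' Inverse of `exportNetwork(..., format = "tsv")`. Condition nodes are taken
#' from the edge list (isolated condition nodes are not representable in an
#' edge list).
#'
#' @param path a TSV edge list with columns `condition`, `substrate`,
#'   `e3_dependent`.
#' @return A [SubstrateNetwork-class].
#' @export
readNetwork <- function(path) {
    e <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("condition", "substrate", "e3_dependent")
    miss <- setdiff(need, names(e))
    if (length(miss))
        stop("edge list missing columns: ", paste(miss, collapse = ", "))
    e$e3_dependent <- as.logical(e$e3_dependent)
    e <- e[order(e$condition, e$substrate), , drop = FALSE]
    rownames(e) <- NULL
    new("SubstrateNetwork", conditions = sort(unique(e$condition)), edges = e)
}
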