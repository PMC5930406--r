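#' @include AllClasses.R
NULL

#' Hypergeometric upper-tail probability
#'
#' Exact probability of observing `k` or more marked elements when drawing
#' `n` from a universe of `N` containing `K` marked elements — the
#' over-representation p-value. Computed with `stats::phyper` (exact,
#' numerically stable tail evaluation).
#'
#' @param k observed overlap count.
#' @param K marked elements in the universe (annotation-set size).
#' @param n draw size (number of hits).
#' @param N universe size (array background).
#' @return `P(X >= k)` in `(0, 1]`.
#' @examples
#' hypergeomSF(2, 4, 3, 10)   # 1/3
#' @export
hypergeomSF <- function(k, K, n, N) {
    stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
              length(N) == 1L)
    if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || k > K || K > N)
        stop("require 0 <= k <= n <= N and k <= K <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via `stats::p.adjust`: monotone
#' after sorting, capped at 1, input order preserved.
#'
#' @param pValues numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order; empty in, empty out.
#' @export
bhAdjust <- function(pValues) {
    if (!length(pValues)) return(numeric(0))
    stopifnot(is.numeric(pValues), all(pValues > 0), all(pValues <= 1))
    stats::p.adjust(pValues, method = "BH")
}

#' Over-representation of annotation sets among hits
#'
#' One hypergeometric upper-tail test per term against the full-array
#' background (the set of proteins printed, never the genome). Term sets are
#' intersected with the background before testing; terms with no background
#' member are dropped. Results are sorted by ascending p with BH q-values
#' computed over all tested terms; the conventional report filter is raw
#' `p < 0.05`, with q-values printed alongside.
#'
#' @param hits character vector of hit symbols, a subset of `background`.
#' @param terms named list of character vectors (e.g. from [readGMT()]).
#' @param background character vector: the array's substrate universe.
#' @return `data.frame` with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   sorted by ascending `p` (ties by term name).
#' @export
enrichTerms <- function(hits, terms, background) {
    background <- unique(background)
    if (!length(background)) stop("empty background")
    hits <- unique(hits)
    if (length(setdiff(hits, background)))
        stop("hits must be a subset of the background")
    stopifnot(is.list(terms), !is.null(names(terms)))
    N <- length(background)
    n <- length(hits)
    rows <- lapply(names(terms), function(tm) {
        tset <- intersect(unique(terms[[tm]]), background)
        K <- length(tset)
        if (K == 0L) return(NULL)
        k <- length(intersect(tset, hits))
        data.frame(term = tm, k = k, K = K, n = n, N = N,
                   p = hypergeomSF(k, K, n, N), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          q = numeric()))
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Significance of the overlap between two protein sets
#'
#' Hypergeometric upper-tail test of `|A n B|` against random draws from the
#' background: `k = |A n B|`, `K = |A|`, `n = |B|`, `N = |background|`.
#' Equivalent to [enrichTerms()] with a single-term annotation.
#'
#' @param setA,setB protein sets, subsets of `background`.
#' @param background the array's substrate universe.
#' @return One-row `data.frame` with columns `k`, `K`, `n`, `N`, `p`.
#' @export
overlapSignificance <- function(setA, setB, background) {
    background <- unique(background)
    setA <- unique(setA); setB <- unique(setB)
    if (length(setdiff(setA, background)) || length(setdiff(setB, background)))
        stop("both sets must be subsets of the background")
    k <- length(intersect(setA, setB))
    data.frame(k = k, K = length(setA), n = length(setB),
               N = length(background),
               p = hypergeomSF(k, length(setA), length(setB),
                               length(background)))
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines `term<TAB>description<TAB>member...`, read via
#' `fgsea::gmtPathways`.
#'
#' @param path a GMT file.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param terms named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(terms, path, descriptions = NULL) {
    stopifnot(is.list(terms), !is.null(names(terms)))
    if (is.null(descriptions)) descriptions <- rep("na", length(terms))
    writeLines(vapply(seq_along(terms), function(i)
        paste(c(names(terms)[i], descriptions[i], terms[[i]]),
              collapse = "\t"), character(1)), path)
    invisible(path)
}
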