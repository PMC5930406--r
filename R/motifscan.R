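#' @include AllClasses.R
NULL

## Broad hydrophobic residue set used as the default Psi of the Psi-K-x-E/D
## SUMOylation consensus; configurable because published tools differ.
.PSI_DEFAULT <- c("A", "I", "L", "M", "P", "F", "V")

.check_sequence <- function(chars) {
    ok <- chars %in% c(.AA20, "X")
    if (!all(ok))
        stop("illegal character '", chars[!ok][1], "' at position ",
             which(!ok)[1])
    invisible(TRUE)
}

## parse a character-class pattern like "[VIL][VIL].[VIL][VIL]" into a list
## of residue sets; "." is the wildcard (NULL entry, matches anything
## including X); X never satisfies a residue class
.parse_class_pattern <- function(pattern) {
    out <- list()
    i <- 1L
    chars <- strsplit(pattern, "")[[1]]
    while (i <= length(chars)) {
        if (chars[i] == "[") {
            j <- which(chars == "]" & seq_along(chars) > i)[1]
            if (is.na(j)) stop("unterminated class in pattern: ", pattern)
            out[[length(out) + 1L]] <- chars[(i + 1L):(j - 1L)]
            i <- j + 1L
        } else if (chars[i] == ".") {
            out[length(out) + 1L] <- list(NULL)
            i <- i + 1L
        } else {
            out[[length(out) + 1L]] <- chars[i]
            i <- i + 1L
        }
    }
    out
}

.match_class_pattern <- function(chars, sets) {
    n <- length(chars)
    w <- length(sets)
    if (n < w) return(integer(0))
    keep <- rep(TRUE, n - w + 1L)
    for (k in seq_len(w)) {
        if (is.null(sets[[k]])) next
        keep <- keep & chars[seq_len(n - w + 1L) + k - 1L] %in% sets[[k]]
    }
    which(keep)
}

#' Scan a protein sequence for the SUMOylation consensus motif
#'
#' Finds forward Psi-K-x-(E/D) sites (hit reported at the acceptor K) and,
#' optionally, inverted (E/D)-x-K-Psi sites. Psi is a large hydrophobic
#' residue (default `A I L M P F V`). The middle `x` position is a wildcard;
#' `X` (unknown residue) never satisfies a residue class. Overlapping hits
#' are all reported, in ascending position.
#'
#' @param sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @param psiSet character vector of residues accepted as Psi.
#' @param includeInverted also report inverted-consensus sites?
#' @return `data.frame` with columns `position` (1-based index of the K),
#'   `motif_class` (`consensus_forward` / `consensus_inverted`), `window`
#'   (matched 4-mer).
#' @examples
#' scanConsensus("AIKQEG")            # forward hit at K, position 3
#' @export
scanConsensus <- function(sequence, psiSet = .PSI_DEFAULT,
                          includeInverted = FALSE) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    empty <- data.frame(position = integer(), motif_class = character(),
                        window = character(), stringsAsFactors = FALSE)
    if (!nzchar(sequence)) return(empty)
    chars <- strsplit(toupper(sequence), "")[[1]]
    .check_sequence(chars)
    hits <- empty
    fwd <- .match_class_pattern(chars, list(psiSet, "K", NULL, c("E", "D")))
    if (length(fwd))
        hits <- rbind(hits, data.frame(
            position = fwd + 1L, motif_class = "consensus_forward",
            window = vapply(fwd, function(s)
                paste(chars[s:(s + 3L)], collapse = ""), character(1)),
            stringsAsFactors = FALSE))
    if (includeInverted) {
        inv <- .match_class_pattern(chars, list(c("E", "D"), NULL, "K", psiSet))
        if (length(inv))
            hits <- rbind(hits, data.frame(
                position = inv + 2L, motif_class = "consensus_inverted",
                window = vapply(inv, function(s)
                    paste(chars[s:(s + 3L)], collapse = ""), character(1)),
                stringsAsFactors = FALSE))
    }
    hits <- hits[order(hits$position, hits$motif_class), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Scan a protein sequence for SUMO-interacting motifs
#'
#' Matches a configurable hydrophobic-core pattern (default
#' `[VIL][VIL].[VIL][VIL]`, the simplest published SIM core; a deliberate
#' stand-in, since SIM definitions vary between tools). Hit positions are the
#' 1-based match starts; overlapping matches are all reported.
#'
#' @param sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @param pattern character-class pattern; `[...]` is a residue class, `.` a
#'   wildcard.
#' @return `data.frame` with columns `position`, `motif_class` (`sim`),
#'   `window`.
#' @examples
#' scanSIM("VVDVV")   # hit at position 1
#' @export
scanSIM <- function(sequence, pattern = "[VIL][VIL].[VIL][VIL]") {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    empty <- data.frame(position = integer(), motif_class = character(),
                        window = character(), stringsAsFactors = FALSE)
    if (!nzchar(sequence)) return(empty)
    chars <- strsplit(toupper(sequence), "")[[1]]
    .check_sequence(chars)
    sets <- .parse_class_pattern(pattern)
    w <- length(sets)
    pos <- .match_class_pattern(chars, sets)
    if (!length(pos)) return(empty)
    out <- data.frame(position = pos, motif_class = "sim",
                      window = vapply(pos, function(s)
                          paste(chars[s:(s + w - 1L)], collapse = ""),
                          character(1)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Scan a set of sequences
#'
#' Applies a scanner over a FASTA-derived sequence set and binds the results
#' with protein identifiers.
#'
#' @param sequences a named character vector or `Biostrings::AAStringSet`.
#' @param scanner a function taking one sequence string and returning a
#'   motif-hit `data.frame` ([scanConsensus()] or [scanSIM()], possibly with
#'   parameters fixed).
#' @return `data.frame` with columns `protein_id`, `position`, `motif_class`,
#'   `window`.
#' @export
scanSequences <- function(sequences, scanner = scanConsensus) {
    if (is(sequences, "AAStringSet"))
        sequences <- stats::setNames(as.character(sequences),
                                     names(sequences))
    stopifnot(is.character(sequences), !is.null(names(sequences)))
    out <- do.call(rbind, lapply(names(sequences), function(id) {
        h <- scanner(sequences[[id]])
        if (!nrow(h)) return(NULL)
        cbind(data.frame(protein_id = rep(id, nrow(h)),
                         stringsAsFactors = FALSE), h)
    }))
    if (is.null(out))
        out <- data.frame(protein_id = character(), position = integer(),
                          motif_class = character(), window = character(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet`; wrapped and unwrapped
#' FASTA are equivalent. Sequence names are truncated at the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    nm <- sub("\\s.*$", "", names(aa))
    stats::setNames(as.character(aa), nm)
}

#' Motif occurrence over a hit set
#'
#' Fraction of called substrates whose sequence carries at least one motif
#' hit under the given scanner. Substrates without an available sequence are
#' counted, logged and excluded from the denominator.
#'
#' @param hitSet character vector of substrate identifiers.
#' @param sequences named character vector (or `AAStringSet`) of sequences.
#' @param scanner scanner function as in [scanSequences()].
#' @return A list with `n_proteins_scanned`, `n_with_site`,
#'   `fraction_with_site` (percentage), `n_missing_sequence`.
#' @export
summarizeMotifCoverage <- function(hitSet, sequences,
                                   scanner = scanConsensus) {
    if (is(sequences, "AAStringSet"))
        sequences <- stats::setNames(as.character(sequences),
                                     names(sequences))
    hitSet <- unique(hitSet)
    have <- intersect(hitSet, names(sequences))
    missing <- setdiff(hitSet, names(sequences))
    if (length(missing))
        .sa_log(length(missing), " substrate(s) without sequence excluded")
    if (!length(have))
        stop("no sequences available for any substrate in the hit set")
    with_site <- vapply(have, function(id) nrow(scanner(sequences[[id]])) > 0L,
                        logical(1))
    list(n_proteins_scanned = length(have),
         n_with_site = sum(with_site),
         fraction_with_site = 100 * sum(with_site) / length(have),
         n_missing_sequence = length(missing))
}
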