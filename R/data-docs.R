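#' Published per-condition hit counts from a proteome-wide SUMOylation screen
#'
#' Reads the bundled table of per-condition substrate counts reported by a
#' published HuProt-based SUMOylation screen: total and reaction-unique hit
#' counts per E3 ligase/SUMO-isoform pairing and for the two
#' saturating-enzyme (50x) controls, together with the isoform-preference
#' percentage as printed. These counts are inputs for the network statistics
#' (isoform preference, uniqueness totals); note that for RanBP2 the printed
#' preference (62.8%) is not the value implied by its totals (64.6%) — a
#' documented inconsistency of the source table that this package does not
#' resolve.
#'
#' @return `data.frame` with columns `condition`, `group`, `isoform`,
#'   `total`, `unique` (`NA` for the 50x rows), `printed_isoform_pct`.
#' @examples
#' counts <- screenCounts()
#' sum(counts$unique, na.rm = TRUE)
#' @export
screenCounts <- function() {
    path <- system.file("extdata", "huprot_screen_counts.tsv",
                        package = "sumoarray", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
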