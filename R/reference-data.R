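#' Published top DE lncRNA abundances (goat hair-follicle study)
#'
#' The published top-20 differentially expressed lncRNA table from the
#' cashmere-goat anagen/catagen skin comparison this pipeline is modelled
#' on: per-row catagen and anagen group FPKM, the printed log2 fold change
#' (catagen/anagen) and p/q values. Used to validate the fold-change
#' convention: the printed log2fc equals the log2 ratio of the printed
#' group FPKMs to within printed precision. One degenerate row
#' (XLOC_011150, catagen FPKM 0) has `log2fc_printed = NA`: the published
#' spreadsheet shows an error artifact where the -Inf ratio would be.
#'
#' @return data.frame with columns `gene_id`, `symbol`, `catagen_fpkm`,
#'   `anagen_fpkm`, `log2fc_printed`, `pvalue`, `qvalue`.
#' @export
reference_de_lncrna <- function() {
  utils::read.delim(
    system.file("extdata", "reference_de_lncrna.tsv", package = "cernet",
                mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = c(
      gene_id = "character", symbol = "character",
      catagen_fpkm = "numeric", anagen_fpkm = "numeric",
      log2fc_printed = "numeric", pvalue = "numeric", qvalue = "numeric"))
}

# number of decimal places carried by a printed numeric string
printed_decimals <- function(x) {
  ifelse(grepl("\\.", x), nchar(sub("^[^.]*\\.", "", x)), 0L)
}

#' Precision-propagation bound for reproducing a printed log2 ratio
#'
#' Printed group abundances are rounded; re-deriving log2(c/a) from them
#' can differ from the originally computed value by up to half an ULP of
#' each printed operand propagated through the ratio, plus half an ULP of
#' the printed log2fc itself:
#' `(0.5 * 10^-dc / c + 0.5 * 10^-da / a) / ln(2) + 0.5 * 10^-dl`.
#'
#' @param catagen,anagen printed abundances (numeric).
#' @param catagen_str,anagen_str,lfc_str the printed strings (to count
#'   decimals).
#' @return Numeric vector of absolute-error bounds.
#' @export
log2fc_precision_bound <- function(catagen, anagen, catagen_str,
                                   anagen_str, lfc_str) {
  dc <- printed_decimals(catagen_str)
  da <- printed_decimals(anagen_str)
  dl <- printed_decimals(lfc_str)
  (0.5 * 10^(-dc) / catagen + 0.5 * 10^(-da) / anagen) / log(2) +
    0.5 * 10^(-dl)
}
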