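#' Worked-example count data: goat mammary gland, dry period vs peak
#' lactation
#'
#' Published per-miRNA raw read counts for the fifteen most differentially
#' expressed conserved miRNAs from a two-library small RNA sequencing
#' study of the dairy goat mammary gland (dry period library "D", peak
#' lactation library "P"), together with the normalised expressions, log2
#' fold changes and p-values as printed in the study's differential
#' expression table.  Used as a worked arithmetic example and as the
#' fixture for validating the normalisation, fold-change and significance
#' machinery against published values.
#'
#' @return data.frame with `name`, `dry`, `peak` (raw counts),
#'   `printed_ne_dry`, `printed_ne_peak` (normalised expressions as
#'   printed), `printed_log2fc`, and `printed_pvalue` (0 where the study
#'   printed 0).
#' @seealso [mammary_library_sizes()], [mammary_qc_counts()]
#' @export
mammary_de_counts <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name dry peak printed_ne_dry printed_ne_peak printed_log2fc printed_pvalue
miR-2887 385 1671 25.9235 106.3458 2.0364 4.3e-175
miR-451 749 1665 50.433 105.964 1.0711 1.25e-68
miR-2478 869 1888 58.5131 120.1561 1.0381 8.41e-74
miR-199b 1565 290 105.3774 18.4562 -2.5134 3e-227
miR-128 8512 1408 573.1456 89.608 -2.6772 0
miR-25 36578 5728 2462.937 364.5414 -2.7563 0
miR-145 41213 6254 2775.029 398.0171 -2.8016 0
miR-98 2531 370 170.4219 23.5475 -2.8555 0
miR-222 5223 734 351.6846 46.7132 -2.9124 0
miR-181b 5330 734 358.8893 46.7132 -2.9416 0
miR-199a-3p 152691 20829 10281.27 1325.6 -2.9553 0
miR-93 3593 460 241.9305 29.2753 -3.0468 0
miR-221 7848 790 528.4359 50.2772 -3.3938 0
let-7b 443620 32993 29870.63 2099.741 -3.8304 0
let-7c 341112 27377 22968.38 1742.327 -3.7206 0")
  df
}

#' Library totals for the worked example
#'
#' Total clean reads of the dry-period and peak-lactation libraries in the
#' published study behind [mammary_de_counts()].
#'
#' @return named numeric vector with elements `dry` and `peak`.
#' @export
mammary_library_sizes <- function() {
  c(dry = 14851375, peak = 15712891)
}

#' Published per-library read accounting for the worked example
#'
#' Raw and per-filter read counts of the two sequencing libraries as
#' printed in the study's accounting table, plus the unique clean tag
#' counts.
#'
#' @return data.frame with one row per library (`dry`, `peak`).
#' @export
mammary_qc_counts <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
library raw_reads high_quality adapter3_null insert_null adapter5_contaminant shorter_than_18 polyA clean_reads unique_tags
dry 15706825 15632233 15496 15085 78042 671847 388 14851375 788915
peak 17349265 17220358 19367 10406 49684 1427823 187 15712891 1108514")
}
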