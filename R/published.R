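# Accessors for the published reference summary tables of the Ningxia
# barnyard grass (Echinochloa spp.) diversity study that this package's
# methods reproduce. Only printed summary values are shipped; the raw
# 46-population measurements were not deposited.

#' Published per-trait summary of the 46-population study
#'
#' The printed per-trait statistics (range, max, min, mean, sample SD, CV %
#' and ten-level Shannon-Wiener H') for the nine quantitative traits of the
#' 46 Ningxia barnyard grass populations. Useful as input for aggregate
#' checks: the package recomputes the quoted column means (mean CV 44.01%,
#' mean H' 1.69) and the M9 CV from its printed mean and SD.
#'
#' @return Tibble with `trait`, `range`, `max`, `min`, `mean`, `s`, `cv`,
#'   `h`.
#' @export
published_trait_summary <- function() {
  readr::read_csv(system.file("extdata", "trait_summary_published.csv",
                              package = "echinodiv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published per-primer SCoT summary of the 46-population study
#'
#' The printed per-primer results of the six-primer SCoT screen: melting
#' temperature, polymorphic band count, average band (allele) frequency and
#' PIC. Band totals per primer were printed only for SCoT12 (9) and SCoT20
#' (15); the remaining counts are `NA` and only the overall total of 72
#' scored bands is known.
#'
#' @return Tibble with `primer`, `tm`, `n_polymorphic`, `n_bands`,
#'   `mean_freq`, `pic`.
#' @export
published_primer_summary <- function() {
  readr::read_csv(system.file("extdata", "scot_primer_published.csv",
                              package = "echinodiv"),
                  show_col_types = FALSE, progress = FALSE)
}
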