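# Herbicide multi-resistance profiling: fresh-weight inhibition, the 78%
# resistance call, site-of-action (SOA) counting, and correlation of
# multi-resistance with quantitative traits.

#' Fresh-weight inhibition rate
#'
#' `100 * (1 - treated / control)` percent, clamped below at 0 when the
#' treated plants outgrew the untreated controls.
#'
#' @param treated_fw Above-ground fresh weight under treatment (g), >= 0.
#' @param control_fw Untreated-control fresh weight (g), > 0.
#' @return Inhibition percentage in \[0, 100\]; vectorized.
#' @export
inhibition_rate <- function(treated_fw, control_fw) {
  if (any(control_fw <= 0)) abort_input("inhibition_rate: control fresh weight must be > 0")
  if (any(treated_fw < 0)) abort_input("inhibition_rate: treated fresh weight must be >= 0")
  pmax(0, 100 * (1 - treated_fw / control_fw))
}

#' Resistance call from an inhibition rate
#'
#' A biotype is called resistant when its fresh-weight inhibition rate is
#' strictly below 78% of the untreated control.
#'
#' @param inhibition Inhibition percentage in \[0, 100\]; vectorized.
#' @param threshold Resistance threshold in percent (default 78).
#' @return Logical vector: `TRUE` = resistant.
#' @export
call_resistance <- function(inhibition, threshold = 78) {
  if (any(inhibition < 0 | inhibition > 100)) {
    abort_input("call_resistance: inhibition must lie in [0, 100]")
  }
  inhibition < threshold
}

#' Default herbicide-to-site-of-action map
#'
#' The six herbicides of the whole-plant assay with an HRAC/WSSA-style
#' mechanism grouping: ACCase inhibitors (metamifop, cyhalofop-butyl), ALS
#' inhibitors (penoxsulam, pyribenzoxim), photosystem II inhibitor
#' (propanil), synthetic auxin (quinclorac). Overridable wherever an
#' `soa_map` argument is accepted.
#'
#' @return A tibble with columns `herbicide` and `soa`.
#' @export
default_soa_map <- function() {
  tibble::tibble(
    herbicide = c("metamifop", "cyhalofop-butyl", "penoxsulam",
                  "pyribenzoxim", "propanil", "quinclorac"),
    soa = c("ACCase", "ACCase", "ALS", "ALS", "PSII", "auxin")
  )
}

#' Per-population resistance profile
#'
#' Applies the inhibition threshold to every population x herbicide record.
#'
#' @param resistance A tibble with `population_id`, `herbicide` and
#'   `inhibition` (see [read_resistance_table()]).
#' @param threshold Resistance threshold in percent.
#' @return The input with a logical `resistant` column added.
#' @export
resistance_profile <- function(resistance, threshold = 78) {
  dplyr::mutate(tibble::as_tibble(resistance),
                resistant = call_resistance(.data$inhibition, threshold))
}

#' Multi-resistance counts per population
#'
#' Counts, per population, the number of herbicides with a resistant call
#' and the number of distinct herbicide sites of action (SOAs) with at least
#' one resistant call. Duplicating a herbicide within an SOA class never
#' changes the SOA count.
#'
#' @param profile Output of [resistance_profile()].
#' @param soa_map Herbicide-to-SOA map (default [default_soa_map()]).
#' @return A tibble with `population_id`, `n_resistant`, `soa_count`.
#' @export
multi_resistance <- function(profile, soa_map = default_soa_map()) {
  unmapped <- setdiff(unique(profile$herbicide), soa_map$herbicide)
  if (length(unmapped)) {
    abort_input("multi_resistance: herbicide '%s' missing from SOA map", unmapped[[1]])
  }
  dplyr::left_join(profile, soa_map, by = "herbicide") |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      n_resistant = sum(.data$resistant),
      soa_count = dplyr::n_distinct(.data$soa[.data$resistant]),
      .groups = "drop"
    )
}

#' Correlation of quantitative traits with multi-resistance
#'
#' Pearson correlation of each trait with the per-population
#' multi-resistance count (distinct resistant SOAs by default, resistant
#' herbicides on request), with a two-sided p-value from the t distribution
#' on n - 2 degrees of freedom and significance flags at 0.05 and 0.01.
#' Traits with zero variance are reported with missing r and p.
#'
#' @param table A trait table.
#' @param counts Output of [multi_resistance()].
#' @param measure `"soa"` (default) correlates against `soa_count`,
#'   `"herbicide"` against `n_resistant`.
#' @param traits Trait columns; defaults to `M1`--`M9` present in the table.
#' @return A tibble with `trait`, `r`, `p`, `sig` (`""`, `"*"` for p <= 0.05,
#'   `"**"` for p <= 0.01).
#' @export
trait_resistance_correlation <- function(table, counts,
                                         measure = c("soa", "herbicide"),
                                         traits = NULL) {
  measure <- match.arg(measure)
  table <- validate_trait_table(table)
  if (is.null(traits)) traits <- intersect(TRAIT_COLS, names(table))
  joined <- dplyr::inner_join(table, counts, by = "population_id")
  if (nrow(joined) < 3) abort_input("trait_resistance_correlation: need n >= 3 matched populations")
  y <- if (measure == "soa") joined$soa_count else joined$n_resistant
  purrr::map(traits, function(tr) {
    cor_with_p(joined[[tr]], y) |> dplyr::mutate(trait = tr, .before = 1)
  }) |>
    purrr::list_rbind()
}

# Pearson r with a two-sided t-test p-value on n-2 df; NA for degenerate
# vectors rather than an error so one flat trait never aborts a screen.
#' @noRd
cor_with_p <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, sig = NA_character_))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p = p,
                 sig = dplyr::case_when(p <= 0.01 ~ "**",
                                        p <= 0.05 ~ "*",
                                        TRUE ~ ""))
}
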