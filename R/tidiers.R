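# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy a trait diversity result
#'
#' @param x A `trait_diversity` object.
#' @param ... Unused.
#' @return The per-trait summary tibble (`trait`, `range`, `max`, `min`,
#'   `mean`, `s`, `cv`, `h`).
#' @method tidy trait_diversity
#' @export
tidy.trait_diversity <- function(x, ...) x$summary

#' One-row overview of a trait diversity result
#'
#' @param x A `trait_diversity` object.
#' @param ... Unused.
#' @return One-row tibble with `n_populations` plus the column aggregates of
#'   [trait_summary_aggregates()].
#' @method glance trait_diversity
#' @export
glance.trait_diversity <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_populations = x$n),
                   trait_summary_aggregates(x$summary))
}

#' Tidy a dendrogram into its merge history
#'
#' @param x A `marker_dendrogram`.
#' @param ... Unused.
#' @return Tibble with one row per merge: `step`, `cluster_a`, `cluster_b`
#'   (negative = leaf index, positive = earlier merge step), `height` (on
#'   the rescaled axis when rescaling is on) and `new_size`.
#' @method tidy marker_dendrogram
#' @export
tidy.marker_dendrogram <- function(x, ...) {
  hc <- x$hclust
  size <- integer(length(x$heights))
  for (s in seq_along(size)) {
    size[s] <- sum(vapply(hc$merge[s, ], function(m) {
      if (m < 0) 1L else size[m]
    }, integer(1)))
  }
  tibble::tibble(step = seq_along(x$heights),
                 cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
                 height = x$heights, new_size = size)
}

#' @method glance marker_dendrogram
#' @export
glance.marker_dendrogram <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), linkage = x$linkage,
                 rescaled = x$rescaled, max_height = max(x$heights))
}

#' Tidy an SNP profile
#'
#' @param x An `snp_profile`.
#' @param ... Unused.
#' @return Long tibble with `sample_id`, `position` and the observed `state`
#'   at every variable site.
#' @method tidy snp_profile
#' @export
tidy.snp_profile <- function(x, ...) {
  if (nrow(x$sites) == 0) {
    return(tibble::tibble(sample_id = character(), position = integer(),
                          state = character()))
  }
  tibble::as_tibble(x$states, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "position",
                        values_to = "state") |>
    dplyr::mutate(position = as.integer(.data$position))
}

#' @method glance snp_profile
#' @export
glance.snp_profile <- function(x, ...) {
  tibble::tibble(locus = x$locus, n_samples = nrow(x$haplotypes),
                 n_variable_sites = nrow(x$sites),
                 n_haplotypes = max(x$haplotypes$haplotype))
}

#' Tidy a marker concordance result
#'
#' @param x A `marker_concordance`.
#' @param ... Unused.
#' @return One row per method pair: `method_a`, `method_b`, `r`, `p`, `sig`,
#'   and the relabeling-maximized `r_max` diagnostic.
#' @method tidy marker_concordance
#' @export
tidy.marker_concordance <- function(x, ...) {
  k <- length(x$methods)
  purrr::map(seq_len(k - 1), function(i) {
    purrr::map((i + 1):k, function(j) {
      p <- x$p[i, j]
      tibble::tibble(method_a = x$methods[i], method_b = x$methods[j],
                     r = x$r[i, j], p = p,
                     sig = dplyr::case_when(is.na(p) ~ NA_character_,
                                            p <= 0.01 ~ "**",
                                            p <= 0.05 ~ "*",
                                            TRUE ~ ""),
                     r_max = x$r_max[i, j])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' @method glance marker_concordance
#' @export
glance.marker_concordance <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble::tibble(n_methods = length(x$methods), n = x$n,
                 mean_r = mean(off, na.rm = TRUE),
                 min_p = min(x$p[upper.tri(x$p)], na.rm = TRUE))
}
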