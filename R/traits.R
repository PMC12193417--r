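# Quantitative-trait variation and diversity: per-trait summary statistics,
# ten-level binning around the trait mean, Shannon-Wiener diversity, and Ward
# clustering of standardized traits.

#' Summary statistics for one quantitative trait
#'
#' Computes range, max, min, mean, sample standard deviation (n-1
#' denominator, matching common statistical-software defaults) and the
#' coefficient of variation CV = 100 * s / mean for a vector of population
#' trait means.
#'
#' @param values Numeric vector of per-population trait values (>= 2 finite
#'   values).
#' @return A one-row tibble with columns `range`, `max`, `min`, `mean`, `s`,
#'   `cv`.
#' @export
summarize_trait <- function(values) {
  if (length(values) < 2 || any(!is.finite(values))) {
    abort_input("summarize_trait: need >= 2 finite values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0 && s > 0) {
    abort_input("summarize_trait: CV undefined (mean 0 with positive spread)")
  }
  cv <- if (s == 0) 0 else 100 * s / m
  tibble::tibble(range = max(values) - min(values),
                 max = max(values), min = min(values),
                 mean = m, s = s, cv = cv)
}

#' Assign ten diversity levels around the trait mean
#'
#' Populations are binned into 10 levels spanning `mean +/- 2 sd` in steps of
#' `0.5 sd`: level 1 holds values below `mean - 2 sd`, level 10 holds values
#' at or above `mean + 2 sd`, and the eight inner levels are half-open
#' intervals `[lo, hi)` of width `0.5 sd`. Genotype frequencies over these
#' levels feed the Shannon-Wiener index.
#'
#' @param values Numeric vector of trait values.
#' @param mean Trait mean defining the bin centre (defaults to `mean(values)`).
#' @param sd Trait standard deviation defining the bin width; must be > 0.
#' @return Integer vector of levels in 1..10, one per value.
#' @export
assign_levels <- function(values, mean = base::mean(values),
                          sd = stats::sd(values)) {
  if (!is.finite(sd) || sd <= 0) {
    abort_input("assign_levels: sd must be > 0 (degenerate trait)")
  }
  edges <- mean - 2 * sd + 0.5 * sd * (0:8)   # 9 inner edges
  lev <- findInterval(values, edges, left.open = FALSE) + 1L
  pmin(pmax(lev, 1L), 10L)
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(Pi * ln(Pi))` over class frequencies `Pi`, in nats.
#' Zero-frequency classes contribute nothing. Maximal (`ln(k)`) at the
#' uniform distribution over k classes; zero when a single class holds all
#' mass.
#'
#' @param freqs Non-negative frequency vector summing to 1.
#' @return The diversity index, a single non-negative number.
#' @export
shannon_index <- function(freqs) {
  if (any(freqs < 0)) abort_input("shannon_index: negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) {
    abort_input("shannon_index: frequencies must sum to 1 (got %.6f)", sum(freqs))
  }
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Trait variation and diversity table
#'
#' For every trait column of a population-by-trait table, computes the
#' summary row (range/max/min/mean/s/CV) plus the ten-level Shannon-Wiener
#' diversity index, the per-population level assignments and the level
#' frequency vectors. Traits with zero spread are rejected unless
#' `drop_degenerate = TRUE`, in which case they are dropped with a warning.
#'
#' @param table A trait table (see [read_trait_table()]).
#' @param traits Trait columns to analyse; defaults to `M1`--`M9` when
#'   present, otherwise all numeric columns except identifiers.
#' @param drop_degenerate Drop zero-variance traits instead of erroring.
#' @return A `trait_diversity` object with components `summary` (one row per
#'   trait: `trait`, `range`, `max`, `min`, `mean`, `s`, `cv`, `h`), `levels`
#'   (long tibble `population_id`, `trait`, `level`), `frequencies` (long
#'   tibble `trait`, `level`, `p`) and `n` (number of populations). `tidy()`
#'   returns the summary, `glance()` the column means of CV and H'.
#' @export
diversity_table <- function(table, traits = NULL, drop_degenerate = FALSE) {
  table <- validate_trait_table(table)
  if (is.null(traits)) traits <- intersect(TRAIT_COLS, names(table))
  if (nrow(table) < 2) abort_input("diversity_table: need >= 2 populations")
  degenerate <- traits[vapply(traits, function(tr) stats::sd(table[[tr]]) == 0,
                              logical(1))]
  if (length(degenerate)) {
    if (!drop_degenerate) {
      abort_input("diversity_table: trait %s has zero spread", degenerate[[1]])
    }
    warning("dropping degenerate trait(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    traits <- setdiff(traits, degenerate)
  }

  rows <- purrr::map(traits, function(tr) {
    v <- table[[tr]]
    smry <- summarize_trait(v)
    lev <- assign_levels(v, smry$mean, smry$s)
    p <- tabulate(lev, nbins = 10) / length(lev)
    list(
      summary = dplyr::mutate(smry, trait = tr, h = shannon_index(p),
                              .before = 1),
      levels = tibble::tibble(population_id = table$population_id,
                              trait = tr, level = lev),
      freqs = tibble::tibble(trait = tr, level = 1:10, p = p)
    )
  })

  out <- list(
    summary = purrr::list_rbind(purrr::map(rows, "summary")) |>
      dplyr::relocate("h", .after = "cv"),
    levels = purrr::list_rbind(purrr::map(rows, "levels")),
    frequencies = purrr::list_rbind(purrr::map(rows, "freqs")),
    n = nrow(table)
  )
  class(out) <- "trait_diversity"
  out
}

#' @export
print.trait_diversity <- function(x, ...) {
  cat(sprintf("<trait_diversity> %d populations, %d traits\n",
              x$n, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Column aggregates of a trait summary table
#'
#' Means of the CV and diversity columns across traits, plus their ranges —
#' the headline figures quoted from a trait diversity analysis.
#'
#' @param summary A tibble with columns `cv` and `h` (one row per trait),
#'   e.g. `diversity_table(x)$summary` or a published summary table.
#' @return One-row tibble: `n_traits`, `mean_cv`, `min_cv`, `max_cv`,
#'   `mean_h`, `min_h`, `max_h`.
#' @export
trait_summary_aggregates <- function(summary) {
  tibble::tibble(
    n_traits = nrow(summary),
    mean_cv = mean(summary$cv), min_cv = min(summary$cv),
    max_cv = max(summary$cv),
    mean_h = mean(summary$h), min_h = min(summary$h), max_h = max(summary$h)
  )
}

#' Standardize trait columns to z-scores
#'
#' Centres and scales every trait column to mean 0 and sample SD 1, as done
#' before Euclidean-distance clustering so traits on different scales
#' contribute equally.
#'
#' @param table A trait table.
#' @param traits Trait columns; defaults to `M1`--`M9` present in the table.
#' @return A tibble with `population_id` and z-scored trait columns.
#' @export
standardize_traits <- function(table, traits = NULL) {
  table <- tibble::as_tibble(table)
  if (!"population_id" %in% names(table)) {
    abort_input("standardize_traits: missing column 'population_id'")
  }
  if (is.null(traits)) traits <- intersect(TRAIT_COLS, names(table))
  for (tr in traits) {
    v <- table[[tr]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort_input("standardize_traits: non-numeric or non-finite trait %s", tr)
    }
    if (stats::sd(v) == 0) {
      abort_input("standardize_traits: trait %s is constant", tr)
    }
  }
  dplyr::select(table, "population_id", dplyr::all_of(traits)) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(traits),
                                ~ as.numeric(scale(.x))))
}

#' Ward minimum-variance clustering of standardized traits
#'
#' Agglomerative Ward clustering over Euclidean distances between rows.
#' Merge heights follow the classical Lance-Williams recurrence on squared
#' Euclidean distances. Optionally, heights are affinely rescaled to the
#' 0--25 axis used by SPSS-style dendrograms, on which published cut values
#' (e.g. a "genetic distance" of 15.0) are expressed.
#'
#' @param z A standardized trait tibble (from [standardize_traits()]) or a
#'   numeric matrix with row names.
#' @param rescale Rescale merge heights to the 0--25 axis.
#' @return A `marker_dendrogram`: list with the underlying [stats::hclust]
#'   object (`hclust`), `labels`, `linkage`, `heights`, logical `rescaled`.
#' @export
ward_cluster <- function(z, rescale = FALSE) {
  m <- dendro_input_matrix(z)
  d2 <- stats::dist(m)^2
  hc <- stats::hclust(d2, method = "ward.D")
  new_marker_dendrogram(hc, linkage = "ward", rescale = rescale)
}

#' @noRd
dendro_input_matrix <- function(z) {
  if (is.data.frame(z)) {
    ids <- if ("population_id" %in% names(z)) z$population_id else
      if ("sample_id" %in% names(z)) z$sample_id else
        as.character(seq_len(nrow(z)))
    m <- as.matrix(dplyr::select(z, dplyr::where(is.numeric)))
    rownames(m) <- ids
  } else {
    m <- as.matrix(z)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  }
  if (nrow(m) < 2) abort_input("clustering: need >= 2 rows")
  if (any(!is.finite(m))) abort_input("clustering: non-finite values in input")
  m
}

#' @noRd
new_marker_dendrogram <- function(hc, linkage, rescale = FALSE) {
  heights <- hc$height
  if (rescale) heights <- 25 * heights / max(heights)
  structure(
    list(hclust = hc, labels = hc$labels, linkage = linkage,
         heights = heights, rescaled = rescale),
    class = "marker_dendrogram"
  )
}

#' @export
print.marker_dendrogram <- function(x, ...) {
  cat(sprintf("<marker_dendrogram> %s linkage, %d leaves%s\n", x$linkage,
              length(x$labels), if (x$rescaled) ", heights rescaled to 0-25" else ""))
  invisible(x)
}

#' Cut a dendrogram at a height threshold
#'
#' Groups are the connected components formed by merges strictly below the
#' threshold (on the rescaled axis when the dendrogram was built with
#' rescaling). Labels are consecutive integers numbered by first appearance
#' in input row order, so the assignment is deterministic and reproducible.
#'
#' @param d A `marker_dendrogram`.
#' @param threshold Cut height (>= 0).
#' @param method Method tag recorded on the assignment (e.g. `"MT"`,
#'   `"SCoT"`).
#' @return A `cluster_assignment` tibble with columns `sample_id`, `cluster`;
#'   attributes `method` and `cut`.
#' @export
cut_dendrogram <- function(d, threshold, method = d$linkage) {
  stopifnot(inherits(d, "marker_dendrogram"), threshold >= 0)
  k <- length(d$labels) - sum(d$heights < threshold)
  raw <- stats::cutree(d$hclust, k = k)
  new_cluster_assignment(names(raw), relabel_first_appearance(raw),
                         method = method, cut = threshold)
}

#' @noRd
new_cluster_assignment <- function(sample_id, cluster, method, cut = NA_real_) {
  out <- tibble::tibble(sample_id = as.character(sample_id),
                        cluster = as.integer(cluster))
  attr(out, "method") <- method
  attr(out, "cut") <- cut
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Per-cluster trait profiles
#'
#' Mean of every trait within each cluster plus cluster sizes — the
#' morphological characterisation of each cluster (e.g. "mean plant height
#' 89.1 cm in cluster 1").
#'
#' @param assignment A `cluster_assignment` covering every table row.
#' @param table A trait table.
#' @param traits Trait columns; defaults to `M1`--`M9` present in the table.
#' @return A tibble with `cluster`, `n` and per-trait means.
#' @export
cluster_profiles <- function(assignment, table, traits = NULL) {
  table <- validate_trait_table(table)
  if (is.null(traits)) traits <- intersect(TRAIT_COLS, names(table))
  missing <- setdiff(table$population_id, assignment$sample_id)
  if (length(missing)) {
    abort_input("cluster_profiles: unassigned sample '%s'", missing[[1]])
  }
  dplyr::inner_join(table,
                    dplyr::rename(assignment, population_id = "sample_id"),
                    by = "population_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(traits), mean),
                     .groups = "drop")
}
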