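# Dominant-marker (SCoT-style) 0/1 band analysis: polymorphic-locus
# detection, per-primer summaries with polymorphism information content,
# simple-matching similarity, and UPGMA clustering.

#' Polymorphic loci of a band matrix
#'
#' A band locus is polymorphic when its column contains both presence (1)
#' and absence (0) across samples; loci where every sample shows the same
#' state are monomorphic. Rates are percentages of loci, overall and per
#' primer.
#'
#' @param m A `band_matrix` with >= 2 samples.
#' @return List with `loci` (tibble `locus`, `primer`, `polymorphic`),
#'   `rate` (overall percentage) and `by_primer` (tibble `primer`, `n_bands`,
#'   `n_polymorphic`, `rate`).
#' @export
polymorphic_loci <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  if (nrow(m) < 2) abort_input("polymorphic_loci: need >= 2 samples")
  pm <- primer_map(m)
  loci <- setdiff(names(m), "sample_id")
  poly <- vapply(loci, function(lc) {
    v <- m[[lc]]
    any(v == 0) && any(v == 1)
  }, logical(1))
  tab <- tibble::tibble(locus = loci, polymorphic = unname(poly)) |>
    dplyr::left_join(pm, by = "locus") |>
    dplyr::relocate("primer", .after = "locus")
  by_primer <- tab |>
    dplyr::group_by(.data$primer) |>
    dplyr::summarise(n_bands = dplyr::n(),
                     n_polymorphic = sum(.data$polymorphic),
                     rate = 100 * mean(.data$polymorphic),
                     .groups = "drop")
  list(loci = tab, rate = 100 * mean(poly), by_primer = by_primer)
}

#' Polymorphism information content of a dominant band locus
#'
#' `PIC = 1 - sum(p_i^2)` over allele-class frequencies. A dominant 0/1
#' locus has two observable classes, band presence at frequency `p` and
#' absence at `1 - p`, giving `PIC = 1 - p^2 - (1 - p)^2`, maximal (0.5) at
#' `p = 0.5` and zero for monomorphic loci. Symmetric in `p` and `1 - p`.
#'
#' @param p Band (presence) frequency in \[0, 1\]; vectorized.
#' @return PIC values in \[0, 0.5\].
#' @export
pic_locus <- function(p) {
  if (any(p < 0 | p > 1)) abort_input("pic_locus: frequency outside [0, 1]")
  1 - p^2 - (1 - p)^2
}

#' Per-primer marker summary
#'
#' For each primer: band count, polymorphic band count, mean band (presence)
#' frequency over its loci, and PIC averaged over its polymorphic loci
#' (monomorphic loci have PIC 0 and are excluded by default so they do not
#' dilute the informativeness measure; set `pic_include_monomorphic = TRUE`
#' to average over all loci). A `Mean`/`Total` pair of aggregate rows is
#' appended, mirroring the usual presentation of dominant-marker tables.
#'
#' @param m A `band_matrix`.
#' @param pic_include_monomorphic Average PIC over all loci rather than
#'   polymorphic loci only.
#' @return A tibble with `primer`, `n_bands`, `n_polymorphic`, `mean_freq`,
#'   `pic`; the last two rows are the `Mean` and `Total` aggregates.
#' @export
primer_summary <- function(m, pic_include_monomorphic = FALSE) {
  stopifnot(inherits(m, "band_matrix"))
  pm <- primer_map(m)
  loci <- setdiff(names(m), "sample_id")
  freq <- vapply(loci, function(lc) mean(m[[lc]]), numeric(1))
  poly <- vapply(loci, function(lc) any(m[[lc]] == 0) && any(m[[lc]] == 1),
                 logical(1))
  per_locus <- tibble::tibble(locus = loci, freq = unname(freq),
                              polymorphic = unname(poly),
                              pic = pic_locus(unname(freq))) |>
    dplyr::left_join(pm, by = "locus")

  empty <- setdiff(unique(pm$primer), per_locus$primer)
  if (length(empty)) {
    warning("primer(s) with zero loci omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }

  rows <- per_locus |>
    dplyr::group_by(.data$primer) |>
    dplyr::summarise(
      n_bands = dplyr::n(),
      n_polymorphic = sum(.data$polymorphic),
      mean_freq = mean(.data$freq),
      pic = if (pic_include_monomorphic) mean(.data$pic) else {
        if (any(.data$polymorphic)) mean(.data$pic[.data$polymorphic]) else 0
      },
      .groups = "drop"
    )
  dplyr::bind_rows(
    rows,
    tibble::tibble(primer = "Mean", n_bands = mean(rows$n_bands),
                   n_polymorphic = mean(rows$n_polymorphic),
                   mean_freq = mean(rows$mean_freq), pic = mean(rows$pic)),
    tibble::tibble(primer = "Total", n_bands = sum(rows$n_bands),
                   n_polymorphic = sum(rows$n_polymorphic),
                   mean_freq = NA_real_, pic = NA_real_)
  )
}

#' Aggregates of a per-primer polymorphism summary
#'
#' Headline figures of a dominant-marker screen computed from per-primer
#' counts: total and mean polymorphic loci per primer, the overall
#' polymorphism rate from the band total, the best single-primer rate, and
#' the PIC column range. Accepts partially known band counts (`NA`) as long
#' as the total is given.
#'
#' @param counts Tibble with columns `primer`, `n_polymorphic` and
#'   optionally `n_bands` (possibly `NA`) and `pic`.
#' @param total_bands Total number of scored bands across primers; defaults
#'   to `sum(counts$n_bands)` when fully known.
#' @return One-row tibble: `total_polymorphic`, `mean_polymorphic`,
#'   `total_bands`, `overall_rate`, `best_primer`, `best_primer_rate`,
#'   `max_pic`, `min_pic` (PIC columns `NA` when absent).
#' @export
polymorphism_aggregates <- function(counts, total_bands = sum(counts$n_bands)) {
  per_rate <- if ("n_bands" %in% names(counts)) {
    100 * counts$n_polymorphic / counts$n_bands
  } else rep(NA_real_, nrow(counts))
  best <- if (all(is.na(per_rate))) NA_integer_ else which.max(per_rate)
  tibble::tibble(
    total_polymorphic = sum(counts$n_polymorphic),
    mean_polymorphic = mean(counts$n_polymorphic),
    total_bands = total_bands,
    overall_rate = 100 * sum(counts$n_polymorphic) / total_bands,
    best_primer = if (is.na(best)) NA_character_ else counts$primer[[best]],
    best_primer_rate = if (is.na(best)) NA_real_ else per_rate[[best]],
    max_pic = if ("pic" %in% names(counts)) max(counts$pic) else NA_real_,
    min_pic = if ("pic" %in% names(counts)) min(counts$pic) else NA_real_
  )
}

#' Simple-matching similarity between band profiles
#'
#' `SM(a, b)` is the fraction of loci at which two samples agree, counting
#' both shared presences (1-1) and shared absences (0-0). All scored loci
#' contribute, monomorphic ones included. `1 - SM` is a scaled Hamming
#' distance and satisfies the triangle inequality.
#'
#' @param m A `band_matrix` with >= 2 samples.
#' @return A symmetric similarity matrix in \[0, 1\] with unit diagonal and
#'   attribute `coefficient = "SM"`.
#' @export
sm_similarity <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  if (nrow(m) < 2) abort_input("sm_similarity: need >= 2 samples")
  x <- as.matrix(dplyr::select(m, -"sample_id"))
  rownames(x) <- m$sample_id
  L <- ncol(x)
  # agreements = 1-1 matches + 0-0 matches
  ones <- x %*% t(x)
  zeros <- (1 - x) %*% t(1 - x)
  s <- (ones + zeros) / L
  attr(s, "coefficient") <- "SM"
  s
}

#' UPGMA clustering of band profiles
#'
#' Average-linkage (UPGMA/SAHN) agglomeration on the simple-matching
#' dissimilarity `1 - SM`, producing an ultrametric dendrogram, cut at a
#' dissimilarity threshold into a cluster assignment.
#'
#' @param s A similarity matrix from [sm_similarity()] (or any symmetric
#'   similarity in \[0, 1\]).
#' @param threshold Dissimilarity cut in \[0, 1\].
#' @return List with `dendrogram` (a `marker_dendrogram`) and `assignment`
#'   (a `cluster_assignment` tagged `"SCoT"`).
#' @export
scot_cluster <- function(s, threshold = 0.62) {
  stopifnot(threshold >= 0, threshold <= 1)
  d <- stats::as.dist(1 - s)
  hc <- stats::hclust(d, method = "average")
  dend <- new_marker_dendrogram(hc, linkage = "upgma")
  list(dendrogram = dend,
       assignment = cut_dendrogram(dend, threshold, method = "SCoT"))
}
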