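# Cross-marker concordance: encode each method's clusters as integer labels
# in a shared sample order and correlate the label vectors pairwise.

#' Encode a cluster assignment as an integer vector in a shared order
#'
#' @param assignment A `cluster_assignment` tibble.
#' @param sample_order Character vector fixing the shared sample order; must
#'   match the assignment's sample set exactly.
#' @return Integer label vector aligned to `sample_order`.
#' @export
encode_labels <- function(assignment, sample_order) {
  if (!setequal(assignment$sample_id, sample_order) ||
      length(sample_order) != nrow(assignment)) {
    abort_input("encode_labels: sample sets differ between assignment and shared order")
  }
  as.integer(assignment$cluster[match(sample_order, assignment$sample_id)])
}

#' Pairwise Pearson concordance of cluster labelings
#'
#' Each marker system's cluster assignment is encoded as integers 1..k (by
#' first appearance in the shared sample order) and the label vectors are
#' correlated pairwise (Pearson r; two-sided p from the t distribution on
#' n - 2 degrees of freedom). Because Pearson-on-labels depends on how the
#' cluster ids are numbered, a relabeling-maximized r (exhaustive over label
#' permutations of one member of each pair) is also reported as a robustness
#' diagnostic; it is always >= the raw r. Pairs involving a constant
#' labeling are reported missing.
#'
#' @param assignments Named list of `cluster_assignment` tibbles (e.g.
#'   `list(MT = ..., ITS = ..., SCoT = ...)`).
#' @param sample_order Shared sample order; defaults to the first
#'   assignment's order.
#' @return A `marker_concordance`: list with `methods`, `n`, matrices `r`,
#'   `p`, `r_max`, and the encoded `labels` matrix. `tidy()` gives one row
#'   per method pair.
#' @export
pearson_concordance <- function(assignments, sample_order = NULL) {
  stopifnot(is.list(assignments), length(assignments) >= 2,
            !is.null(names(assignments)))
  if (is.null(sample_order)) sample_order <- assignments[[1]]$sample_id
  n <- length(sample_order)
  if (n < 3) abort_input("pearson_concordance: need n >= 3 samples")
  labels <- vapply(assignments, encode_labels, integer(n),
                   sample_order = sample_order)
  methods <- names(assignments)
  k <- length(methods)
  r <- p <- r_max <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  diag(r) <- diag(r_max) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- cor_with_p(labels[, i], labels[, j])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      r_max[i, j] <- r_max[j, i] <-
        relabel_max_cor(labels[, i], labels[, j])
    }
  }
  structure(list(methods = methods, n = n, r = r, p = p, r_max = r_max,
                 labels = labels),
            class = "marker_concordance")
}

# Maximum Pearson r over all permutations of the second vector's label ids;
# exhaustive, intended for k <= 6 clusters.
#' @noRd
relabel_max_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  ks <- sort(unique(b))
  if (length(ks) > 6) {
    abort_input("relabel diagnostic: more than 6 cluster labels (%d)", length(ks))
  }
  perms <- permutations_of(length(ks))
  best <- -1
  for (row in seq_len(nrow(perms))) {
    relab <- perms[row, ][match(b, ks)]
    best <- max(best, stats::cor(a, relab))
  }
  best
}

#' @noRd
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}

#' @export
print.marker_concordance <- function(x, ...) {
  cat(sprintf("<marker_concordance> %d methods, n = %d\nPearson r:\n",
              length(x$methods), x$n))
  print(round(x$r, 3))
  invisible(x)
}
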