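# Fixture builders and independent oracles used across the suite.

# Tiny in-memory alignment from named sequences.
aln_fixture <- function(..., locus = "ITS", reference_id = NULL) {
  new_locus_alignment(c(...), locus = locus, reference_id = reference_id)
}

# Band matrix from a plain 0/1 matrix; one primer per `per_primer` loci.
band_fixture <- function(x, primers = NULL) {
  n_loci <- ncol(x)
  loci <- sprintf("L%02d", seq_len(n_loci))
  if (is.null(primers)) primers <- rep("P1", n_loci)
  df <- tibble::as_tibble(as.data.frame(x))
  names(df) <- loci
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%02d", seq_len(nrow(x)))), df)
  new_band_matrix(df, tibble::tibble(locus = loci, primer = primers))
}

# Naive SAHN agglomeration via the Lance-Williams recurrence, evaluated
# directly on a full distance matrix; the independent oracle for hclust-based
# Ward (on squared Euclidean distances) and UPGMA dendrograms.
naive_sahn <- function(d, method = c("ward", "average")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1) {
    m <- length(active)
    best <- Inf; bi <- 1; bj <- 2
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (d[i, j] < best - 1e-12) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    ni <- sizes[bi]; nj <- sizes[bj]
    newd <- vapply(seq_len(m), function(k) {
      if (k == bi || k == bj) return(NA_real_)
      nk <- sizes[k]
      if (method == "ward") {
        ((ni + nk) * d[bi, k] + (nj + nk) * d[bj, k] - nk * d[bi, bj]) /
          (ni + nj + nk)
      } else {
        (ni * d[bi, k] + nj * d[bj, k]) / (ni + nj)
      }
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(c(active[[bi]], active[[bj]])))
    sizes <- c(sizes[keep], ni + nj)
    membership <- integer(n)
    for (c_i in seq_along(active)) membership[active[[c_i]]] <- c_i
    partitions[[length(partitions) + 1]] <- membership
  }
  list(heights = heights, partitions = partitions)
}

# Partition of n leaves implied by an hclust after `k`-cluster cut, as
# canonical co-membership for comparison with the naive oracle.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Pairwise co-clustering agreement (Rand index) computed directly.
pair_agreement_oracle <- function(a, b) {
  ut <- upper.tri(diag(length(a)))
  mean(outer(a, a, "==")[ut] == outer(b, b, "==")[ut])
}

# fine refines coarse: each fine class maps into exactly one coarse class.
is_refinement_oracle <- function(fine, coarse) {
  all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
}

# Random unrooted tree with positive branch lengths and its additive
# distance matrix (independent generative oracle for NJ).
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
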