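# Saitou-Nei neighbor-joining with deterministic tie-breaking, plus
# column-resampling bootstrap supports mapped onto the original topology.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration on the Q criterion. Among equally
#' minimal pairs the lexicographically smallest pair of current node indices
#' is chosen, so output is deterministic even on fully tied matrices.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sibling edge, preserving the path length between the joined nodes. The
#' result is exact on additive matrices.
#'
#' @param d Symmetric numeric distance matrix with row/column names
#'   (>= 3 taxa, finite entries).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort_input("nj_tree: need >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (any(is.na(d))) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(ij) {
      paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = "/")
    })
    abort_input("nj_tree: undefined distances for pair(s) %s",
                paste(pairs, collapse = ", "))
  }

  # Each active node carries a Newick fragment; merging wraps two fragments
  # with their branch lengths. The finished string is parsed by ape.
  frag <- rownames(d)
  D <- unname(d)

  clamp_pair <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    c(vi, vj)
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    u <- rowSums(D) / (r - 2)
    Q <- D - outer(u, u, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    # first strict minimum in row-major pair order = lexicographically
    # smallest (i, j) among ties
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
      }
    }
    vi <- 0.5 * D[bi, bj] + 0.5 * (u[bi] - u[bj])
    vj <- D[bi, bj] - vi
    v <- clamp_pair(vi, vj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[bi], v[1], frag[bj], v[2])
    dk <- 0.5 * (D[bi, ] + D[bj, ] - D[bi, bj])
    keep <- setdiff(seq_len(r), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
  }

  va <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  vb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  vc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  for (nm in c("va", "vb", "vc")) {   # clamp with deficit to the next edge
    v <- get(nm)
    if (v < 0) {
      nxt <- c(va = "vb", vb = "vc", vc = "va")[[nm]]
      assign(nxt, get(nxt) + v)
      assign(nm, 0)
    }
  }
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[1], max(va, 0), frag[2], max(vb, 0), frag[3], max(vc, 0))
  ape::read.tree(text = newick)
}

#' Bootstrap supports for a neighbor-joining barcode tree
#'
#' Builds the NJ tree from K2P distances on the original alignment, then
#' resamples alignment columns with replacement `replicates` times, rebuilds
#' the NJ tree per replicate, and annotates each internal edge of the
#' original topology with the percentage of replicates containing the same
#' bipartition. Replicate r draws from a deterministic substream derived
#' from `(seed, r)`, so runs are reproducible and supports do not depend on
#' sample order. Replicates whose resampled distances saturate contribute no
#' bipartitions.
#'
#' @param aln A `locus_alignment` with >= 3 samples.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling streams.
#' @return An [ape::phylo] tree; for >= 4 samples `node.label` holds integer
#'   supports in 0..100, for 3 samples supports are undefined and the tree is
#'   returned unannotated.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1) {
  stopifnot(inherits(aln, "locus_alignment"), replicates >= 1)
  enc <- encode_alignment(aln)
  d <- k2p_matrix_encoded(enc)
  if (any(is.na(d))) abort_input("bootstrap_support: saturated distances in original alignment")
  tree <- nj_tree(d)
  n <- length(aln$sequences)
  if (n < 4) return(tree)

  L <- ncol(enc)
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(as.integer((as.numeric(seed) + 1009 * r) %% 2147483647))
    cols <- sample.int(L, L, replace = TRUE)
    dr <- k2p_matrix_encoded(enc[, cols, drop = FALSE])
    if (any(is.na(dr))) next
    boots[[r]] <- nj_tree(dr)
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(as.integer(round(100 * counts / replicates)))
  tree
}

# Integer base coding (A=1, C=2, G=3, T=4, everything else 0) for fast
# pairwise K2P over many bootstrap replicates.
#' @noRd
encode_alignment <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  enc <- matrix(match(mat, c("A", "C", "G", "T"), nomatch = 0L),
                nrow = nrow(mat))
  rownames(enc) <- names(aln$sequences)
  enc
}

#' @noRd
k2p_matrix_encoded <- function(enc) {
  n <- nrow(enc)
  ids <- rownames(enc)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  purine <- enc == 1L | enc == 3L
  valid <- enc > 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- valid[i, ] & valid[j, ]
      m <- sum(use)
      if (m == 0) abort_input("k2p: no comparable sites for pair %s/%s", ids[i], ids[j])
      diff <- use & (enc[i, ] != enc[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      tv <- sum(diff) - ts
      P <- ts / m; Q <- tv / m
      a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
      d[i, j] <- d[j, i] <- if (a1 <= 0 || a2 <= 0) NA_real_ else
        -0.5 * log(a1) - 0.25 * log(a2)
    }
  }
  d
}
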