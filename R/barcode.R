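# DNA-barcode analysis: variable sites against an optional reference,
# haplotype grouping, Kimura two-parameter distances with explicit
# transition/transversion accounting, and multi-locus concatenation.

#' Variable sites and haplotype groups of a locus alignment
#'
#' A site is variable when at least two distinct unambiguous bases (A/C/G/T)
#' occur among the samples at that position; gaps, N and IUPAC ambiguity
#' codes are excluded from the comparison at that site. The haplotype of a
#' sample is the equivalence class of its full vector of states at the
#' variable sites, numbered 1..k by first appearance. When the alignment
#' carries a reference accession, positions are additionally reported in the
#' reference's ungapped 1-based coordinates.
#'
#' @param aln A `locus_alignment` with >= 2 samples.
#' @return An `snp_profile`: list with `locus`, `sites` (tibble `position`,
#'   optional `ref_position`, `n_states`), `states` (character matrix,
#'   samples x variable sites), and `haplotypes` (tibble `sample_id`,
#'   `haplotype`).
#' @export
variable_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$sequences) < 2) abort_input("variable_sites: need >= 2 samples")
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(mat) <- names(aln$sequences)

  unambiguous <- c("A", "C", "G", "T")
  n_states <- apply(mat, 2, function(col) {
    length(unique(col[col %in% unambiguous]))
  })
  pos <- which(n_states >= 2)

  sites <- tibble::tibble(position = pos, n_states = n_states[pos])
  if (!is.null(aln$reference)) {
    ref <- strsplit(aln$reference, "", fixed = TRUE)[[1]]
    ref_coord <- cumsum(ref != "-")
    sites$ref_position <- ifelse(ref[pos] == "-", NA_integer_, ref_coord[pos])
    sites <- dplyr::relocate(sites, "ref_position", .after = "position")
  }

  states <- mat[, pos, drop = FALSE]
  colnames(states) <- as.character(pos)
  key <- apply(states, 1, paste, collapse = "")
  hap <- relabel_first_appearance(key)

  structure(
    list(locus = aln$locus, sites = sites, states = states,
         haplotypes = tibble::tibble(sample_id = rownames(mat),
                                     haplotype = hap)),
    class = "snp_profile"
  )
}

#' @export
print.snp_profile <- function(x, ...) {
  cat(sprintf("<snp_profile> %s: %d variable site(s), %d haplotype(s) over %d samples\n",
              x$locus, nrow(x$sites), max(x$haplotypes$haplotype),
              nrow(x$haplotypes)))
  invisible(x)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Counts, over the sites where both sequences carry an unambiguous base
#' (pairwise deletion of gaps, N and ambiguity codes), the proportions of
#' transitions P (A<->G, C<->T) and transversions Q, and evaluates
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. When a logarithm argument is
#' non-positive the distance is saturated and returned as `NA` with
#' `saturated = TRUE` rather than clamped.
#'
#' @param a,b Equal-length aligned sequences (character scalars).
#' @return One-row tibble: `distance`, `P`, `Q`, `sites` (compared sites),
#'   `saturated`.
#' @export
k2p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) abort_input("k2p_distance: sequences differ in length")
  unamb <- c("A", "C", "G", "T")
  use <- ca %in% unamb & cb %in% unamb
  n <- sum(use)
  if (n == 0) abort_input("k2p_distance: no comparable sites after pairwise deletion")
  xa <- ca[use]; xb <- cb[use]
  diff <- xa != xb
  transition <- diff & ((xa %in% PURINES) == (xb %in% PURINES))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  tibble::tibble(distance = d, P = P, Q = Q, sites = n, saturated = saturated)
}

#' Pairwise K2P distance matrix for a locus alignment
#'
#' @param aln A `locus_alignment` with >= 2 samples.
#' @return A symmetric numeric matrix with zero diagonal and attributes
#'   `metric = "K2P"` and `saturated` (logical matrix flagging pairs whose
#'   distance is undefined, reported as `NA`).
#' @export
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$sequences) < 2) abort_input("k2p_matrix: need >= 2 samples")
  d <- k2p_matrix_encoded(encode_alignment(aln))
  sat <- is.na(d)
  diag(sat) <- FALSE
  attr(d, "metric") <- "K2P"
  attr(d, "saturated") <- sat
  d
}

#' Concatenate barcode loci into a combined alignment
#'
#' Per-sample concatenation in the given locus order; all loci must cover
#' the identical sample set. Locus boundaries are recorded so positions can
#' be traced back. Combining loci can only refine haplotype groups, never
#' coarsen them.
#'
#' @param alns List of `locus_alignment`s.
#' @return A `locus_alignment` with locus name `"A+B+..."` and an attribute
#'   `boundaries` (tibble `locus`, `start`, `end`, 1-based inclusive).
#' @export
concatenate_barcodes <- function(alns) {
  stopifnot(length(alns) >= 1)
  ids <- names(alns[[1]]$sequences)
  for (a in alns) {
    if (!setequal(names(a$sequences), ids)) {
      diff <- c(setdiff(ids, names(a$sequences)),
                setdiff(names(a$sequences), ids))
      abort_input("concatenate_barcodes: sample set mismatch at locus %s (%s)",
                  a$locus, paste(diff, collapse = ", "))
    }
  }
  seqs <- purrr::map(alns, ~ .x$sequences[ids])
  combined <- purrr::reduce(seqs, ~ paste0(.x, .y))
  names(combined) <- ids
  lens <- vapply(alns, function(a) a$length, numeric(1))
  out <- new_locus_alignment(combined,
                             locus = paste(vapply(alns, `[[`, "", "locus"),
                                           collapse = "+"))
  attr(out, "boundaries") <- tibble::tibble(
    locus = vapply(alns, `[[`, "", "locus"),
    start = cumsum(c(1, utils::head(lens, -1))),
    end = cumsum(lens)
  )
  out
}

#' Haplotype-based cluster assignment for a barcode locus
#'
#' Groups are the haplotype equivalence classes of [variable_sites()],
#' labelled 1..k by first appearance; the invariant-locus case yields a
#' single group. When the alignment holds at least three samples, a
#' neighbor-joining tree on K2P distances is attached for reporting
#' (omitted when any pairwise distance is saturated).
#'
#' @param aln A `locus_alignment`.
#' @return A `cluster_assignment` tibble (`sample_id`, `cluster`) with
#'   attributes `method` (the locus name) and, when computable, `tree`
#'   (an [ape::phylo]).
#' @export
barcode_cluster <- function(aln) {
  prof <- variable_sites(aln)
  out <- new_cluster_assignment(prof$haplotypes$sample_id,
                                prof$haplotypes$haplotype,
                                method = aln$locus)
  if (length(aln$sequences) >= 3) {
    d <- k2p_matrix(aln)
    if (!any(attr(d, "saturated"))) {
      attr(out, "tree") <- nj_tree(d)
    }
  }
  out
}
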