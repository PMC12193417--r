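# Internal helpers shared across modules.

TRAIT_COLS <- paste0("M", 1:9)

# IUPAC nucleotide codes accepted in alignments; '-' marks an alignment gap.
IUPAC_CODES <- c("A", "C", "G", "T", "N", "-",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' @noRd
abort_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

# Deterministic sub-seed for a named component of a larger randomized
# procedure; keeps independent generators on independent streams so adding a
# component never perturbs the draws of an earlier one. Result stays within
# 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  offsets <- c(traits = 11L, barcode = 23L, bands = 37L, resistance = 53L,
               plastid = 71L, reference = 89L, bootstrap = 101L)
  off <- if (is.character(stream)) offsets[[stream]] else as.integer(stream)
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

#' @noRd
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Relabel an integer/character grouping so labels are consecutive integers
# 1..k in order of first appearance.
#' @noRd
relabel_first_appearance <- function(x) {
  as.integer(factor(x, levels = unique(x)))
}

#' Pairwise co-clustering agreement of two partitions
#'
#' Fraction of sample pairs on which two cluster label vectors agree about
#' co-membership (the Rand index). Useful for comparing a recovered
#' clustering with a known ground truth irrespective of label numbering.
#'
#' @param a,b Equal-length cluster label vectors over the same samples.
#' @return Agreement in \[0, 1\]; 1 means identical partitions.
#' @export
pair_agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pa <- outer(a, a, "==")[upper.tri(diag(length(a)))]
  pb <- outer(b, b, "==")[upper.tri(diag(length(b)))]
  mean(pa == pb)
}

#' Does one partition refine another?
#'
#' `TRUE` when every class of the finer partition sits inside a single
#' class of the coarser one — e.g. multi-locus haplotype groups always
#' refine each single-locus grouping.
#'
#' @param fine,coarse Equal-length cluster label vectors.
#' @return A single logical.
#' @export
is_refinement <- function(fine, coarse) {
  all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
}
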