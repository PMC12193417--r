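# Readers and writers for every external representation the pipeline touches:
# trait tables, aligned FASTA, 0/1 band matrices, fresh-weight tables, Newick
# trees and cluster tables. All readers validate strictly; malformed input is
# a typed error, never a silent coercion.

#' Read a population-by-trait table
#'
#' Reads a CSV of per-population quantitative trait means with columns
#' `population_id` and the nine traits `M1`--`M9` (M1 leaf length, M2 leaf
#' width, M3 panicle length, M4 raceme length, M5 awn length, M6 spikelet
#' length, M7 first-glume/spikelet length ratio, M8 main stem diameter,
#' M9 plant height; centimetres except the dimensionless M7). An optional
#' `region` column is carried through. When `replicates = TRUE` the file may
#' contain several rows per population (individual plants); they are averaged
#' into the population mean before validation.
#'
#' @param path Path to a CSV file with a header row.
#' @param replicates If `TRUE`, aggregate replicate rows per population by
#'   their mean before validation.
#' @return A validated tibble with `population_id`, `M1`--`M9` and optionally
#'   `region`; row order preserved.
#' @export
read_trait_table <- function(path, replicates = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (replicates) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("population_id", "region")))) |>
      dplyr::summarise(dplyr::across(dplyr::any_of(TRAIT_COLS), mean),
                       .groups = "drop")
  }
  validate_trait_table(df)
}

#' Validate a trait table
#'
#' Checks the invariants of a population-by-trait table: all nine trait
#' columns present and numeric, no duplicate population ids, all values
#' finite and non-negative, and the glume ratio M7 within (0, 1].
#'
#' @param df A data frame with `population_id` and `M1`--`M9`.
#' @return The table as a tibble, unchanged, if valid.
#' @export
validate_trait_table <- function(df) {
  if (!"population_id" %in% names(df)) {
    abort_input("trait table: missing column 'population_id'")
  }
  missing <- setdiff(TRAIT_COLS, names(df))
  if (length(missing)) {
    abort_input("trait table: missing trait column(s) %s",
                paste(missing, collapse = ", "))
  }
  df$population_id <- as.character(df$population_id)
  dup <- df$population_id[duplicated(df$population_id)]
  if (length(dup)) {
    abort_input("trait table: duplicate population_id '%s'", dup[[1]])
  }
  for (tr in TRAIT_COLS) {
    v <- df[[tr]]
    if (!is.numeric(v)) {
      abort_input("trait table: non-numeric values in column %s", tr)
    }
    if (any(!is.finite(v))) {
      abort_input("trait table: non-finite value in column %s (row %d)",
                  tr, which(!is.finite(v))[[1]])
    }
    if (any(v < 0)) {
      abort_input("trait table: negative value in column %s (row %d)",
                  tr, which(v < 0)[[1]])
    }
  }
  if (any(df$M7 <= 0 | df$M7 > 1)) {
    abort_input("trait table: ratio out of range in column M7 (row %d); must lie in (0, 1]",
                which(df$M7 <= 0 | df$M7 > 1)[[1]])
  }
  tibble::as_tibble(df)
}

#' Read an aligned FASTA file for one barcode locus
#'
#' Reads a (possibly line-wrapped) FASTA file of pre-aligned sequences for a
#' single locus. Sequences are upper-cased; all records, including the
#' optional reference accession, must have identical length and use only
#' IUPAC nucleotide codes plus `-` gaps. The package does not align;
#' alignment is an upstream step.
#'
#' @param path Path to a FASTA file.
#' @param locus Locus name (e.g. `"ITS"`, `"psbA"`).
#' @param reference_id Optional record id to treat as the coordinate
#'   reference (e.g. a GenBank accession); it is excluded from the sample set
#'   but used for reference-coordinate SNP reporting.
#' @return A `locus_alignment` object.
#' @export
read_alignment <- function(path, locus, reference_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort_input("alignment %s: empty FASTA file", path)
  new_locus_alignment(
    sequences = toupper(as.character(seqs)),
    locus = locus,
    reference_id = reference_id
  )
}

#' Construct a locus alignment from named sequences
#'
#' @param sequences Named character vector of equal-length sequences.
#' @param locus Locus name.
#' @param reference_id Optional name of the reference record.
#' @return A `locus_alignment`: list with `sequences` (samples only),
#'   `reference` (named character or `NULL`), `locus` and `length`.
#' @export
new_locus_alignment <- function(sequences, locus, reference_id = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort_input("alignment %s: all records must be named", locus)
  }
  if (anyDuplicated(names(sequences))) {
    abort_input("alignment %s: duplicate record id '%s'", locus,
                names(sequences)[duplicated(names(sequences))][[1]])
  }
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1) {
    abort_input("alignment %s: not aligned; record lengths differ (%s)",
                locus, paste(unique(widths), collapse = ", "))
  }
  bad <- vapply(
    strsplit(sequences, "", fixed = TRUE),
    function(ch) any(!ch %in% IUPAC_CODES), logical(1)
  )
  if (any(bad)) {
    abort_input("alignment %s: illegal character in record '%s'",
                locus, names(sequences)[bad][[1]])
  }
  ref <- NULL
  if (!is.null(reference_id)) {
    if (!reference_id %in% names(sequences)) {
      abort_input("alignment %s: reference id '%s' not present", locus, reference_id)
    }
    ref <- sequences[reference_id]
    sequences <- sequences[setdiff(names(sequences), reference_id)]
  }
  structure(
    list(sequences = sequences, reference = ref, locus = locus,
         length = unique(widths)),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d samples, %d bp%s\n",
              x$locus, length(x$sequences), x$length,
              if (!is.null(x$reference)) {
                sprintf(", reference %s", names(x$reference))
              } else ""))
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70) {
  seqs <- c(aln$reference, aln$sequences)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a sample-by-band 0/1 matrix with its band-to-primer map
#'
#' The band matrix CSV has a `sample_id` column plus one 0/1 column per band
#' locus (dominant scoring: 1 = band present, 0 = absent). The primer map CSV
#' has columns `locus` and `primer` and must cover every band column.
#'
#' @param path Path to the band matrix CSV.
#' @param primer_map Path to the primer map CSV, or a data frame with
#'   columns `locus` and `primer`.
#' @return A `band_matrix`: a tibble (`sample_id` + 0/1 band columns) with
#'   the primer map stored in `attr(, "primer_map")`.
#' @export
read_band_matrix <- function(path, primer_map) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(primer_map)) {
    primer_map <- readr::read_csv(primer_map, show_col_types = FALSE,
                                  progress = FALSE)
  }
  new_band_matrix(df, primer_map)
}

#' Construct and validate a band matrix
#'
#' @param df Data frame with `sample_id` and 0/1 band columns.
#' @param primer_map Data frame with columns `locus` and `primer`.
#' @return A validated `band_matrix` tibble.
#' @export
new_band_matrix <- function(df, primer_map) {
  if (!"sample_id" %in% names(df)) {
    abort_input("band matrix: missing column 'sample_id'")
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort_input("band matrix: duplicate sample_id '%s'",
                df$sample_id[duplicated(df$sample_id)][[1]])
  }
  loci <- setdiff(names(df), "sample_id")
  if (!length(loci)) abort_input("band matrix: no band columns")
  for (lc in loci) {
    v <- df[[lc]]
    if (!all(is_wholenumber(v) & v %in% c(0, 1))) {
      abort_input("band matrix: cell value outside {0, 1} in locus %s", lc)
    }
    df[[lc]] <- as.integer(v)
  }
  if (!all(c("locus", "primer") %in% names(primer_map))) {
    abort_input("primer map: needs columns 'locus' and 'primer'")
  }
  primer_map <- tibble::as_tibble(primer_map)
  primer_map$locus <- as.character(primer_map$locus)
  primer_map$primer <- as.character(primer_map$primer)
  if (anyDuplicated(primer_map$locus)) {
    abort_input("primer map: locus '%s' mapped more than once",
                primer_map$locus[duplicated(primer_map$locus)][[1]])
  }
  unmapped <- setdiff(loci, primer_map$locus)
  if (length(unmapped)) {
    abort_input("band matrix: locus '%s' absent from primer map", unmapped[[1]])
  }
  out <- tibble::as_tibble(df)
  attr(out, "primer_map") <- primer_map[primer_map$locus %in% loci, ]
  class(out) <- c("band_matrix", class(out))
  out
}

#' Band-to-primer map of a band matrix
#'
#' @param m A `band_matrix`.
#' @return A tibble with columns `locus` and `primer`.
#' @export
primer_map <- function(m) attr(m, "primer_map")

#' Read a herbicide fresh-weight / inhibition table
#'
#' Long-format CSV with columns `population_id`, `herbicide` and either the
#' pair `treated_fw`, `control_fw` (grams of above-ground fresh weight under
#' treatment and in the untreated control) or a precomputed `inhibition`
#' percentage in \[0, 100\].
#'
#' @param path Path to the CSV file.
#' @return A validated tibble; when fresh weights are given, an `inhibition`
#'   column is added via [inhibition_rate()].
#' @export
read_resistance_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("population_id", "herbicide") %in% names(df))) {
    abort_input("resistance table: needs columns 'population_id' and 'herbicide'")
  }
  df$population_id <- as.character(df$population_id)
  if (all(c("treated_fw", "control_fw") %in% names(df))) {
    df$inhibition <- inhibition_rate(df$treated_fw, df$control_fw)
  } else if (!"inhibition" %in% names(df)) {
    abort_input("resistance table: needs 'treated_fw'+'control_fw' or 'inhibition'")
  }
  if (any(!is.finite(df$inhibition) | df$inhibition < 0 | df$inhibition > 100)) {
    abort_input("resistance table: inhibition outside [0, 100]")
  }
  tibble::as_tibble(df)
}

#' Write a tree to a Newick file
#'
#' Emits standard Newick with branch lengths and, when present, integer
#' bootstrap supports as internal-node labels. Leaf names containing Newick
#' metacharacters are single-quoted.
#'
#' @param tree An [ape::phylo] tree with tip labels and edge lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label))) {
    abort_input("write_newick: every leaf must be named")
  }
  # labels with Newick metacharacters are written single-quoted; placeholders
  # shield them from the writer's own label sanitation
  meta <- which(grepl("[][(),;:'\"[:space:]]", tree$tip.label))
  quoted <- paste0("'", gsub("'", "''", tree$tip.label[meta]), "'")
  placeholder <- sprintf("EDVQUOTELBL%03d", seq_along(meta))
  tree$tip.label[meta] <- placeholder
  txt <- ape::write.tree(tree)
  for (i in seq_along(meta)) {
    txt <- sub(placeholder[i], quoted[i], txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree; internal-node labels (bootstrap supports)
#'   are preserved in `node.label`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a cluster assignment to CSV
#'
#' @param assignment A tibble with `sample_id` and `cluster` (as produced by
#'   [cut_dendrogram()] or [barcode_cluster()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  readr::write_csv(assignment, path)
  invisible(path)
}
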