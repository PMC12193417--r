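# End-to-end orchestration: traits -> resistance -> barcodes (per locus +
# combined) -> SCoT -> cross-marker concordance, with per-stage logging and
# optional CSV/Newick export.

#' Run the full multi-marker diversity analysis
#'
#' Executes every stage of the pipeline on a coherent set of inputs and
#' returns a self-describing report. Inputs may be file paths (CSV/FASTA,
#' see the `read_*` readers) or objects already in memory; a simulated study
#' from [simulate_study()] can be passed directly via `study`. Stages can be
#' skipped; each stage logs one line with its parameters, and results of
#' completed stages are kept even when a later stage is skipped.
#'
#' @param study Optional [simulate_study()] result supplying all inputs.
#' @param traits Trait table (tibble or CSV path).
#' @param alignments Named list of `locus_alignment`s (or FASTA paths; names
#'   are locus names).
#' @param bands A `band_matrix`, or CSV path (then `band_primer_map` must be
#'   given).
#' @param band_primer_map Primer map (tibble or CSV path) when `bands` is a
#'   path.
#' @param resistance Fresh-weight/inhibition tibble or CSV path.
#' @param trait_cut Cut height for the trait dendrogram (on the 0--25
#'   rescaled axis when `trait_rescale = TRUE`; the published analysis cuts
#'   at 15.0).
#' @param trait_rescale Rescale Ward heights to the 0--25 axis.
#' @param scot_cut Simple-matching dissimilarity cut (published analysis:
#'   0.62; synthetic default geometry: 0.30).
#' @param combine Loci to concatenate for the combined barcode stage.
#' @param bootstrap Bootstrap replicates for the primary barcode tree
#'   (0 = off; the published analysis used 1000).
#' @param primary_locus Locus used for barcode concordance and bootstrap.
#' @param soa_map Herbicide-to-SOA map.
#' @param resistance_measure `"soa"` or `"herbicide"` multi-resistance count.
#' @param pic_include_monomorphic Passed to [primer_summary()].
#' @param skip Character vector of stages to skip, among
#'   `c("traits", "resistance", "barcode", "scot", "concordance")`.
#' @param seed Seed for the bootstrap stage.
#' @param out_dir Optional output directory for CSV/Newick exports.
#' @return A `diversity_report`: list with the per-stage results
#'   (`trait_diversity`, `trait_dendrogram`, `trait_assignment`,
#'   `cluster_profiles`, `resistance_profile`, `multi_resistance`,
#'   `trait_resistance`, `snp_profiles`, `barcode_assignments`,
#'   `combined_assignment`, `k2p`, `tree`, `primer_summary`, `sm`,
#'   `scot_dendrogram`, `scot_assignment`, `concordance`), a `summary`
#'   tibble of per-method group counts, and the resolved `config`.
#' @export
run_study <- function(study = NULL,
                      traits = study$traits,
                      alignments = study$alignments,
                      bands = study$bands,
                      band_primer_map = NULL,
                      resistance = study$resistance,
                      trait_cut = 15, trait_rescale = TRUE,
                      scot_cut = 0.62,
                      combine = c("ITS", "psbA"),
                      bootstrap = 0,
                      primary_locus = "ITS",
                      soa_map = default_soa_map(),
                      resistance_measure = "soa",
                      pic_include_monomorphic = FALSE,
                      skip = character(),
                      seed = 1,
                      out_dir = NULL) {
  stages <- c("traits", "resistance", "barcode", "scot", "concordance")
  bad <- setdiff(skip, stages)
  if (length(bad)) abort_input("run_study: unknown stage '%s' in skip", bad[[1]])
  run <- setdiff(stages, skip)
  report <- list(config = list(
    trait_cut = trait_cut, trait_rescale = trait_rescale, scot_cut = scot_cut,
    combine = combine, bootstrap = bootstrap, primary_locus = primary_locus,
    resistance_measure = resistance_measure,
    pic_include_monomorphic = pic_include_monomorphic, seed = seed,
    stages = run
  ))

  if (is.character(traits)) traits <- read_trait_table(traits)
  if (!is.null(alignments)) {
    alignments <- purrr::imap(alignments, function(a, nm) {
      if (is.character(a)) read_alignment(a, locus = nm) else a
    })
  }
  if (is.character(bands)) bands <- read_band_matrix(bands, band_primer_map)
  if (is.character(resistance)) resistance <- read_resistance_table(resistance)

  check_shared_samples(traits, alignments, bands, resistance, run)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("traits" %in% run) {
    message(sprintf("stage traits: %d populations, cut %.2f (rescale %s)",
                    nrow(traits), trait_cut, trait_rescale))
    report$trait_diversity <- diversity_table(traits)
    z <- standardize_traits(traits)
    report$trait_dendrogram <- ward_cluster(z, rescale = trait_rescale)
    report$trait_assignment <- cut_dendrogram(report$trait_dendrogram,
                                              trait_cut, method = "MT")
    report$cluster_profiles <- cluster_profiles(report$trait_assignment, traits)
    if (!is.null(out_dir)) {
      readr::write_csv(report$trait_diversity$summary,
                       file.path(out_dir, "trait_summary.csv"))
      readr::write_csv(tidy(report$trait_dendrogram),
                       file.path(out_dir, "trait_merges.csv"))
      write_assignment(report$trait_assignment,
                       file.path(out_dir, "trait_assignment.csv"))
      readr::write_csv(report$cluster_profiles,
                       file.path(out_dir, "cluster_profiles.csv"))
    }
  }

  if ("resistance" %in% run && !is.null(resistance)) {
    message(sprintf("stage resistance: %d records, threshold 78%%",
                    nrow(resistance)))
    report$resistance_profile <- resistance_profile(resistance)
    report$multi_resistance <- multi_resistance(report$resistance_profile,
                                                soa_map)
    report$trait_resistance <- trait_resistance_correlation(
      traits, report$multi_resistance, measure = resistance_measure)
    if (!is.null(out_dir)) {
      readr::write_csv(report$multi_resistance,
                       file.path(out_dir, "multi_resistance.csv"))
      readr::write_csv(report$trait_resistance,
                       file.path(out_dir, "trait_resistance.csv"))
    }
  }

  if ("barcode" %in% run && !is.null(alignments)) {
    message(sprintf("stage barcode: loci %s; combine %s; bootstrap %d",
                    paste(names(alignments), collapse = "/"),
                    paste(combine, collapse = "+"), bootstrap))
    report$snp_profiles <- purrr::map(alignments, variable_sites)
    report$barcode_assignments <- purrr::map(alignments, barcode_cluster)
    if (length(combine) >= 2 && all(combine %in% names(alignments))) {
      comb <- concatenate_barcodes(alignments[combine])
      report$combined_assignment <- barcode_cluster(comb)
    }
    aln <- alignments[[primary_locus]]
    report$k2p <- k2p_matrix(aln)
    report$tree <- if (bootstrap > 0) {
      bootstrap_support(aln, replicates = bootstrap, seed = seed)
    } else attr(report$barcode_assignments[[primary_locus]], "tree")
    if (!is.null(out_dir)) {
      for (nm in names(report$snp_profiles)) {
        readr::write_csv(report$snp_profiles[[nm]]$sites,
                         file.path(out_dir, sprintf("snp_sites_%s.csv",
                                                    gsub("[^A-Za-z0-9]", "_", nm))))
      }
      write_assignment(report$barcode_assignments[[primary_locus]],
                       file.path(out_dir, "barcode_assignment.csv"))
      utils::write.csv(report$k2p, file.path(out_dir, "k2p_matrix.csv"))
      if (!is.null(report$tree)) {
        write_newick(report$tree, file.path(out_dir, "barcode_tree.nwk"))
      }
    }
  }

  if ("scot" %in% run && !is.null(bands)) {
    message(sprintf("stage scot: %d samples x %d bands, cut %.2f",
                    nrow(bands), ncol(bands) - 1, scot_cut))
    report$primer_summary <- primer_summary(
      bands, pic_include_monomorphic = pic_include_monomorphic)
    report$polymorphism <- polymorphic_loci(bands)
    report$sm <- sm_similarity(bands)
    sc <- scot_cluster(report$sm, threshold = scot_cut)
    report$scot_dendrogram <- sc$dendrogram
    report$scot_assignment <- sc$assignment
    if (!is.null(out_dir)) {
      readr::write_csv(report$primer_summary,
                       file.path(out_dir, "primer_summary.csv"))
      utils::write.csv(report$sm, file.path(out_dir, "sm_matrix.csv"))
      readr::write_csv(tidy(report$scot_dendrogram),
                       file.path(out_dir, "scot_merges.csv"))
      write_assignment(report$scot_assignment,
                       file.path(out_dir, "scot_assignment.csv"))
    }
  }

  if ("concordance" %in% run) {
    methods <- list()
    if (!is.null(report$trait_assignment)) methods$MT <- report$trait_assignment
    if (!is.null(report$barcode_assignments)) {
      methods[[primary_locus]] <- report$barcode_assignments[[primary_locus]]
    }
    if (!is.null(report$scot_assignment)) methods$SCoT <- report$scot_assignment
    if (length(methods) >= 2) {
      message(sprintf("stage concordance: methods %s",
                      paste(names(methods), collapse = ", ")))
      report$concordance <- pearson_concordance(methods,
                                                sample_order = traits$population_id)
      if (!is.null(out_dir)) {
        readr::write_csv(tidy(report$concordance),
                         file.path(out_dir, "concordance.csv"))
      }
    }
  }

  report$summary <- report_summary(report)
  if (!is.null(out_dir)) {
    readr::write_csv(report$summary, file.path(out_dir, "summary.csv"))
    yaml::write_yaml(report$config, file.path(out_dir, "run_config.yaml"))
  }
  class(report) <- "diversity_report"
  report
}

#' @noRd
check_shared_samples <- function(traits, alignments, bands, resistance, run) {
  base_ids <- traits$population_id
  check <- function(ids, what) {
    if (!setequal(ids, base_ids)) {
      diff <- c(setdiff(base_ids, ids), setdiff(ids, base_ids))
      abort_input("run_study: sample ids of %s differ from trait table (%s)",
                  what, paste(diff, collapse = ", "))
    }
  }
  if ("barcode" %in% run && !is.null(alignments)) {
    for (nm in names(alignments)) {
      check(names(alignments[[nm]]$sequences), paste("locus", nm))
    }
  }
  if ("scot" %in% run && !is.null(bands)) check(bands$sample_id, "band matrix")
  if ("resistance" %in% run && !is.null(resistance)) {
    check(unique(resistance$population_id), "resistance table")
  }
  invisible(TRUE)
}

#' @noRd
report_summary <- function(report) {
  rows <- list()
  add <- function(method, assignment) {
    if (is.null(assignment)) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      method = method, n_samples = nrow(assignment),
      n_groups = max(assignment$cluster),
      cut = attr(assignment, "cut") %||% NA_real_)
  }
  add("MT", report$trait_assignment)
  for (nm in names(report$barcode_assignments)) {
    add(nm, report$barcode_assignments[[nm]])
  }
  if (!is.null(report$combined_assignment)) {
    add(attr(report$combined_assignment, "method"), report$combined_assignment)
  }
  add("SCoT", report$scot_assignment)
  if (!length(rows)) return(tibble::tibble())
  purrr::list_rbind(rows)
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report>\n")
  print(x$summary)
  invisible(x)
}
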