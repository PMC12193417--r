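# Synthetic-study generator: complete multi-marker studies (trait table,
# per-locus alignments, band matrix, fresh-weight table) with known ground
# truth, so every pipeline stage is testable without field data.

#' Default paper-like simulation configuration
#'
#' One place holding the study conditions the generator emulates: 46
#' populations in 5 groups (sizes 12/13/9/3/9, an unbalanced field
#' collection); barcode loci ITS (588 bp, 5 nuclear haplotypes), psbA
#' (337 bp, 2 plastid haplotypes), matK (1312 bp, 2 plastid haplotypes) and
#' the invariant trnL-F (954 bp); plastid haplotypes cross the nuclear
#' groups so the ITS+psbA combination yields 7 haplotype classes; 72 band
#' loci over 6 SCoT primers (62 polymorphic) with symmetric flip noise
#' 0.02; and multi-resistance counts coupled to leaf length (M1) and
#' spikelet length (M6) through a binomial-logistic link.
#'
#' Trait archetypes are anchored on the published cluster descriptions
#' (e.g. mean plant height 89.13 cm and leaf length 39.0 cm in group 1,
#' 26.59 cm leaves in group 2, 0.66 cm stems in group 3, 0.81 cm awns in
#' group 4, 43.35 cm height in group 5); within-group spreads are set so
#' the pooled per-trait dispersion matches the published trait table and
#' non-awn marginals stay normal. Awnless groups are truncated at zero, so
#' awn length is zero-inflated and non-normal, as observed in the field
#' data.
#'
#' @param seed Master seed stored in the config.
#' @return A `sim_config` list; see [simulate_study()].
#' @export
paper_like_config <- function(seed = 1) {
  trait_means <- rbind(
    c(39.0, 1.30, 11.0, 3.5, 0.00, 0.39, 0.45, 0.50, 89.13),
    c(26.6, 0.95,  8.5, 2.5, 0.05, 0.32, 0.40, 0.38, 62.0),
    c(30.0, 0.90,  9.5, 3.0, 0.50, 0.37, 0.42, 0.55, 70.0),
    c(33.0, 0.95, 10.0, 3.0, 0.81, 0.36, 0.44, 0.40, 85.0),
    c(22.0, 0.70,  7.0, 2.2, 0.00, 0.30, 0.36, 0.33, 43.35)
  )
  colnames(trait_means) <- TRAIT_COLS
  cfg <- list(
    group_sizes = c(12L, 13L, 9L, 3L, 9L),
    trait_means = trait_means,
    trait_sds = stats::setNames(
      c(3.5, 0.20, 1.0, 0.35, 0.06, 0.03, 0.03, 0.10, 8.0), TRAIT_COLS),
    trait_sd_scale = 1,
    loci = list(
      ITS     = list(length = 588L,  driver = "nuclear", n_haplotypes = 5L,
                     n_sites = 5L),
      psbA    = list(length = 337L,  driver = "plastid", n_haplotypes = 2L,
                     n_sites = 2L),
      matK    = list(length = 1312L, driver = "plastid", n_haplotypes = 2L,
                     n_sites = 1L),
      `trnL-F` = list(length = 954L, driver = "none", n_haplotypes = 1L,
                      n_sites = 0L)
    ),
    # plastid haplotype 2 occurs only inside nuclear groups 4 and 5, so the
    # ITS x psbA cross realises exactly 7 combined haplotypes
    plastid_split_groups = c(4L, 5L),
    band_counts = stats::setNames(
      c(12L, 13L, 9L, 15L, 12L, 11L),
      c("SCoT06", "SCoT11", "SCoT12", "SCoT20", "SCoT29", "SCoT31")),
    n_monomorphic_bands = 10L,
    band_flip = 0.02,
    soa_map = default_soa_map(),
    resistance_coupling = 1.5,
    resistance_intercept = 0,
    coupled_traits = c("M1", "M6"),
    seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  if (any(cfg$group_sizes < 1)) abort_input("sim config: group sizes must be >= 1")
  if (nrow(cfg$trait_means) != length(cfg$group_sizes)) {
    abort_input("sim config: one archetype row per group required")
  }
  if (any(cfg$trait_sds <= 0) || cfg$trait_sd_scale <= 0) {
    abort_input("sim config: trait SDs must be > 0")
  }
  if (cfg$band_flip < 0 || cfg$band_flip >= 0.5) {
    abort_input("sim config: band flip probability must lie in [0, 0.5)")
  }
  for (nm in names(cfg$loci)) {
    lc <- cfg$loci[[nm]]
    if (lc$n_sites > lc$length) {
      abort_input("sim config: locus %s has more variable sites than length", nm)
    }
    if (lc$n_haplotypes > 1 && lc$n_sites < lc$n_haplotypes - 1) {
      abort_input("sim config: locus %s needs >= %d variable sites for %d haplotypes",
                  nm, lc$n_haplotypes - 1, lc$n_haplotypes)
    }
  }
  if (cfg$n_monomorphic_bands >= sum(cfg$band_counts)) {
    abort_input("sim config: all bands monomorphic")
  }
  invisible(cfg)
}

#' Simulate a complete multi-marker diversity study
#'
#' Draws a full study from a [paper_like_config()]-style configuration:
#' per-population trait values from the group archetype normals (truncated
#' to valid ranges); barcode sequences as a random reference carrying
#' planted group-specific substitutions, identical within a group; band
#' profiles as group profiles XOR symmetric Bernoulli flip noise; and
#' multi-resistance as a binomial count whose logit is linear in the
#' configured (z-scored) traits, translated into per-herbicide fresh
#' weights. Each component draws from its own seed-derived substream, so
#' output is byte-reproducible and adding a component never perturbs the
#' others.
#'
#' @param cfg A `sim_config` (see [paper_like_config()]).
#' @param seed Master seed; defaults to `cfg$seed`.
#' @param out_dir Optional directory; when given, all input files
#'   (`traits.csv`, `<locus>.fasta`, `bands.csv`, `primer_map.csv`,
#'   `resistance.csv`) plus `truth.csv` and the resolved `config.yaml` are
#'   written there.
#' @return List with `traits` (trait tibble), `alignments` (named list of
#'   `locus_alignment`s, each carrying its synthetic reference accession),
#'   `bands` (a `band_matrix`), `resistance` (long fresh-weight tibble),
#'   `truth` (tibble `population_id`, `group`, `plastid_group`,
#'   `combined_haplotype`, planted band profile row index), `planted_sites`
#'   (per-locus variable positions) and the resolved `config`.
#' @export
simulate_study <- function(cfg = paper_like_config(), seed = cfg$seed,
                           out_dir = NULL) {
  validate_sim_config(cfg)
  G <- length(cfg$group_sizes)
  n <- sum(cfg$group_sizes)
  group <- rep(seq_len(G), cfg$group_sizes)
  ids <- sprintf("P%02d", seq_len(n))

  # plastid haplotype: 2 only within the designated nuclear groups (split
  # deterministically inside each), crossing the nuclear grouping
  plastid <- rep(1L, n)
  for (g in cfg$plastid_split_groups) {
    idx <- which(group == g)
    first2 <- ceiling(length(idx) / 2) + 1
    if (first2 <= length(idx)) plastid[idx[first2:length(idx)]] <- 2L
  }

  ## traits ------------------------------------------------------------
  set.seed(derive_seed(seed, "traits"))
  sds <- cfg$trait_sds * cfg$trait_sd_scale
  traits <- tibble::as_tibble(
    stats::setNames(lapply(TRAIT_COLS, function(tr) {
      v <- stats::rnorm(n, cfg$trait_means[group, tr], sds[[tr]])
      v <- pmax(v, 0)
      if (tr == "M7") v <- pmin(pmax(v, 0.01), 1)
      v
    }), TRAIT_COLS)
  )
  traits <- dplyr::bind_cols(tibble::tibble(population_id = ids), traits)

  ## barcodes -----------------------------------------------------------
  set.seed(derive_seed(seed, "reference"))
  alignments <- list()
  planted_sites <- list()
  for (nm in names(cfg$loci)) {
    lc <- cfg$loci[[nm]]
    ref <- sample(c("A", "C", "G", "T"), lc$length, replace = TRUE)
    sites <- if (lc$n_sites > 0) sort(sample.int(lc$length, lc$n_sites)) else integer()
    planted_sites[[nm]] <- sites
    hap_seqs <- planted_haplotypes(ref, sites, lc$n_haplotypes)
    hap_of <- switch(lc$driver,
                     nuclear = group,
                     plastid = plastid,
                     none = rep(1L, n))
    seqs <- hap_seqs[hap_of]
    names(seqs) <- ids
    ref_id <- paste0("REF_", nm)
    all_seqs <- c(stats::setNames(paste(ref, collapse = ""), ref_id), seqs)
    alignments[[nm]] <- new_locus_alignment(all_seqs, locus = nm,
                                            reference_id = ref_id)
  }

  ## bands --------------------------------------------------------------
  set.seed(derive_seed(seed, "bands"))
  n_bands <- sum(cfg$band_counts)
  n_poly <- n_bands - cfg$n_monomorphic_bands
  profiles <- matrix(1L, G, n_bands)
  for (b in seq_len(n_poly)) {     # leading loci polymorphic, trailing all-1
    col <- stats::rbinom(G, 1, 0.5)
    while (length(unique(col)) == 1) col <- stats::rbinom(G, 1, 0.5)
    profiles[, b] <- col
  }
  # scoring noise afflicts the variable (faint) bands; invariant strong
  # bands are scored unambiguously, keeping the observed polymorphism rate
  # at the planted 62/72 condition
  flips <- matrix(0L, n, n_bands)
  flips[, seq_len(n_poly)] <- stats::rbinom(n * n_poly, 1, cfg$band_flip)
  bands <- (profiles[group, , drop = FALSE] + flips) %% 2L
  locus_names <- unlist(lapply(names(cfg$band_counts), function(p) {
    sprintf("%s_b%02d", p, seq_len(cfg$band_counts[[p]]))
  }))
  pm <- tibble::tibble(locus = locus_names,
                       primer = rep(names(cfg$band_counts), cfg$band_counts))
  # assign polymorphic/monomorphic columns across primers in index order
  band_df <- tibble::as_tibble(as.data.frame(bands))
  names(band_df) <- locus_names
  band_df <- dplyr::bind_cols(tibble::tibble(sample_id = ids), band_df)
  bands_m <- new_band_matrix(band_df, pm)

  ## resistance ---------------------------------------------------------
  set.seed(derive_seed(seed, "resistance"))
  zc <- rowMeans(scale(as.matrix(traits[, cfg$coupled_traits, drop = FALSE])))
  n_soa <- dplyr::n_distinct(cfg$soa_map$soa)
  p_res <- stats::plogis(cfg$resistance_intercept + cfg$resistance_coupling * zc)
  soa_count <- stats::rbinom(n, n_soa, p_res)
  soa_classes <- unique(cfg$soa_map$soa)
  resistance <- purrr::map(seq_len(n), function(i) {
    res_classes <- if (soa_count[i] > 0) {
      sample(soa_classes, soa_count[i])
    } else character()
    herb <- cfg$soa_map
    resistant <- herb$soa %in% res_classes
    inh <- ifelse(resistant, stats::runif(nrow(herb), 20, 70),
                  stats::runif(nrow(herb), 85, 100))
    control <- stats::runif(nrow(herb), 8, 12)
    tibble::tibble(population_id = ids[i], herbicide = herb$herbicide,
                   control_fw = round(control, 4),
                   treated_fw = round(control * (1 - inh / 100), 4))
  }) |> purrr::list_rbind()
  resistance$inhibition <- inhibition_rate(resistance$treated_fw,
                                           resistance$control_fw)

  combined <- relabel_first_appearance(paste(group, plastid))
  truth <- tibble::tibble(population_id = ids, group = group,
                          plastid_group = plastid,
                          combined_haplotype = combined,
                          soa_count = soa_count)

  out <- list(traits = traits, alignments = alignments, bands = bands_m,
              resistance = resistance, truth = truth,
              planted_sites = planted_sites, config = cfg, seed = seed)

  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Haplotype sequences from a reference and planted site list: haplotype 1 is
# the reference; haplotypes 2..k-1 each substitute one site; the last
# haplotype substitutes all remaining sites, so every planted site varies.
# Substitutions are transitions of the reference base (deterministic).
#' @noRd
planted_haplotypes <- function(ref, sites, k) {
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  subs_at <- function(positions) {
    s <- ref
    s[positions] <- transit[s[positions]]
    paste(s, collapse = "")
  }
  if (k == 1) return(subs_at(integer()))
  assigned <- lapply(seq_len(k - 1), function(h) {
    if (h < k - 1) sites[h] else sites[(k - 1):length(sites)]
  })
  c(subs_at(integer()), vapply(assigned, subs_at, character(1)))
}

#' Write a simulated study to disk
#'
#' @param study Output of [simulate_study()].
#' @param out_dir Directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$traits, file.path(out_dir, "traits.csv"))
  for (nm in names(study$alignments)) {
    write_alignment(study$alignments[[nm]],
                    file.path(out_dir, paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                              ".fasta")))
  }
  readr::write_csv(tibble::as_tibble(study$bands),
                   file.path(out_dir, "bands.csv"))
  readr::write_csv(primer_map(study$bands),
                   file.path(out_dir, "primer_map.csv"))
  readr::write_csv(study$resistance, file.path(out_dir, "resistance.csv"))
  readr::write_csv(study$truth, file.path(out_dir, "truth.csv"))
  cfg <- study$config
  cfg$trait_means <- apply(cfg$trait_means, 1, as.list)
  cfg$soa_map <- as.list(stats::setNames(cfg$soa_map$soa, cfg$soa_map$herbicide))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
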