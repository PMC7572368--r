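#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic genome / time-course / promoter /
#' annotation generators, with defaults mirroring the azalea study design:
#' 13 chromosomes, a five-stage corolla time course with five replicates,
#' eight time-order levels, and the signed co-expression cutoffs 0.81 / -0.57.
#'
#' The planted regulatory cascade uses phase-shifted cosine profiles on the
#' log2(TPM+1) scale: level `l` has phase `(l-1) * phase_step_deg` along one
#' full expression cycle across the stages, so that the Pearson correlation
#' between mean profiles of levels `l` and `m` is exactly
#' `cos((l - m) * phase_step_deg)`. With the default 26 degree step, adjacent
#' levels correlate at 0.899 (above the 0.81 positive cutoff) and levels two
#' apart at 0.616 (safely below it), which is what makes breadth-first level
#' assignment recover the planted ordering.
#'
#' @param seed integer RNG seed; every generator is a pure function of the
#'   config, so a fixed seed yields byte-identical outputs.
#' @param n_chromosomes number of chromosomes (default 13).
#' @param genes_per_chromosome genes per chromosome (default 60).
#' @param n_stages number of developmental stages T1..Tn (default 5).
#' @param n_replicates replicates per stage (default 5).
#' @param n_levels number of planted time-order levels L1..Ln (default 8).
#' @param pos_cutoff,neg_cutoff signed Pearson edge cutoffs
#'   (defaults 0.81 and -0.57).
#' @param noise_sd Gaussian noise sd on the log2(TPM+1) scale (default 0.4).
#' @param dup_mode_fractions named fractions of catalog genes planted per
#'   duplication mode (WGD, TD, PD, TRD, DSD); may sum to less than 1
#'   (the remainder stays singleton).
#' @param ks_peaks list of `c(location, weight, spread)` triples describing a
#'   truncated-Gaussian mixture of synonymous distances; the default single
#'   component at 0.65 mirrors the paralog Ks peak of the azalea lineage WGD.
#' @param motif_length width of generated PWMs (default 15 bp; wide enough
#'   that an exact-consensus match in 2 kb of random sequence is essentially
#'   impossible by chance).
#' @param tfs_per_level planted TFs per level (default 16).
#' @param targets_per_level planted enzyme targets per level (default 10).
#' @param n_background_tfs TFs with no planted cascade role (default 24).
#' @param amplitude_log2 cosine amplitude on log2(TPM+1) (default 2.5, i.e.
#'   about a 32-fold swing between peak and trough).
#' @param baseline_log2 baseline log2(TPM+1) of cascade genes (default 6).
#' @param phase_step_deg phase increment per level in degrees (default 26).
#' @param low_expr_fraction fraction of background genes given mean TPM
#'   below 0.5 to exercise the expression filter (default 0.1).
#' @param repressed_fraction fraction of planted targets whose direct link is
#'   repression (sign-flipped profile; default 0.1).
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 13L,
                             genes_per_chromosome = 60L,
                             n_stages = 5L,
                             n_replicates = 5L,
                             n_levels = 8L,
                             pos_cutoff = 0.81,
                             neg_cutoff = -0.57,
                             noise_sd = 0.4,
                             dup_mode_fractions = c(WGD = 0.10, TD = 0.05,
                                                    PD = 0.05, TRD = 0.05,
                                                    DSD = 0.08),
                             ks_peaks = list(c(location = 0.65, weight = 1,
                                               spread = 0.1)),
                             motif_length = 15L,
                             tfs_per_level = 16L,
                             targets_per_level = 10L,
                             n_background_tfs = 24L,
                             amplitude_log2 = 2.5,
                             baseline_log2 = 6,
                             phase_step_deg = 26,
                             low_expr_fraction = 0.1,
                             repressed_fraction = 0.1) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              n_levels = as.integer(n_levels),
              pos_cutoff = pos_cutoff, neg_cutoff = neg_cutoff,
              noise_sd = noise_sd,
              dup_mode_fractions = dup_mode_fractions,
              ks_peaks = ks_peaks,
              motif_length = as.integer(motif_length),
              tfs_per_level = as.integer(tfs_per_level),
              targets_per_level = as.integer(targets_per_level),
              n_background_tfs = as.integer(n_background_tfs),
              amplitude_log2 = amplitude_log2,
              baseline_log2 = baseline_log2,
              phase_step_deg = phase_step_deg,
              low_expr_fraction = low_expr_fraction,
              repressed_fraction = repressed_fraction)
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("n_chromosomes", "genes_per_chromosome", "n_stages",
              "n_replicates", "n_levels", "motif_length", "tfs_per_level",
              "targets_per_level")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stopf("config field '%s' must be a count >= 1", f)
  }
  fr <- cfg$dup_mode_fractions
  modes <- c("WGD", "TD", "PD", "TRD", "DSD")
  if (!all(names(fr) %in% modes))
    stopf("dup_mode_fractions names must be among %s",
          paste(modes, collapse = ", "))
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stopf("dup_mode_fractions must lie in [0,1] and sum to <= 1")
  if (!(cfg$neg_cutoff < 0 && 0 < cfg$pos_cutoff))
    stopf("cutoffs must satisfy neg_cutoff < 0 < pos_cutoff")
  if (cfg$noise_sd < 0) stopf("noise_sd must be non-negative")
  for (pk in cfg$ks_peaks) {
    if (length(pk) < 3 || pk[1] < 0 || pk[2] <= 0 || pk[3] <= 0)
      stopf("each ks_peaks entry needs (location >= 0, weight > 0, spread > 0)")
  }
  # eight phase-shifted levels must stay distinguishable inside one cycle
  if ((cfg$n_levels - 1) * cfg$phase_step_deg >= 330)
    stopf("n_levels x phase_step_deg exceeds what %d stages can represent",
          cfg$n_stages)
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      sprintf("%d chromosomes x %d genes, %d stages x %d replicates,",
              x$n_chromosomes, x$genes_per_chromosome, x$n_stages,
              x$n_replicates),
      sprintf("%d levels, cutoffs (%.2f, %.2f), seed %d\n",
              x$n_levels, x$pos_cutoff, x$neg_cutoff, x$seed))
  invisible(x)
}

# stage x replicate sample design shared by the generators
sample_design <- function(cfg) {
  data.frame(sample = paste0("T", rep(seq_len(cfg$n_stages),
                                      each = cfg$n_replicates),
                             "_R", rep(seq_len(cfg$n_replicates),
                                       cfg$n_stages)),
             stage = rep(seq_len(cfg$n_stages), each = cfg$n_replicates),
             replicate = rep(seq_len(cfg$n_replicates), cfg$n_stages),
             stringsAsFactors = FALSE)
}
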