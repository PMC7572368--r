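# Codon-aligned sequence pairs with controlled synonymous / nonsynonymous
# divergence. Sequences are built from the fourfold-degenerate xCN codon
# block (Ala GCN, Thr ACN, Pro CCN, Ser TCN): every such codon has exactly
# one synonymous site (the third position) and two nonsynonymous sites, any
# third-position change is synonymous, and any first-position change stays
# inside the block (always nonsynonymous, never a stop). That makes the
# expected counting-method estimates exactly controllable.

xcn_codons <- function() {
  as.vector(outer(NUCS, NUCS, function(f, t) paste0(f, "C", t)))
}

#' Generate codon-aligned pairs with target Ks and Ka/Ks
#'
#' For each pair, sequence A is random over the xCN codon block; each codon of
#' sequence B independently receives at most one substitution: a synonymous
#' third-position change with probability `p_s`, or a nonsynonymous
#' first-position change with probability `2 p_n`, where
#' `p = 3/4 (1 - exp(-4/3 d))` inverts the Jukes-Cantor correction for the
#' target distances. The expected NG86 estimates then equal the targets up to
#' binomial sampling error.
#'
#' @param n_pairs number of pairs.
#' @param target_ks target synonymous distance (>= 0).
#' @param target_omega target Ka/Ks ratio (>= 0).
#' @param seed integer RNG seed.
#' @param length_nt sequence length in nucleotides; must be a positive
#'   multiple of 3 (default 900).
#' @return list with `pairs` (list of `list(id, seq_a, seq_b)`) and `truth`
#'   (data.frame pair_id, syn_subs, nonsyn_subs, target_ks, target_omega).
#' @export
generate_divergent_cds <- function(n_pairs, target_ks, target_omega, seed,
                                   length_nt = 900L) {
  if (target_ks < 0 || target_omega < 0)
    stopf("target_ks and target_omega must be non-negative")
  if (length_nt < 3 || length_nt %% 3 != 0)
    stopf("length_nt = %d is not a positive multiple of 3 (frame violation)",
          length_nt)
  ps <- 3 / 4 * (1 - exp(-4 / 3 * target_ks))
  if (ps >= 3 / 4 - 1e-12)
    stopf("target_ks = %g is beyond saturation (expected synonymous difference proportion >= 3/4)",
          target_ks)
  pn <- 3 / 4 * (1 - exp(-4 / 3 * target_omega * target_ks))
  if (ps + 2 * pn > 1)
    stopf("targets require more than one substitution per codon on average (p_s + 2 p_n = %.3f > 1)",
          ps + 2 * pn)
  L <- length_nt %/% 3
  cods <- xcn_codons()
  with_seed(seed, {
    pairs <- vector("list", n_pairs)
    truth <- data.frame(pair_id = sprintf("pair%04d", seq_len(n_pairs)),
                        syn_subs = 0L, nonsyn_subs = 0L,
                        target_ks = target_ks, target_omega = target_omega)
    for (i in seq_len(n_pairs)) {
      a <- sample(cods, L, replace = TRUE)
      b <- a
      u <- runif(L)
      syn_i <- which(u < ps)
      non_i <- which(u >= ps & u < ps + 2 * pn)
      for (j in syn_i) {
        third <- substr(b[j], 3, 3)
        substr(b[j], 3, 3) <- sample(setdiff(NUCS, third), 1)
      }
      for (j in non_i) {
        first <- substr(b[j], 1, 1)
        substr(b[j], 1, 1) <- sample(setdiff(NUCS, first), 1)
      }
      truth$syn_subs[i] <- length(syn_i)
      truth$nonsyn_subs[i] <- length(non_i)
      pairs[[i]] <- list(id = truth$pair_id[i],
                         seq_a = paste(a, collapse = ""),
                         seq_b = paste(b, collapse = ""))
    }
    list(pairs = pairs, truth = truth)
  })
}

#' Draw Ks values from the configured peak mixture
#'
#' Samples synonymous distances from the truncated-Gaussian mixture described
#' by `config$ks_peaks` (components truncated at 0 by resampling). Used to
#' exercise [ks_density()] peak recovery with known peak locations.
#'
#' @param config a [synthetic_config()].
#' @param n number of values.
#' @return numeric vector of non-negative Ks values.
#' @export
sample_ks_mixture <- function(config, n) {
  validate_config(config)
  pk <- do.call(rbind, config$ks_peaks)
  w <- pk[, 2] / sum(pk[, 2])
  with_seed(config$seed + 7L, {
    comp <- sample.int(nrow(pk), n, replace = TRUE, prob = w)
    x <- rnorm(n, pk[comp, 1], pk[comp, 3])
    while (any(x < 0)) {
      i <- which(x < 0)
      x[i] <- rnorm(length(i), pk[comp[i], 1], pk[comp[i], 3])
    }
    x
  })
}
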