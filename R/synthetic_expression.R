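# Time-course expression with a planted TF cascade, promoters with planted
# binding sites, and gene->term annotations with planted enrichment.

#' Stage x replicate expression container
#'
#' @param tpm genes x samples matrix of TPM values (row names = gene ids).
#' @param design data.frame with columns sample, stage, replicate matching
#'   the matrix columns.
#' @param is_tf named logical vector over the row genes.
#' @return an object of class `timecourse`.
#' @export
timecourse <- function(tpm, design, is_tf) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)),
            ncol(tpm) == nrow(design),
            all(c("sample", "stage", "replicate") %in% names(design)))
  if (any(tpm < 0)) stopf("TPM values must be non-negative")
  if (anyDuplicated(rownames(tpm))) stopf("gene ids must be unique")
  is_tf <- is_tf[rownames(tpm)]
  is_tf[is.na(is_tf)] <- FALSE
  names(is_tf) <- rownames(tpm)
  structure(list(tpm = tpm, design = design, is_tf = is_tf),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("timecourse: %d genes (%d TFs) x %d samples (%d stages)\n",
              nrow(x$tpm), sum(x$is_tf), ncol(x$tpm),
              length(unique(x$design$stage))))
  invisible(x)
}

stage_mean_mat <- function(tc, log2 = FALSE) {
  v <- if (log2) log2(tc$tpm + 1) else tc$tpm
  st <- tc$design$stage
  stages <- sort(unique(st))
  out <- matrix(0, nrow(v), length(stages),
                dimnames = list(rownames(v), paste0("T", stages)))
  for (i in seq_along(stages))
    out[, i] <- rowMeans(v[, st == stages[i], drop = FALSE])
  out
}

#' Generate a stage x replicate time course with a planted TF cascade
#'
#' Cascade TFs (the first `n_levels * tfs_per_level` TFs in catalog order, in
#' consecutive level blocks) receive phase-shifted cosine profiles on the
#' log2(TPM+1) scale, one phase per planted level, so that mean-profile
#' correlations between levels are exactly `cos(level difference x phase
#' step)`. Each planted enzyme target copies its direct regulator's profile
#' (sign-flipped cosine for repressed targets). Background genes are flat
#' plus noise, and a fraction of them sit below the 0.5-TPM expression
#' filter. Gaussian noise of sd `noise_sd` is added on the log2 scale and
#' the matrix is transformed back to TPM.
#'
#' @param config a [synthetic_config()].
#' @param catalog catalog from [generate_genome()] (same config).
#' @return list with `tc` (a [timecourse()]) and `truth`: `level_by_tf`
#'   (named integer), `chains` (list of `list(tfs, target, sign)`, most
#'   upstream TF first), `seed_candidates` (level-1 TF ids), `de_genes`,
#'   `low_expr_genes`.
#' @export
generate_timecourse <- function(config, catalog) {
  validate_config(config)
  validate_catalog(catalog)
  if ((config$n_levels - 1) * config$phase_step_deg >= 330)
    stopf("n_levels not representable by %d stage peak positions",
          config$n_stages)
  with_seed(config$seed + 1L, generate_timecourse_impl(config, catalog))
}

generate_timecourse_impl <- function(cfg, catalog) {
  design <- sample_design(cfg)
  t0 <- design$stage - 1            # 0-based stage coordinate
  w <- 2 * pi / cfg$n_stages
  phase <- function(level) (level - 1) * cfg$phase_step_deg * pi / 180
  cosprof <- function(level, flip = FALSE)
    cfg$baseline_log2 + (if (flip) -1 else 1) *
      cfg$amplitude_log2 * cos(w * t0 - phase(level))

  tf_ids <- catalog$gene_id[catalog$is_tf]
  n_casc <- cfg$n_levels * cfg$tfs_per_level
  if (length(tf_ids) < n_casc)
    stopf("catalog has %d TFs but the cascade needs %d", length(tf_ids), n_casc)
  casc_tf <- tf_ids[seq_len(n_casc)]
  level_by_tf <- setNames(rep(seq_len(cfg$n_levels), each = cfg$tfs_per_level),
                          casc_tf)

  targets <- catalog$gene_id[catalog$pathway_tag != "none"]
  n_tgt <- cfg$n_levels * cfg$targets_per_level
  if (length(targets) < n_tgt)
    stopf("catalog has %d pathway genes but the cascade needs %d",
          length(targets), n_tgt)
  targets <- targets[seq_len(n_tgt)]
  tgt_level <- rep(seq_len(cfg$n_levels), each = cfg$targets_per_level)

  # one regulator chain per target: direct regulator at the target's level,
  # second- and third-order regulators one and two levels upstream
  fam_of <- setNames(catalog$tf_family, catalog$gene_id)
  chains <- vector("list", n_tgt)
  tf_at_level <- split(casc_tf, level_by_tf[casc_tf])
  for (i in seq_len(n_tgt)) {
    l <- tgt_level[i]
    pick <- function(lv) tf_at_level[[lv]][1 + (i - 1) %% cfg$tfs_per_level]
    ups <- seq(max(1, l - 2), l)     # levels of the chain, upstream first
    chains[[i]] <- list(tfs = vapply(ups, pick, character(1)),
                        target = targets[i],
                        sign = if (runif(1) < cfg$repressed_fraction) "-"
                               else "+")
  }

  genes <- catalog$gene_id
  n <- length(genes)
  prof <- matrix(0, n, nrow(design), dimnames = list(genes, design$sample))
  for (tf in casc_tf) prof[tf, ] <- cosprof(level_by_tf[tf])
  bg_tfs <- setdiff(tf_ids, casc_tf)
  for (tf in bg_tfs) prof[tf, ] <- runif(1, 2, 6)
  for (i in seq_len(n_tgt)) {
    ch <- chains[[i]]
    direct <- ch$tfs[length(ch$tfs)]
    prof[ch$target, ] <- cosprof(level_by_tf[direct], flip = ch$sign == "-")
  }
  background <- setdiff(genes, c(tf_ids, targets))
  n_low <- round(cfg$low_expr_fraction * length(background))
  low_genes <- background[seq_len(n_low)]
  for (g in background) prof[g, ] <- runif(1, 1, 8)
  prof[low_genes, ] <- 0.2           # mean TPM ~0.15, below the 0.5 filter

  x <- prof
  if (cfg$noise_sd > 0)
    x <- x + matrix(rnorm(length(x), 0, cfg$noise_sd), nrow(x))
  tpm <- pmax(2^x - 1, 0)

  tc <- timecourse(tpm, design,
                   setNames(catalog$is_tf, catalog$gene_id))
  list(tc = tc,
       truth = list(level_by_tf = level_by_tf,
                    chains = chains,
                    seed_candidates = names(level_by_tf)[level_by_tf == 1L],
                    de_genes = c(casc_tf, targets),
                    low_expr_genes = low_genes,
                    family_of = fam_of))
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

#' Generate one PWM per transcription-factor family
#'
#' Count matrices with a dominant random consensus base per column (85 of 100
#' counts), wide enough that an exact consensus match in random sequence is
#' vanishingly rare.
#'
#' @param families family labels (default the built-in 16-family pool).
#' @param width motif width in bp.
#' @param seed integer RNG seed.
#' @return named list of `pwm` objects (`id`, `family`, 4 x width `counts`
#'   with rows A,C,G,T, uniform `bg`).
#' @export
generate_pwms <- function(families = tf_family_pool(), width = 15L,
                          seed = 1L) {
  if (width < 4) stopf("PWM width must be >= 4")
  with_seed(seed, {
    out <- lapply(families, function(fam) {
      cons <- sample(NUCS, width, replace = TRUE)
      counts <- matrix(5, 4, width, dimnames = list(NUCS, NULL))
      counts[cbind(match(cons, NUCS), seq_len(width))] <- 85
      structure(list(id = paste0("PWM_", fam), family = fam, counts = counts,
                     bg = rep(0.25, 4)), class = "pwm")
    })
    setNames(out, families)
  })
}

pwm_consensus <- function(pwm) {
  paste(NUCS[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Generate promoter sequences with planted binding sites
#'
#' Each planted chain's target receives a 2-kb (by default) i.i.d. uniform
#' promoter with one exact-consensus site of its direct regulator's family
#' PWM embedded at a recorded offset on a random strand; a set of background
#' genes receives motif-free promoters.
#'
#' @param catalog gene catalog (provides family labels).
#' @param pwm_set named list of PWMs keyed by family ([generate_pwms()]).
#' @param truth time-course truth holding the planted `chains`.
#' @param upstream_length promoter length in bases (default 2000).
#' @param n_background number of motif-free background promoters (default 20).
#' @param seed integer RNG seed.
#' @return list with `promoters` (named character vector) and `sites`
#'   (data.frame gene, motif_id, family, offset, strand); offsets are 0-based
#'   positions of the site's leftmost base on the forward strand.
#' @export
generate_promoters <- function(catalog, pwm_set, truth,
                               upstream_length = 2000L, n_background = 20L,
                               seed = 1L) {
  widths <- vapply(pwm_set, function(p) ncol(p$counts), integer(1))
  if (upstream_length < max(widths))
    stopf("upstream_length %d shorter than motif width %d",
          upstream_length, max(widths))
  chains <- truth$chains
  tgt <- vapply(chains, function(ch) ch$target, character(1))
  fam_of <- setNames(catalog$tf_family, catalog$gene_id)
  with_seed(seed, {
    bg_pool <- setdiff(catalog$gene_id, tgt)
    bg <- sample(bg_pool, min(n_background, length(bg_pool)))
    genes <- c(tgt, bg)
    prom <- vapply(genes, function(g)
      paste(sample(NUCS, upstream_length, replace = TRUE), collapse = ""),
      character(1))
    sites <- NULL
    for (ch in chains) {
      direct <- ch$tfs[length(ch$tfs)]
      fam <- fam_of[[direct]]
      pwm <- pwm_set[[fam]]
      if (is.null(pwm)) stopf("no PWM for family '%s'", fam)
      w <- ncol(pwm$counts)
      cons <- pwm_consensus(pwm)
      off <- sample.int(upstream_length - w + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") cons else revcomp(cons)
      substr(prom[ch$target], off + 1L, off + w) <- ins
      sites <- rbind(sites, data.frame(gene = ch$target, motif_id = pwm$id,
                                       family = fam, offset = off,
                                       strand = strand,
                                       stringsAsFactors = FALSE))
    }
    list(promoters = prom, sites = sites)
  })
}

#' Generate gene-to-term annotations with planted enrichment
#'
#' Every gene is annotated to each term with a uniform background rate; for
#' each planted enriched term, the member genes of the supplied study set are
#' annotated at a much higher rate, so that the upper-tail hypergeometric
#' test on that study set is expected to reject far below the 0.001
#' adjusted-p threshold.
#'
#' @param catalog gene catalog (defines the gene universe).
#' @param n_terms number of terms to generate.
#' @param enriched named list: term id -> character vector of study genes to
#'   enrich (may be empty/NULL for a pure null).
#' @param seed integer RNG seed.
#' @param base_rate background annotation probability (default 0.03).
#' @param enriched_rate annotation probability of study genes in enriched
#'   terms (default 0.5).
#' @return list with `annotations` (data.frame gene_id, term_id) and `truth`
#'   (list with `enriched_terms`).
#' @export
generate_annotations <- function(catalog, n_terms, enriched = NULL, seed = 1L,
                                 base_rate = 0.03, enriched_rate = 0.5) {
  enriched <- enriched %||% list()
  if (n_terms < length(enriched))
    stopf("n_terms = %d < %d planted enriched terms", n_terms,
          length(enriched))
  bad <- setdiff(unlist(enriched), catalog$gene_id)
  if (length(bad)) stopf("enriched genes not in catalog: %s",
                         paste(head(bad, 5), collapse = ", "))
  terms <- sprintf("TERM%04d", seq_len(n_terms))
  if (length(enriched)) {
    if (!all(names(enriched) %in% terms))
      stopf("enriched term ids must be among %s..%s", terms[1],
            terms[n_terms])
  }
  genes <- catalog$gene_id
  with_seed(seed, {
    ann <- list()
    for (tm in terms) {
      hit <- runif(length(genes)) < base_rate
      members <- genes[hit]
      if (tm %in% names(enriched)) {
        st <- enriched[[tm]]
        members <- union(members, st[runif(length(st)) < enriched_rate])
      }
      if (length(members))
        ann[[tm]] <- data.frame(gene_id = members, term_id = tm,
                                stringsAsFactors = FALSE)
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(gene_id = character(0), term_id = character(0))
    rownames(annotations) <- NULL
    list(annotations = annotations,
         truth = list(enriched_terms = names(enriched)))
  })
}
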