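# Synthetic gene catalog, homolog pairs and collinear blocks with planted
# duplication modes. Coordinates are 0-based half-open; the unit of "gene
# distance" for tandem/proximal rules is the rank (order index) within a
# chromosome, not base pairs.

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

tf_family_pool <- function() {
  c("MYB", "bHLH", "WD40", "WRKY", "ERF", "GRAS", "C2H2", "C3H",
    "NAC", "bZIP", "MADS", "AP2", "ARF", "DOF", "HSF", "TCP")
}

#' Generate a synthetic gene catalog with planted duplication modes
#'
#' Builds a multi-chromosome ordered gene catalog, plants homologous gene
#' pairs of each duplication mode, and emits the collinear (synteny) anchors
#' of the planted whole-genome-duplicate blocks:
#' \itemize{
#'   \item WGD pairs sit inside collinear blocks of at least 5 anchor pairs
#'     spanning two chromosomes;
#'   \item TD pairs are rank-adjacent on one chromosome;
#'   \item PD pairs are separated by 1--9 intervening genes;
#'   \item TRD pairs join one block-anchored gene (the ancestral locus) to an
#'     unanchored gene on another chromosome;
#'   \item DSD pairs violate all of the above.
#' }
#' At most 4 same-chromosome pairs are planted per chromosome so that planted
#' tandem/proximal pairs can never themselves chain into a spurious collinear
#' block of 5 or more anchors.
#'
#' Transcription-factor and pathway labels for the downstream co-expression
#' cascade are also assigned here (which genes are TFs, their families, and
#' which genes are pathway enzyme targets); the expression-level structure
#' itself is planted by [generate_timecourse()].
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `catalog` (data.frame: gene_id, chrom, start,
#'   end, strand, rank, is_tf, tf_family, pathway_tag), `pairs` (gene_a,
#'   gene_b, score), `anchors` (block_id, gene_a, gene_b), and `truth`
#'   (list with `mode_by_pair`).
#' @export
generate_genome <- function(config) {
  validate_config(config)
  with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(cfg) {
  nc <- cfg$n_chromosomes
  gpc <- cfg$genes_per_chromosome
  n_genes <- nc * gpc

  chrom <- rep(seq_len(nc), each = gpc)
  rank <- rep(seq_len(gpc) - 1L, nc)
  len <- sample(900:3000, n_genes, replace = TRUE)
  gap <- sample(500:5000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  for (c in seq_len(nc)) {
    i <- which(chrom == c)
    start[i] <- cumsum(c(0L, (len + gap)[i[-length(i)]])) + gap[i]
  }
  catalog <- data.frame(
    gene_id = sprintf("AZA%02dG%04d", chrom, rank + 1L),
    chrom = paste0("chr", sprintf("%02d", chrom)),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    rank = rank, is_tf = FALSE, tf_family = NA_character_,
    pathway_tag = "none", stringsAsFactors = FALSE)

  # --- cascade labels -------------------------------------------------------
  n_casc_tf <- cfg$n_levels * cfg$tfs_per_level
  n_tf <- n_casc_tf + cfg$n_background_tfs
  n_targets <- cfg$n_levels * cfg$targets_per_level
  if (n_tf + n_targets > n_genes)
    stopf("catalog too small: %d TFs + %d targets > %d genes",
          n_tf, n_targets, n_genes)
  lab <- sample.int(n_genes, n_tf + n_targets)
  # positional (catalog) order, so the time-course generator can reconstruct
  # the level blocks from the catalog alone: cascade TFs are the first
  # n_levels x tfs_per_level TFs in catalog order, one level per block
  tf_idx <- sort(lab[seq_len(n_tf)])
  tgt_idx <- sort(lab[n_tf + seq_len(n_targets)])
  catalog$is_tf[tf_idx] <- TRUE
  fams <- tf_family_pool()
  # within each level every family appears at most once, so that family-level
  # binding support identifies the planted regulator among its level cohort
  casc_fams <- unlist(lapply(seq_len(cfg$n_levels), function(l)
    rep_len(fams, cfg$tfs_per_level)))
  catalog$tf_family[tf_idx] <-
    c(casc_fams, sample(fams, cfg$n_background_tfs, replace = TRUE))
  catalog$pathway_tag[tgt_idx] <-
    rep_len(c("anthocyanin", "carotenoid"), n_targets)

  # --- duplication planting -------------------------------------------------
  fr <- cfg$dup_mode_fractions
  frac <- function(m) if (m %in% names(fr)) fr[[m]] else 0
  n_pairs <- c(WGD = floor(frac("WGD") * n_genes / 2),
               TD  = floor(frac("TD") * n_genes / 2),
               PD  = floor(frac("PD") * n_genes / 2),
               TRD = floor(frac("TRD") * n_genes),
               DSD = floor(frac("DSD") * n_genes / 2))

  used <- rep(FALSE, n_genes)          # genes consumed by planted pairs
  idx_of <- function(c, r) (c - 1L) * gpc + r + 1L

  pairs <- list(); anchors <- list(); modes <- list()
  add_pair <- function(i, j, mode) {
    pairs[[length(pairs) + 1L]] <<- c(catalog$gene_id[i], catalog$gene_id[j])
    modes[[length(modes) + 1L]] <<- mode
  }

  # WGD: collinear blocks of 5-8 consecutive anchors between two chromosomes
  anchored_idx <- integer(0)
  anchored_chroms <- character(0)   # "chrA|chrB" of the block, per anchored gene
  block_chrom_pairs <- character(0) # unordered chrom pairs hosting a block
  chrom_pair_key <- function(c1, c2) paste(sort(c(c1, c2)), collapse = "|")
  # cross-chromosome non-anchor pairs per chrom pair are capped at 4 so they
  # can never chain into a spurious collinear block (min_anchors = 5)
  xchrom_tally <- new.env(parent = emptyenv())
  xchrom_ok <- function(key) {
    n <- get0(key, envir = xchrom_tally, ifnotfound = 0L)
    if (n >= 4L || key %in% block_chrom_pairs) return(FALSE)
    assign(key, n + 1L, envir = xchrom_tally)
    TRUE
  }
  if (n_pairs["WGD"] > 0) {
    if (n_pairs["WGD"] < 5)
      stopf("infeasible config: %d WGD pairs cannot fill a collinear block (needs >= 5 anchors)",
            n_pairs["WGD"])
    remaining <- n_pairs["WGD"]
    block_id <- 0L
    guard <- 0L
    while (remaining > 0) {
      size <- min(remaining, if (remaining >= 12) 7L else remaining)
      if (size < 5) size <- remaining  # tail block absorbed below
      if (size < 5) stopf("infeasible WGD block sizing")
      cpair <- sample.int(nc, 2)
      s1 <- sample.int(gpc - size + 1L, 1) - 1L
      s2 <- sample.int(gpc - size + 1L, 1) - 1L
      i1 <- idx_of(cpair[1], s1 + 0:(size - 1L))
      i2 <- idx_of(cpair[2], s2 + 0:(size - 1L))
      if (any(used[c(i1, i2)])) {
        guard <- guard + 1L
        if (guard > 2000) stopf("infeasible config: cannot place WGD blocks (fractions too high)")
        next
      }
      used[c(i1, i2)] <- TRUE
      block_id <- block_id + 1L
      for (k in seq_len(size)) {
        add_pair(i1[k], i2[k], "WGD")
        anchors[[length(anchors) + 1L]] <-
          data.frame(block_id = paste0("block", block_id),
                     gene_a = catalog$gene_id[i1[k]],
                     gene_b = catalog$gene_id[i2[k]],
                     stringsAsFactors = FALSE)
      }
      anchored_idx <- c(anchored_idx, i1, i2)
      ck <- chrom_pair_key(catalog$chrom[i1[1]], catalog$chrom[i2[1]])
      anchored_chroms <- c(anchored_chroms, rep(ck, 2L * size))
      block_chrom_pairs <- unique(c(block_chrom_pairs, ck))
      remaining <- remaining - size
    }
  }

  # TD / PD: same-chromosome pairs, capped at 4 per chromosome combined
  same_chrom_quota <- rep(4L, nc)
  if (n_pairs["TD"] + n_pairs["PD"] > sum(same_chrom_quota))
    stopf("infeasible config: %d same-chromosome pairs exceed capacity %d",
          n_pairs["TD"] + n_pairs["PD"], sum(same_chrom_quota))
  place_same_chrom <- function(n, gap_range, mode) {
    guard <- 0L
    while (n > 0) {
      c <- sample.int(nc, 1)
      if (same_chrom_quota[c] == 0L) { guard <- guard + 1L }
      else {
        g <- if (length(gap_range) == 1L) gap_range else sample(gap_range, 1)
        r1 <- sample.int(gpc - g, 1) - 1L
        i <- idx_of(c, r1); j <- idx_of(c, r1 + g)
        if (!used[i] && !used[j]) {
          used[c(i, j)] <<- TRUE
          same_chrom_quota[c] <<- same_chrom_quota[c] - 1L
          add_pair(i, j, mode)
          n <- n - 1L
        } else guard <- guard + 1L
      }
      if (guard > 5000)
        stopf("infeasible config: cannot place %s pairs", mode)
    }
  }
  place_same_chrom(n_pairs["TD"], 1L, "TD")
  place_same_chrom(n_pairs["PD"], 2:9, "PD")

  # TRD: ancestral (anchored) locus paired with a novel unanchored gene
  if (n_pairs["TRD"] > 0) {
    if (length(anchored_idx) == 0)
      stopf("infeasible config: TRD pairs need WGD blocks for ancestral loci")
    guard <- 0L
    n <- n_pairs["TRD"]
    while (n > 0) {
      k <- sample.int(length(anchored_idx), 1)
      a <- anchored_idx[k]
      b <- sample.int(n_genes, 1)
      key <- chrom_pair_key(catalog$chrom[a], catalog$chrom[b])
      # the novel locus must sit outside the ancestral block's chromosome
      # pair, and the pair's own chrom pair must stay un-chainable
      if (!used[b] && catalog$chrom[b] != catalog$chrom[a] &&
          !grepl(catalog$chrom[b], anchored_chroms[k], fixed = TRUE) &&
          xchrom_ok(key)) {
        used[b] <- TRUE
        add_pair(a, b, "TRD")
        n <- n - 1L
      } else guard <- guard + 1L
      if (guard > 5000) stopf("infeasible config: cannot place TRD pairs")
    }
  }

  # DSD: unanchored genes on different chromosomes
  if (n_pairs["DSD"] > 0) {
    guard <- 0L
    n <- n_pairs["DSD"]
    while (n > 0) {
      ij <- sample.int(n_genes, 2)
      if (!any(used[ij]) && catalog$chrom[ij[1]] != catalog$chrom[ij[2]] &&
          xchrom_ok(chrom_pair_key(catalog$chrom[ij[1]],
                                   catalog$chrom[ij[2]]))) {
        used[ij] <- TRUE
        add_pair(ij[1], ij[2], "DSD")
        n <- n - 1L
      } else guard <- guard + 1L
      if (guard > 5000) stopf("infeasible config: cannot place DSD pairs")
    }
  }

  if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    pair_df <- data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
                          score = round(runif(nrow(pr), 0.7, 1), 4),
                          stringsAsFactors = FALSE)
    mode_df <- data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
                          mode = unlist(modes), stringsAsFactors = FALSE)
    ord <- sample.int(nrow(pair_df))          # shuffle: order carries no signal
    pair_df <- pair_df[ord, , drop = FALSE]
    rownames(pair_df) <- NULL
  } else {
    pair_df <- data.frame(gene_a = character(0), gene_b = character(0),
                          score = numeric(0), stringsAsFactors = FALSE)
    mode_df <- data.frame(gene_a = character(0), gene_b = character(0),
                          mode = character(0), stringsAsFactors = FALSE)
  }
  anchor_df <- if (length(anchors)) do.call(rbind, anchors) else
    data.frame(block_id = character(0), gene_a = character(0),
               gene_b = character(0), stringsAsFactors = FALSE)

  list(catalog = catalog, pairs = pair_df, anchors = anchor_df,
       truth = list(mode_by_pair = mode_df))
}

#' Validate a gene catalog
#'
#' Checks the catalog invariants: unique ids, start < end, and ranks forming
#' a permutation of 0..n-1 within each chromosome.
#' @param catalog a catalog data.frame.
#' @return the catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "rank")
  if (!all(need %in% names(catalog)))
    stopf("catalog lacks columns: %s",
          paste(setdiff(need, names(catalog)), collapse = ", "))
  if (anyDuplicated(catalog$gene_id)) stopf("catalog gene ids not unique")
  if (any(catalog$start >= catalog$end)) stopf("catalog has start >= end")
  for (c in unique(catalog$chrom)) {
    r <- sort(catalog$rank[catalog$chrom == c])
    if (!identical(as.integer(r), seq_along(r) - 1L))
      stopf("ranks on %s are not a permutation of 0..n-1", c)
  }
  invisible(catalog)
}
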