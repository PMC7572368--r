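# Duplication-mode classification: collinear block chaining from homolog
# pairs, the WGD > TD > PD > TRD > DSD priority rules, and the proportion
# statistics reported over them.

DUP_MODES <- c("WGD", "TD", "PD", "TRD", "DSD")

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Chain homolog pairs into collinear (synteny) blocks
#'
#' Within each chromosome pair, anchors are chained by longest-chain dynamic
#' programming over rank coordinates: a chain must be strictly increasing in
#' rank on side a and strictly monotone (increasing or decreasing) on side b,
#' with per-step rank gaps of at most `max_rank_gap` on both sides. Maximal
#' chains are extracted greedily (longest first, pairs used at most once)
#' until no chain of `min_anchors` anchors remains. Ties are broken
#' deterministically by (chromosome id, smallest rank).
#'
#' @param pairs data.frame with columns gene_a, gene_b.
#' @param catalog gene catalog providing chromosome and rank per gene.
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_rank_gap maximum per-step rank gap on either side (default 25).
#' @return list of `synteny_block` objects: list(block_id, anchors
#'   (data.frame gene_a, gene_b), chrom_a, chrom_b, orientation).
#' @export
chain_synteny <- function(pairs, catalog, min_anchors = 5L,
                          max_rank_gap = 25L) {
  if (nrow(pairs) == 0) return(list())
  unknown <- setdiff(c(pairs$gene_a, pairs$gene_b), catalog$gene_id)
  if (length(unknown))
    stopf("pair references unknown gene(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  rank <- setNames(catalog$rank, catalog$gene_id)

  # orient each pair so side a is the lexicographically smaller chromosome
  # (ties: smaller rank), making the chromosome-pair grouping canonical
  a <- pairs$gene_a; b <- pairs$gene_b
  swap <- (chrom[a] > chrom[b]) | (chrom[a] == chrom[b] & rank[a] > rank[b])
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  grp <- paste(chrom[a], chrom[b], sep = "|")

  blocks <- list()
  bid <- 0L
  for (g in sort(unique(grp))) {
    sel <- which(grp == g)
    df <- data.frame(gene_a = a[sel], gene_b = b[sel],
                     ra = rank[a[sel]], rb = rank[b[sel]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$ra, df$rb), , drop = FALSE]
    repeat {
      ch <- longest_chain(df, max_rank_gap)
      if (length(ch) < min_anchors) break
      bid <- bid + 1L
      anc <- df[ch, c("gene_a", "gene_b")]
      rownames(anc) <- NULL
      orientation <- if (length(ch) > 1 && df$rb[ch[2]] < df$rb[ch[1]])
        "inverted" else "same"
      blocks[[bid]] <- structure(
        list(block_id = paste0("block", bid), anchors = anc,
             chrom_a = chrom[anc$gene_a[1]], chrom_b = chrom[anc$gene_b[1]],
             orientation = orientation),
        class = "synteny_block")
      df <- df[-ch, , drop = FALSE]
    }
  }
  blocks
}

# longest chain (indices into df, which is sorted by (ra, rb)) with strictly
# increasing ra, strictly monotone rb, and per-step gaps <= max_gap; the DP is
# run for both orientations and the longer chain returned (ties: forward
# orientation, then smallest start rank by the df ordering)
longest_chain <- function(df, max_gap) {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  best <- integer(0)
  for (dirn in c(1, -1)) {
    len <- rep(1L, n); prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        step_a <- df$ra[i] - df$ra[j]
        step_b <- dirn * (df$rb[i] - df$rb[j])
        ok <- step_a > 0 && step_a <= max_gap &&
          step_b > 0 && step_b <= max_gap
        if (ok && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    end <- which.max(len)           # ties: smallest index = smallest rank
    chain <- integer(0); i <- end
    while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
    if (length(chain) > length(best)) best <- chain
  }
  best
}

#' Classify duplicated gene pairs into WGD/TD/PD/TRD/DSD
#'
#' Pair rules, applied in the priority order WGD > TD > PD > TRD > DSD:
#' \itemize{
#'   \item WGD: both members are anchors of a collinear block;
#'   \item TD: same chromosome, adjacent in rank (gene distance 1);
#'   \item PD: same chromosome, gene distance strictly between 1 and
#'     `proximal_max_gap` (default 10, i.e. fewer than 10 genes apart);
#'   \item TRD: exactly one member anchored in any block (the ancestral
#'     locus), and not TD/PD;
#'   \item DSD: everything else.
#' }
#' A gene in several pairs takes the highest-priority mode among its pairs;
#' catalog genes in no pair are singletons.
#'
#' @param catalog gene catalog.
#' @param pairs data.frame gene_a, gene_b.
#' @param blocks blocks from [chain_synteny()] (may be an empty list, in
#'   which case WGD and TRD are unreachable).
#' @param proximal_max_gap proximal rule upper bound on gene distance
#'   (exclusive; default 10).
#' @return a `dup_assignment`: list with `genes` (data.frame gene_id, mode,
#'   partner; mode "singleton" for unpaired genes) and `pairs` (data.frame
#'   gene_a, gene_b, mode).
#' @export
classify_duplicates <- function(catalog, pairs, blocks,
                                proximal_max_gap = 10L) {
  unknown <- setdiff(c(pairs$gene_a, pairs$gene_b), catalog$gene_id)
  if (length(unknown))
    stopf("pair references unknown gene(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  rank <- setNames(catalog$rank, catalog$gene_id)
  anchored <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))

  mode <- character(nrow(pairs))
  if (nrow(pairs)) {
    a <- pairs$gene_a; b <- pairs$gene_b
    n_anch <- (a %in% anchored) + (b %in% anchored)
    same <- chrom[a] == chrom[b]
    gap <- abs(rank[a] - rank[b])
    mode <- ifelse(n_anch == 2L, "WGD",
            ifelse(same & gap == 1L, "TD",
            ifelse(same & gap > 1L & gap < proximal_max_gap, "PD",
            ifelse(n_anch == 1L, "TRD", "DSD"))))
  }
  pair_df <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                        mode = mode, stringsAsFactors = FALSE)

  # per-gene: highest-priority mode among the gene's pairs
  gene_mode <- setNames(rep("singleton", nrow(catalog)), catalog$gene_id)
  partner <- setNames(rep(NA_character_, nrow(catalog)), catalog$gene_id)
  prio <- setNames(seq_along(DUP_MODES), DUP_MODES)
  if (nrow(pair_df)) {
    long <- rbind(data.frame(g = pair_df$gene_a, p = pair_df$gene_b,
                             mode = pair_df$mode),
                  data.frame(g = pair_df$gene_b, p = pair_df$gene_a,
                             mode = pair_df$mode))
    long <- long[order(prio[long$mode], long$p), , drop = FALSE]
    first <- !duplicated(long$g)
    gene_mode[long$g[first]] <- long$mode[first]
    partner[long$g[first]] <- long$p[first]
  }
  genes <- data.frame(gene_id = catalog$gene_id, mode = unname(gene_mode),
                      partner = unname(partner), stringsAsFactors = FALSE)
  structure(list(genes = genes, pairs = pair_df), class = "dup_assignment")
}

#' @export
print.dup_assignment <- function(x, ...) {
  tab <- table(factor(x$genes$mode, levels = c(DUP_MODES, "singleton")))
  cat("duplication assignment:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Per-mode duplicated-gene counts and percentages
#'
#' Percentages are 100 x mode count / `total_genes`, half-up rounded to one
#' decimal (the denominator is typically the full protein-coding gene count,
#' not just duplicated genes).
#'
#' @param assignment a `dup_assignment`, or a named vector of per-mode gene
#'   counts (for desk arithmetic over published counts).
#' @param total_genes denominator (> 0).
#' @return data.frame mode, count, percentage.
#' @export
mode_proportions <- function(assignment, total_genes) {
  if (total_genes <= 0) stopf("total_genes must be positive")
  counts <- if (inherits(assignment, "dup_assignment")) {
    tab <- table(factor(assignment$genes$mode, levels = DUP_MODES))
    setNames(as.integer(tab), DUP_MODES)
  } else {
    if (is.null(names(assignment))) stopf("counts must be named by mode")
    assignment[intersect(DUP_MODES, names(assignment))]
  }
  if (sum(counts) > total_genes)
    stopf("duplicated genes (%d) exceed total_genes (%d)", sum(counts),
          total_genes)
  data.frame(mode = names(counts), count = as.integer(counts),
             percentage = round_half_up(100 * as.integer(counts) /
                                          total_genes, 1),
             stringsAsFactors = FALSE)
}

#' Share of a gene set arising from tandem or proximal duplication
#'
#' @param assignment a `dup_assignment`.
#' @param gene_set non-empty character vector of gene ids.
#' @return list with `count` (genes of the set classified TD or PD), `size`,
#'   and `percentage` (half-up, two decimals).
#' @export
set_td_pd_fraction <- function(assignment, gene_set) {
  if (length(gene_set) == 0) stopf("gene_set must be non-empty")
  unknown <- setdiff(gene_set, assignment$genes$gene_id)
  if (length(unknown))
    stopf("gene_set contains unknown gene(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  tdpd <- assignment$genes$gene_id[assignment$genes$mode %in% c("TD", "PD")]
  k <- length(intersect(gene_set, tdpd))
  list(count = k, size = length(gene_set),
       percentage = round_half_up(100 * k / length(gene_set), 2))
}

#' Overlap of an expanded-gene-family set with each duplication mode
#'
#' @param egf_genes character vector of expanded-gene-family member ids.
#' @param assignment a `dup_assignment`.
#' @return list with `counts` (named per-mode intersection sizes, plus
#'   `singleton`) and `td_pd_share` (percentage of EGF genes in TD or PD;
#'   NA for an empty set).
#' @export
egf_mode_overlap <- function(egf_genes, assignment) {
  modes <- setNames(assignment$genes$mode, assignment$genes$gene_id)
  m <- modes[intersect(egf_genes, names(modes))]
  counts <- table(factor(m, levels = c(DUP_MODES, "singleton")))
  share <- if (length(egf_genes))
    round_half_up(100 * sum(m %in% c("TD", "PD")) / length(egf_genes), 2)
  else NA_real_
  list(counts = setNames(as.integer(counts), names(counts)),
       td_pd_share = share)
}
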