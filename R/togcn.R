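# Time-ordered gene co-expression network: expression filter, differential
# gate, signed Pearson network, seed selection, breadth-first level
# assignment, and level -> stage-group mapping.

#' Remove genes below an average-TPM floor
#'
#' Keeps genes whose mean TPM over all samples is at least `min_avg_tpm`
#' (the boundary is kept) and reports the number removed.
#'
#' @param tc a [timecourse()].
#' @param min_avg_tpm expression floor (default 0.5 TPM).
#' @return the filtered `timecourse`, with attribute `removed` (count).
#' @export
filter_expressed <- function(tc, min_avg_tpm = 0.5) {
  stopifnot(inherits(tc, "timecourse"))
  keep <- rowMeans(tc$tpm) >= min_avg_tpm
  removed <- sum(!keep)
  if (all(!keep)) warning("expression filter removed every gene")
  message(sprintf("filter_expressed: removed %d of %d genes (mean TPM < %g)",
                  removed, length(keep), min_avg_tpm))
  out <- timecourse(tc$tpm[keep, , drop = FALSE], tc$design, tc$is_tf[keep])
  attr(out, "removed") <- removed
  out
}

#' Genes differentially expressed between any two stages
#'
#' Welch t-tests on log2(TPM+1) for every stage pair, Benjamini-Hochberg
#' correction jointly across all genes x stage pairs; a gene qualifies if any
#' stage pair has adjusted p <= `fdr` and absolute mean log2 fold change of
#' at least `min_abs_log2fc`. (A count-model test such as DESeq2's would
#' normally stand here; a pre-computed DE list can be substituted downstream.)
#'
#' @param tc a [timecourse()]; every stage needs at least 2 replicates.
#' @param fdr adjusted-p cutoff (default 0.05).
#' @param min_abs_log2fc fold-change cutoff on log2(TPM+1) means (default 1).
#' @return character vector of gene ids.
#' @export
differential_genes <- function(tc, fdr = 0.05, min_abs_log2fc = 1) {
  stopifnot(inherits(tc, "timecourse"))
  st <- tc$design$stage
  reps <- table(st)
  if (any(reps < 2))
    stopf("stage(s) %s have fewer than 2 replicates (variance undefined)",
          paste(names(reps)[reps < 2], collapse = ", "))
  x <- log2(tc$tpm + 1)
  stages <- sort(unique(st))
  prs <- combn(stages, 2)
  n_genes <- nrow(x)
  pmat <- matrix(NA_real_, n_genes, ncol(prs))
  fcmat <- matrix(NA_real_, n_genes, ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i1 <- st == prs[1, k]; i2 <- st == prs[2, k]
    for (g in seq_len(n_genes)) {
      a <- x[g, i1]; b <- x[g, i2]
      fcmat[g, k] <- mean(b) - mean(a)
      if (sd(a) == 0 && sd(b) == 0) {
        pmat[g, k] <- if (mean(a) == mean(b)) 1 else 0
      } else {
        pmat[g, k] <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
      }
    }
  }
  padj <- matrix(p.adjust(pmat, method = "BH"), n_genes)
  hit <- rowSums(padj <= fdr & abs(fcmat) >= min_abs_log2fc, na.rm = TRUE) > 0
  rownames(x)[hit]
}

#' Signed Pearson co-expression network
#'
#' Correlations are computed across all stage x replicate samples on the
#' log2(TPM+1) scale (set `use_log2 = FALSE` for raw TPM, or
#' `stage_means = TRUE` to correlate stage means). TF-TF and TF-gene edges
#' are stored when r >= `pos_cutoff` or r <= `neg_cutoff`; gene-gene edges
#' are excluded by default and there are no self-edges. Constant-expression
#' genes yield no edges.
#'
#' @param tc a [timecourse()] (>= 3 samples).
#' @param tf_set,gene_set character vectors of TF and candidate gene ids
#'   (must be rows of the matrix).
#' @param pos_cutoff,neg_cutoff signed edge cutoffs (defaults 0.81, -0.57).
#' @param use_log2 correlate log2(TPM+1) values (default TRUE).
#' @param stage_means correlate per-stage means instead of replicate-level
#'   samples (default FALSE).
#' @param gene_gene also store gene-gene edges (default FALSE).
#' @return a `signed_gcn`: list with `nodes` (data.frame id, is_tf), `edges`
#'   (data.frame gene_a, gene_b, r, sign), and `cutoffs`.
#' @export
pearson_network <- function(tc, tf_set, gene_set, pos_cutoff = 0.81,
                            neg_cutoff = -0.57, use_log2 = TRUE,
                            stage_means = FALSE, gene_gene = FALSE) {
  stopifnot(inherits(tc, "timecourse"))
  if (!(neg_cutoff < 0 && 0 < pos_cutoff))
    stopf("cutoffs must satisfy neg_cutoff < 0 < pos_cutoff")
  miss <- setdiff(c(tf_set, gene_set), rownames(tc$tpm))
  if (length(miss)) stopf("genes not in matrix: %s",
                          paste(head(miss, 5), collapse = ", "))
  x <- if (stage_means) stage_mean_mat(tc, log2 = use_log2) else
    if (use_log2) log2(tc$tpm + 1) else tc$tpm
  if (ncol(x) < 3) stopf("need at least 3 samples to correlate")
  tf_set <- unique(tf_set)
  gene_set <- unique(setdiff(gene_set, tf_set))
  ids <- c(tf_set, gene_set)
  x <- x[ids, , drop = FALSE]
  ok <- apply(x, 1, sd) > 0
  r <- suppressWarnings(cor(t(x[ok, , drop = FALSE])))
  idx <- which(ok)
  tfq <- ids[idx] %in% tf_set
  edges <- NULL
  nt <- sum(tfq)
  if (nt > 1) {
    m <- r[tfq, tfq, drop = FALSE]
    ut <- which(upper.tri(m) & (m >= pos_cutoff | m <= neg_cutoff),
                arr.ind = TRUE)
    if (nrow(ut))
      edges <- rbind(edges, data.frame(gene_a = rownames(m)[ut[, 1]],
                                       gene_b = colnames(m)[ut[, 2]],
                                       r = m[ut], stringsAsFactors = FALSE))
  }
  if (nt > 0 && sum(!tfq) > 0) {
    m <- r[tfq, !tfq, drop = FALSE]
    hit <- which(m >= pos_cutoff | m <= neg_cutoff, arr.ind = TRUE)
    if (nrow(hit))
      edges <- rbind(edges, data.frame(gene_a = rownames(m)[hit[, 1]],
                                       gene_b = colnames(m)[hit[, 2]],
                                       r = m[hit], stringsAsFactors = FALSE))
  }
  if (gene_gene && sum(!tfq) > 1) {
    m <- r[!tfq, !tfq, drop = FALSE]
    ut <- which(upper.tri(m) & (m >= pos_cutoff | m <= neg_cutoff),
                arr.ind = TRUE)
    if (nrow(ut))
      edges <- rbind(edges, data.frame(gene_a = rownames(m)[ut[, 1]],
                                       gene_b = colnames(m)[ut[, 2]],
                                       r = m[ut], stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r > 0, "+", "-")
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids, is_tf = ids %in% tf_set,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 cutoffs = c(pos = pos_cutoff, neg = neg_cutoff)),
            class = "signed_gcn")
}

#' @export
print.signed_gcn <- function(x, ...) {
  cat(sprintf("signed GCN: %d nodes (%d TFs), %d edges (%d +, %d -), cutoffs (%.2f, %.2f)\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-"),
              x$cutoffs["pos"], x$cutoffs["neg"]))
  invisible(x)
}

#' Permutation-calibrated correlation cutoffs
#'
#' For a grid of candidate cutoffs, compares the number of edges in the real
#' data with the average count obtained after independently permuting each
#' gene's samples (which preserves marginal profiles but destroys
#' co-expression). Returns the smallest-magnitude cutoffs whose
#' permutation-based edge FDR is at most `target_edge_fdr`; falls back to
#' (0.81, -0.57) with a warning when no grid point qualifies.
#'
#' @param tc a filtered [timecourse()].
#' @param tf_set,gene_set node sets as in [pearson_network()].
#' @param n_permutations number of permutations (>= 10; default 1000).
#' @param target_edge_fdr tolerated fraction of null edges (default 0.01).
#' @param seed RNG seed for the permutations.
#' @return named numeric vector c(pos, neg).
#' @export
suggest_cutoffs <- function(tc, tf_set, gene_set, n_permutations = 1000L,
                            target_edge_fdr = 0.01, seed = 1L) {
  stopifnot(inherits(tc, "timecourse"))
  if (n_permutations < 10) stopf("need at least 10 permutations")
  ids <- unique(c(tf_set, gene_set))
  x <- log2(tc$tpm[ids, , drop = FALSE] + 1)
  x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
  tfq <- rownames(x) %in% tf_set
  rvals <- function(m) {
    r <- suppressWarnings(cor(t(m)))
    rtt <- r[tfq, tfq, drop = FALSE]
    c(rtt[upper.tri(rtt)], as.vector(r[tfq, !tfq, drop = FALSE]))
  }
  real <- rvals(x)
  pos_grid <- seq(0.50, 0.99, by = 0.01)
  neg_grid <- -seq(0.30, 0.99, by = 0.01)
  null_pos <- numeric(length(pos_grid))
  null_neg <- numeric(length(neg_grid))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      xp <- t(apply(x, 1, sample))
      nullr <- rvals(xp)
      null_pos <- null_pos + vapply(pos_grid, function(c) sum(nullr >= c),
                                    numeric(1))
      null_neg <- null_neg + vapply(neg_grid, function(c) sum(nullr <= c),
                                    numeric(1))
    }
  })
  null_pos <- null_pos / n_permutations
  null_neg <- null_neg / n_permutations
  real_pos <- vapply(pos_grid, function(c) sum(real >= c), numeric(1))
  real_neg <- vapply(neg_grid, function(c) sum(real <= c), numeric(1))
  fdr_pos <- null_pos / pmax(real_pos, 1)
  fdr_neg <- null_neg / pmax(real_neg, 1)
  okp <- which(fdr_pos <= target_edge_fdr)
  okn <- which(fdr_neg <= target_edge_fdr)
  if (!length(okp) || !length(okn)) {
    warning("no grid cutoff met the edge FDR target; falling back to (0.81, -0.57)")
    return(c(pos = 0.81, neg = -0.57))
  }
  c(pos = pos_grid[okp[1]], neg = neg_grid[okn[1]])
}

#' Select the seed TF: high at the first stage, silent afterwards
#'
#' Scores each TF by `z(T1) - max(z(T2..Tn))` on its stage-mean z-scored
#' profile and returns the maximizer among TFs whose mean TPM at T1 passes
#' the expression floor. Ties break by larger T1 TPM, then lexicographic id.
#'
#' @param tc a [timecourse()].
#' @param tf_set candidate TF ids.
#' @param min_avg_tpm expression floor at T1 (default 0.5).
#' @return a single TF id.
#' @export
select_seed <- function(tc, tf_set, min_avg_tpm = 0.5) {
  stopifnot(inherits(tc, "timecourse"))
  tf_set <- intersect(tf_set, rownames(tc$tpm))
  if (!length(tf_set)) stopf("no candidate TF present in the matrix")
  sm <- stage_mean_mat(tc)[tf_set, , drop = FALSE]
  pass <- sm[, 1] >= min_avg_tpm
  if (!any(pass)) stopf("no TF passes the T1 expression floor")
  sm <- sm[pass, , drop = FALSE]
  z <- t(scale(t(sm)))
  z[is.nan(z)] <- 0                  # constant profiles score 0
  score <- z[, 1] - apply(z[, -1, drop = FALSE], 1, max)
  ord <- order(-score, -sm[, 1], rownames(sm))
  rownames(sm)[ord[1]]
}

#' Breadth-first time-order level assignment from a seed TF
#'
#' TF levels are 1 + the shortest positive-path distance to the seed over
#' TF-TF edges; non-TF genes attach at 1 + the minimum level of their
#' positively linked TFs. Level construction stops after `max_levels` or at
#' the first level (beyond the seed level) whose total membership (TFs +
#' genes) is not above `min_nodes`; that level and everything deeper is
#' discarded. Unreachable nodes stay unassigned.
#'
#' @param gcn a `signed_gcn`.
#' @param seed_tf seed TF id (must be a network node).
#' @param max_levels maximum number of levels (default 8).
#' @param min_nodes minimum members a retained level must exceed (default 20).
#' @return a `level_assignment`: list with `levels` (data.frame id, is_tf,
#'   level), `level_counts` (data.frame level, members, tfs), `seed_tf`.
#' @export
assign_levels <- function(gcn, seed_tf, max_levels = 8L, min_nodes = 20L) {
  stopifnot(inherits(gcn, "signed_gcn"))
  if (!seed_tf %in% gcn$nodes$id) stopf("seed TF '%s' not in network", seed_tf)
  tfs <- gcn$nodes$id[gcn$nodes$is_tf]
  e <- gcn$edges
  pos_tt <- e[e$sign == "+" & e$gene_a %in% tfs & e$gene_b %in% tfs, ,
              drop = FALSE]
  g <- igraph::graph_from_data_frame(pos_tt[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = tfs))
  d <- igraph::distances(g, v = seed_tf)[1, ]
  tf_level <- d + 1
  tf_level[!is.finite(tf_level)] <- NA

  # non-TF genes: 1 + min level over positively linked TFs
  pos_tg <- e[e$sign == "+" & xor(e$gene_a %in% tfs, e$gene_b %in% tfs), ,
              drop = FALSE]
  gene_of <- ifelse(pos_tg$gene_a %in% tfs, pos_tg$gene_b, pos_tg$gene_a)
  tf_of <- ifelse(pos_tg$gene_a %in% tfs, pos_tg$gene_a, pos_tg$gene_b)
  ids <- gcn$nodes$id
  level <- setNames(rep(NA_real_, length(ids)), ids)
  level[names(tf_level)] <- tf_level
  if (nrow(pos_tg)) {
    lv <- tf_level[tf_of]
    gene_level <- tapply(lv, gene_of, function(v)
      if (all(is.na(v))) NA_real_ else 1 + min(v, na.rm = TRUE))
    level[names(gene_level)] <- gene_level
  }
  level[level > max_levels] <- NA

  # node-count floor: truncate at the first thin level beyond the seed level
  if (max_levels >= 2) for (k in 2:max_levels) {
    if (sum(level == k, na.rm = TRUE) <= min_nodes) {
      level[level >= k] <- NA
      break
    }
  }
  keep <- !is.na(level)
  levels_df <- data.frame(id = ids[keep],
                          is_tf = gcn$nodes$is_tf[keep],
                          level = as.integer(level[keep]),
                          stringsAsFactors = FALSE)
  counts <- aggregate(cbind(members = rep(1, nrow(levels_df)),
                            tfs = as.integer(levels_df$is_tf)) ~ level,
                      data = levels_df, FUN = sum)
  structure(list(levels = levels_df, level_counts = counts,
                 seed_tf = seed_tf),
            class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat(sprintf("level assignment from seed %s: %d members over %d levels\n",
              x$seed_tf, nrow(x$levels), nrow(x$level_counts)))
  invisible(x)
}

#' Map time-order levels to developmental stage groups
#'
#' Each level is tagged with the stage at which its mean z-scored profile
#' peaks, then stages are grouped (by default: first stage = initial, next
#' two = transitional, remainder = terminal, matching a five-stage corolla
#' design).
#'
#' @param levels a `level_assignment`.
#' @param tc the [timecourse()] the network was built from.
#' @param stage_groups named list mapping group label -> stage indices.
#' @return list with `level_stage` (data.frame level, peak_stage, group) and
#'   `group_counts` (data.frame group, members, tfs).
#' @export
map_levels_to_stages <- function(levels, tc,
                                 stage_groups = list(initial = 1,
                                                     transitional = 2:3,
                                                     terminal = 4:5)) {
  stopifnot(inherits(levels, "level_assignment"),
            inherits(tc, "timecourse"))
  sm <- stage_mean_mat(tc, log2 = TRUE)
  z <- t(scale(t(sm)))
  grp_of <- function(stage) {
    for (g in names(stage_groups))
      if (stage %in% stage_groups[[g]]) return(g)
    "terminal"
  }
  lv <- sort(unique(levels$levels$level))
  peak <- vapply(lv, function(k) {
    members <- intersect(levels$levels$id[levels$levels$level == k],
                         rownames(z))
    which.max(colMeans(z[members, , drop = FALSE]))
  }, integer(1))
  level_stage <- data.frame(level = lv, peak_stage = peak,
                            group = vapply(peak, grp_of, character(1)),
                            stringsAsFactors = FALSE)
  memb <- merge(levels$levels, level_stage, by = "level")
  gc <- aggregate(cbind(members = rep(1, nrow(memb)),
                        tfs = as.integer(memb$is_tf)) ~ group, data = memb,
                  FUN = sum)
  list(level_stage = level_stage, group_counts = gc)
}
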