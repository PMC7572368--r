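# Hierarchical regulator inference: pathway sub-networks, direct regulators,
# upstream regulator chains, promoter PWM scanning, and binding-site
# filtering of candidate direct regulators.

edge_lookup <- function(gcn) {
  e <- gcn$edges
  setNames(e$r, pair_key(e$gene_a, e$gene_b))
}

level_of <- function(levels) {
  setNames(levels$levels$level, levels$levels$id)
}

#' Pathway sub-network for one stage group
#'
#' Restricts a pathway's enzyme genes to those whose peak expression (stage
#' of maximum z-scored stage-mean profile) falls in `stage_group`, and
#' returns them together with every TF sharing a network edge with them,
#' plus a TF-family tally of the connected regulators.
#'
#' @param gcn a `signed_gcn`.
#' @param levels a `level_assignment`.
#' @param pathway_genes enzyme gene ids of the pathway.
#' @param stage_group one of the group labels of `stage_groups`.
#' @param tc the [timecourse()] (for peak stages).
#' @param family_of named character vector TF id -> family (optional, for
#'   the tally).
#' @param stage_groups group definition as in [map_levels_to_stages()].
#' @return list with `enzymes`, `tfs`, `edges` (induced edge set) and
#'   `family_tally` (named counts; `NA` family as "unknown").
#' @export
pathway_subnetwork <- function(gcn, levels, pathway_genes, stage_group, tc,
                               family_of = NULL,
                               stage_groups = list(initial = 1,
                                                   transitional = 2:3,
                                                   terminal = 4:5)) {
  stopifnot(inherits(gcn, "signed_gcn"), inherits(tc, "timecourse"))
  present <- intersect(pathway_genes, rownames(tc$tpm))
  sm <- stage_mean_mat(tc, log2 = TRUE)[present, , drop = FALSE]
  z <- t(scale(t(sm)))
  z[is.nan(z)] <- 0
  peak <- apply(z, 1, which.max)
  in_group <- names(peak)[peak %in% stage_groups[[stage_group]]]
  enz <- intersect(in_group, gcn$nodes$id)
  if (!length(enz)) {
    warning(sprintf("no pathway gene peaks in stage group '%s'", stage_group))
    return(list(enzymes = character(0), tfs = character(0),
                edges = gcn$edges[0, ], family_tally = integer(0)))
  }
  e <- gcn$edges
  touch <- e$gene_a %in% enz | e$gene_b %in% enz
  sub <- e[touch, , drop = FALSE]
  tf_ids <- gcn$nodes$id[gcn$nodes$is_tf]
  tfs <- unique(c(sub$gene_a, sub$gene_b))
  tfs <- intersect(tfs, tf_ids)
  fam <- if (is.null(family_of)) rep(NA_character_, length(tfs)) else
    family_of[tfs]
  fam[is.na(fam)] <- "unknown"
  tally <- sort(table(fam), decreasing = TRUE)
  list(enzymes = enz, tfs = tfs, edges = sub,
       family_tally = setNames(as.integer(tally), names(tally)))
}

#' Potential direct regulators of a target gene
#'
#' TFs with a positive edge to the target whose level does not exceed the
#' target's (a regulator cannot first appear later than its target), sorted
#' by descending edge correlation. Negative-edge TFs are reported separately
#' as potential repressors (attribute `repressors`).
#'
#' @param gcn a `signed_gcn`.
#' @param levels a `level_assignment` covering the target.
#' @param target target gene id.
#' @param strict require level(TF) < level(target) instead of <= (default
#'   FALSE).
#' @return data.frame tf, level, r (with attribute `repressors`).
#' @export
direct_regulators <- function(gcn, levels, target, strict = FALSE) {
  stopifnot(inherits(gcn, "signed_gcn"))
  lv <- level_of(levels)
  if (is.na(lv[target]))
    stopf("target '%s' has no assigned level", target)
  e <- gcn$edges
  touch <- e[e$gene_a == target | e$gene_b == target, , drop = FALSE]
  other <- ifelse(touch$gene_a == target, touch$gene_b, touch$gene_a)
  tf_ids <- gcn$nodes$id[gcn$nodes$is_tf]
  is_tf <- other %in% tf_ids
  pos <- touch$sign == "+" & is_tf
  neg <- touch$sign == "-" & is_tf
  ok_level <- if (strict) lv[other] < lv[target] else lv[other] <= lv[target]
  ok <- pos & !is.na(ok_level) & ok_level
  out <- data.frame(tf = other[ok], level = as.integer(lv[other[ok]]),
                    r = touch$r[ok], stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "repressors") <- sort(unique(other[neg]))
  out
}

#' Enumerate hierarchical regulator chains up to a maximum order
#'
#' Simple paths `TF_k -> ... -> TF_1 -> target` over positive TF-TF edges
#' with non-decreasing levels toward the target, of length at most
#' `max_order`. Chains are deduplicated and ordered deterministically by the
#' head (most upstream) TF's level, then by descending product of link
#' correlations.
#'
#' @param gcn a `signed_gcn`.
#' @param levels a `level_assignment`.
#' @param target target gene id (needs at least one direct regulator for a
#'   non-empty result).
#' @param max_order maximum chain length in TFs (default 3).
#' @return data.frame target, order, tf_path (comma-separated, most upstream
#'   first), direct_tf, corr_product, head_level.
#' @export
regulator_chains <- function(gcn, levels, target, max_order = 3L) {
  direct <- direct_regulators(gcn, levels, target)
  lv <- level_of(levels)
  e <- gcn$edges
  tf_ids <- gcn$nodes$id[gcn$nodes$is_tf]
  pos_tt <- e[e$sign == "+" & e$gene_a %in% tf_ids & e$gene_b %in% tf_ids, ,
              drop = FALSE]
  nbr <- split(c(pos_tt$gene_b, pos_tt$gene_a),
               c(pos_tt$gene_a, pos_tt$gene_b))
  rmap <- edge_lookup(gcn)
  chains <- list()
  grow <- function(path, rprod) {
    # path: direct regulator first; extend upstream at non-increasing levels
    chains[[length(chains) + 1L]] <<- list(path = path, rprod = rprod)
    if (length(path) >= max_order) return()
    head_tf <- path[length(path)]
    for (up in nbr[[head_tf]] %||% character(0)) {
      if (up %in% path) next
      if (is.na(lv[up]) || lv[up] > lv[head_tf]) next
      grow(c(path, up), rprod * rmap[[pair_key(head_tf, up)]])
    }
  }
  for (i in seq_len(nrow(direct)))
    grow(direct$tf[i], direct$r[i])
  if (!length(chains))
    return(data.frame(target = character(0), order = integer(0),
                      tf_path = character(0), direct_tf = character(0),
                      corr_product = numeric(0), head_level = integer(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    target = target,
    order = vapply(chains, function(c) length(c$path), integer(1)),
    tf_path = vapply(chains, function(c)
      paste(rev(c$path), collapse = ","), character(1)),
    direct_tf = vapply(chains, function(c) c$path[1], character(1)),
    corr_product = vapply(chains, function(c) c$rprod, numeric(1)),
    stringsAsFactors = FALSE)
  out$head_level <- as.integer(lv[vapply(chains, function(c)
    c$path[length(c$path)], character(1))])
  out <- out[!duplicated(out$tf_path), , drop = FALSE]
  out <- out[order(out$head_level, -out$corr_product, out$tf_path), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# log-odds score matrix of a PWM: log2 of (pseudocounted column frequency /
# background), pseudocount 0.01 per cell
pwm_score_matrix <- function(pwm) {
  counts <- pwm$counts + 0.01
  freq <- sweep(counts, 2, colSums(counts), "/")
  log2(freq / pwm$bg)
}

#' Scan a promoter with a PWM on both strands
#'
#' Log-odds scoring against the PWM background with pseudocount 0.01; a hit
#' is any offset (either strand) whose score reaches `threshold` times the
#' maximal achievable score. Overlapping hits are all reported. Offsets are
#' 0-based positions of the site's leftmost base on the forward strand.
#'
#' @param promoter sequence over A,C,G,T.
#' @param pwm a `pwm` object.
#' @param threshold fraction of the maximum score in (0, 1] (default 0.85).
#' @param gene optional promoter owner id copied into the result.
#' @return data.frame gene, motif_id, offset, strand, score (possibly empty;
#'   a promoter shorter than the motif yields an empty result).
#' @export
pwm_scan <- function(promoter, pwm, threshold = 0.85, gene = NA_character_) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  promoter <- toupper(promoter)
  if (grepl("[^ACGT]", promoter)) stopf("promoter must be over {A,C,G,T}")
  sm <- pwm_score_matrix(pwm)
  w <- ncol(sm)
  L <- nchar(promoter)
  empty <- data.frame(gene = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  # tiny slack so an exact-consensus site passes threshold = 1 despite
  # floating-point summation order
  cutoff <- threshold * sum(apply(sm, 2, max)) - 1e-9
  scan_one <- function(seq) {
    nt <- match(strsplit(seq, "")[[1]], NUCS)
    n_off <- L - w + 1L
    sc <- numeric(n_off)
    for (j in seq_len(w)) sc <- sc + sm[cbind(nt[j:(j + n_off - 1L)], j)]
    sc
  }
  fwd <- scan_one(promoter)
  rev_ <- scan_one(revcomp(promoter))
  hits_f <- which(fwd >= cutoff)
  hits_r <- which(rev_ >= cutoff)
  out <- rbind(
    if (length(hits_f))
      data.frame(gene = gene, motif_id = pwm$id, offset = hits_f - 1L,
                 strand = "+", score = fwd[hits_f], stringsAsFactors = FALSE),
    if (length(hits_r))
      data.frame(gene = gene, motif_id = pwm$id,
                 offset = L - w + 1L - hits_r,   # reflect to forward coords
                 strand = "-", score = rev_[hits_r], stringsAsFactors = FALSE))
  if (is.null(out)) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters with a set of PWMs
#'
#' @param promoters named character vector (gene -> promoter sequence).
#' @param pwm_set named list of `pwm` objects.
#' @param threshold fraction-of-maximum score threshold (default 0.85).
#' @return data.frame gene, motif_id, family, offset, strand, score.
#' @export
scan_promoters <- function(promoters, pwm_set, threshold = 0.85) {
  res <- list()
  for (g in names(promoters)) {
    for (pwm in pwm_set) {
      h <- pwm_scan(promoters[[g]], pwm, threshold, gene = g)
      if (nrow(h)) {
        h$family <- pwm$family
        res[[length(res) + 1L]] <- h
      }
    }
  }
  if (!length(res))
    return(data.frame(gene = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), family = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate regulator chains with promoter binding support
#'
#' A chain's direct link is binding-supported when the target's promoter has
#' at least one hit for a PWM of the direct regulator's family. When at least
#' one supported chain exists for a target, unsupported chains of that target
#' are flagged as demoted (kept, not deleted). TFs without a family label are
#' flagged "unknown-family" and never supported.
#'
#' @param chains data.frame from [regulator_chains()] (possibly several
#'   targets concatenated).
#' @param hits data.frame from [scan_promoters()] (gene = promoter owner).
#' @param family_of named character vector TF id -> family.
#' @return `chains` with added columns `direct_family`, `supported`,
#'   `demoted`, `flag`.
#' @export
filter_chains_by_binding <- function(chains, hits, family_of) {
  if (!nrow(chains)) {
    chains$direct_family <- character(0)
    chains$supported <- logical(0)
    chains$demoted <- logical(0)
    chains$flag <- character(0)
    return(chains)
  }
  fam <- family_of[chains$direct_tf]
  hit_key <- unique(paste(hits$gene, hits$family, sep = "|"))
  supported <- !is.na(fam) &
    paste(chains$target, fam, sep = "|") %in% hit_key
  flag <- ifelse(is.na(fam), "unknown-family", "")
  demoted <- rep(FALSE, nrow(chains))
  for (tg in unique(chains$target)) {
    i <- chains$target == tg
    if (any(supported[i])) demoted[i & !supported] <- TRUE
  }
  chains$direct_family <- unname(fam)
  chains$supported <- supported
  chains$demoted <- demoted
  chains$flag <- flag
  chains
}
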