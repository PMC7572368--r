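# Hypergeometric functional enrichment with Benjamini-Hochberg correction,
# and the ratio/composition reports used throughout the results.

#' Upper-tail hypergeometric enrichment of a study set
#'
#' For each term, tests over-representation of the term's genes in the study
#' set against the background universe: `p = P(X >= k)` with `X`
#' hypergeometric(N = |background|, K = term genes in background,
#' n = |study|). P-values are BH-adjusted across all tested terms; terms with
#' no background annotation are skipped.
#'
#' @param study study gene set (must be a subset of `background`).
#' @param annotation data.frame gene_id, term_id.
#' @param background background gene universe.
#' @param alpha adjusted-p threshold flagged in the `enriched` column
#'   (default 0.001).
#' @return data.frame term_id, k, n, K, N, p, p_adj, enriched; the full table
#'   is always returned, sorted by p.
#' @export
hypergeom_enrichment <- function(study, annotation, background,
                                 alpha = 0.001) {
  study <- unique(study); background <- unique(background)
  bad <- setdiff(study, background)
  if (length(bad))
    stopf("study genes outside background: %s",
          paste(head(bad, 10), collapse = ", "))
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(study)
  terms <- split(unique(ann[c("gene_id", "term_id")])$gene_id,
                 unique(ann[c("gene_id", "term_id")])$term_id)
  if (!length(terms))
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), enriched = logical(0)))
  K <- vapply(terms, length, integer(1))
  k <- vapply(terms, function(g) length(intersect(g, study)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(terms), k = k, n = n, K = K, N = N,
                    p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  out$enriched <- out$p_adj < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH FDR adjustment (order-preserving, monotone, clipped at 1).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Ratio statistic with half-up rounding
#'
#' @param numerator,denominator non-negative counts, numerator <=
#'   denominator, denominator > 0.
#' @param decimals digits of the printed percentage (default 2).
#' @param label optional label.
#' @return list(label, numerator, denominator, percentage).
#' @export
proportion <- function(numerator, denominator, decimals = 2, label = NULL) {
  if (denominator <= 0) stopf("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stopf("numerator must lie in [0, denominator]")
  list(label = label, numerator = numerator, denominator = denominator,
       percentage = round_half_up(100 * numerator / denominator, decimals))
}

#' Stage-group composition of a leveled network
#'
#' Members and TF sub-counts per stage group, plus grand totals
#' (total members = TFs + structural genes).
#'
#' @param levels a `level_assignment`.
#' @param stage_map result of [map_levels_to_stages()].
#' @return list with `by_group` (data.frame group, members, tfs,
#'   structural) and `total` (named vector members, tfs, structural).
#' @export
network_composition_report <- function(levels, stage_map) {
  bg <- stage_map$group_counts
  bg$structural <- bg$members - bg$tfs
  total <- c(members = sum(bg$members), tfs = sum(bg$tfs),
             structural = sum(bg$structural))
  list(by_group = bg, total = total)
}
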