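# End-to-end conveniences: synthesize a full study and run the TO-GCN chain.

#' Synthesize a complete study with planted ground truth
#'
#' Runs every generator under one configuration: gene catalog with planted
#' duplication modes, staged time course with a planted TF cascade, one PWM
#' per TF family, promoters with planted binding sites, and annotations with
#' planted enrichment (one enriched term per pathway tag by default).
#'
#' @param config a [synthetic_config()].
#' @param n_terms number of annotation terms (default 50).
#' @return list with `catalog`, `pairs`, `anchors`, `tc`, `pwms`,
#'   `promoters`, `annotations`, and merged `truth`.
#' @export
synthesize_study <- function(config, n_terms = 50L) {
  gen <- generate_genome(config)
  tcg <- generate_timecourse(config, gen$catalog)
  pwms <- generate_pwms(width = config$motif_length, seed = config$seed + 2L)
  prom <- generate_promoters(gen$catalog, pwms, tcg$truth,
                             seed = config$seed + 3L)
  # plant one enriched term per pathway: its study set is the pathway's genes
  paths <- setdiff(unique(gen$catalog$pathway_tag), "none")
  enr <- setNames(lapply(paths, function(p)
    gen$catalog$gene_id[gen$catalog$pathway_tag == p]),
    sprintf("TERM%04d", seq_along(paths)))
  ann <- generate_annotations(gen$catalog, n_terms, enr,
                              seed = config$seed + 4L)
  list(catalog = gen$catalog, pairs = gen$pairs, anchors = gen$anchors,
       tc = tcg$tc, pwms = pwms, promoters = prom$promoters,
       annotations = ann$annotations,
       truth = c(gen$truth, tcg$truth,
                 list(motif_sites = prom$sites,
                      enriched_terms = ann$truth$enriched_terms,
                      enriched_study_sets = enr)))
}

#' Run the TO-GCN chain on a time course
#'
#' Expression filter, differential gate, signed Pearson network over the
#' differentially expressed TFs and genes, seed selection, breadth-first
#' level assignment, and level -> stage-group mapping.
#'
#' @param tc a [timecourse()].
#' @param pos_cutoff,neg_cutoff signed edge cutoffs (defaults 0.81, -0.57).
#' @param min_avg_tpm expression floor (default 0.5).
#' @param de_genes optional pre-computed DE gene ids (bypasses the built-in
#'   Welch gate).
#' @param seed_tf optional seed TF id (default: selected by [select_seed()]).
#' @param max_levels,min_nodes level construction bounds (defaults 8, 20).
#' @return list with `tc` (filtered), `de_genes`, `gcn`, `seed_tf`,
#'   `levels`, `stage_map`.
#' @export
run_togcn <- function(tc, pos_cutoff = 0.81, neg_cutoff = -0.57,
                      min_avg_tpm = 0.5, de_genes = NULL, seed_tf = NULL,
                      max_levels = 8L, min_nodes = 20L) {
  tcf <- suppressMessages(filter_expressed(tc, min_avg_tpm))
  if (is.null(de_genes)) de_genes <- differential_genes(tcf)
  de_genes <- intersect(de_genes, rownames(tcf$tpm))
  tfs <- de_genes[tcf$is_tf[de_genes]]
  genes <- setdiff(de_genes, tfs)
  gcn <- pearson_network(tcf, tfs, genes, pos_cutoff, neg_cutoff)
  if (is.null(seed_tf)) seed_tf <- select_seed(tcf, tfs, min_avg_tpm)
  levels <- assign_levels(gcn, seed_tf, max_levels, min_nodes)
  stage_map <- map_levels_to_stages(levels, tcf)
  list(tc = tcf, de_genes = de_genes, gcn = gcn, seed_tf = seed_tf,
       levels = levels, stage_map = stage_map)
}
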