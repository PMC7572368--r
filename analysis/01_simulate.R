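#!/usr/bin/env Rscript
# Step 1 — synthesize the study inputs with planted ground truth.
#
# Emits every file the downstream steps consume: a 13-chromosome gene catalog
# with planted duplication modes, homolog pairs and collinear anchors, a
# 5-stage x 5-replicate corolla-style TPM time course with a planted 8-level
# TF cascade, family PWMs, 2-kb promoters with planted binding sites, and
# gene-to-term annotations with planted enrichment.

suppressPackageStartupMessages(library(azaleanet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
cfg <- synthetic_config(seed = seed)
print(cfg)
study <- synthesize_study(cfg)

write_catalog(study$catalog, "results/inputs/catalog.tsv")
write.table(study$pairs, "results/inputs/pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(study$anchors, "results/inputs/anchors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_expression(study$tc, "results/inputs/expression.tsv")
write_fasta(study$promoters, "results/inputs/promoters.fa")
write_pwms(study$pwms, "results/inputs/pwms.txt")
write.table(study$annotations, "results/inputs/annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_report_json(
  list(seed = seed,
       mode_by_pair = study$truth$mode_by_pair,
       level_by_tf = as.list(study$truth$level_by_tf),
       seed_candidates = study$truth$seed_candidates,
       chains = study$truth$chains,
       motif_sites = study$truth$motif_sites,
       enriched_terms = study$truth$enriched_terms,
       enriched_study_sets = study$truth$enriched_study_sets,
       low_expr_genes = study$truth$low_expr_genes),
  "results/inputs/truth.json")

cat(sprintf("catalog: %d genes on %d chromosomes (%d TFs, %d pathway genes)\n",
            nrow(study$catalog), length(unique(study$catalog$chrom)),
            sum(study$catalog$is_tf),
            sum(study$catalog$pathway_tag != "none")))
cat(sprintf("planted: %d homolog pairs (%s), %d cascade TFs over %d levels,\n",
            nrow(study$pairs),
            paste(names(table(study$truth$mode_by_pair$mode)),
                  table(study$truth$mode_by_pair$mode),
                  sep = "=", collapse = " "),
            length(study$truth$level_by_tf), cfg$n_levels))
cat(sprintf("         %d regulator chains, %d promoter motif sites, %d enriched terms\n",
            length(study$truth$chains), nrow(study$truth$motif_sites),
            length(study$truth$enriched_terms)))
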