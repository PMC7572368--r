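#!/usr/bin/env Rscript
# Step 5 — hierarchical regulator inference with promoter binding evidence.
#
# Extracts the pigment-pathway sub-network of the initial stage group, scans
# the 2-kb promoters with the family PWMs, enumerates first- to third-order
# upstream regulator chains for a panel of enzyme targets, and keeps the
# direct regulators whose family has a binding site in the target's promoter.

suppressPackageStartupMessages(library(azaleanet))
dir.create("results/regulators", recursive = TRUE, showWarnings = FALSE)

catalog <- read_catalog("results/inputs/catalog.tsv")
tc <- read_expression("results/inputs/expression.tsv",
                      tf_ids = catalog$gene_id[catalog$is_tf])
promoters <- read_fasta("results/inputs/promoters.fa")
pwms <- read_pwms("results/inputs/pwms.txt")
truth <- jsonlite::read_json("results/inputs/truth.json",
                             simplifyVector = TRUE)
fam_of <- setNames(catalog$tf_family, catalog$gene_id)

res <- run_togcn(tc)
antho <- catalog$gene_id[catalog$pathway_tag == "anthocyanin"]
sub <- pathway_subnetwork(res$gcn, res$levels, antho, "initial", res$tc,
                          family_of = fam_of)
cat(sprintf("initial-stage anthocyanin sub-network: %d enzymes, %d TFs\n",
            length(sub$enzymes), length(sub$tfs)))
cat("TF family tally of connected regulators:\n")
print(sub$family_tally)

hits <- scan_promoters(promoters, pwms, threshold = 1.0)
cat(sprintf("promoter scan: %d hits across %d promoters (planted: %d)\n",
            nrow(hits), length(promoters), nrow(truth$motif_sites)))
write.table(hits, "results/regulators/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# chains for the first few planted enzyme targets present in the network
lv <- setNames(res$levels$levels$level, res$levels$levels$id)
targets <- vapply(seq_len(nrow(truth$chains)), function(i)
  truth$chains$target[i], "")
targets <- head(intersect(targets, names(lv)), 5)
all_chains <- NULL
for (tg in targets) {
  ch <- regulator_chains(res$gcn, res$levels, tg)
  ann <- filter_chains_by_binding(ch, hits, fam_of)
  cat(sprintf("%s: %d chains (orders %s), %d binding-supported direct TFs\n",
              tg, nrow(ann), paste(range(ann$order), collapse = "-"),
              length(unique(ann$direct_tf[ann$supported]))))
  all_chains <- rbind(all_chains,
                      ann[ann$supported | ann$order > 1, ][
                        seq_len(min(200, nrow(ann))), ])
}
write.table(all_chains, "results/regulators/chains.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_report_json(list(family_tally = as.list(sub$family_tally),
                       n_hits = nrow(hits),
                       targets_examined = targets),
                  "results/regulators/report.json")
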