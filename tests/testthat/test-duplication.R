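# Collinear chaining and the WGD/TD/PD/TRD/DSD priority rules.

toy_catalog <- function(n_per_chrom, chroms = c("chr01", "chr02")) {
  do.call(rbind, lapply(chroms, function(c) data.frame(
    gene_id = paste0(c, "_g", seq_len(n_per_chrom)),
    chrom = c, start = (seq_len(n_per_chrom) - 1) * 1000,
    end = (seq_len(n_per_chrom) - 1) * 1000 + 500, strand = "+",
    rank = seq_len(n_per_chrom) - 1L, is_tf = FALSE,
    tf_family = NA_character_, pathway_tag = "none",
    stringsAsFactors = FALSE)))
}

test_that("six consecutive collinear pairs chain into one block", {
  cat <- toy_catalog(10)
  pairs <- data.frame(gene_a = paste0("chr01_g", 1:6),
                      gene_b = paste0("chr02_g", 1:6))
  blocks <- chain_synteny(pairs, cat)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 6)
  expect_equal(blocks[[1]]$orientation, "same")
  # inverted orientation also chains
  pairs2 <- data.frame(gene_a = paste0("chr01_g", 1:6),
                       gene_b = paste0("chr02_g", 6:1))
  blocks2 <- chain_synteny(pairs2, cat)
  expect_length(blocks2, 1)
  expect_equal(blocks2[[1]]$orientation, "inverted")
})

test_that("chains below min_anchors yield no blocks; empty input is fine", {
  cat <- toy_catalog(10)
  pairs <- data.frame(gene_a = paste0("chr01_g", 1:4),
                      gene_b = paste0("chr02_g", 1:4))
  expect_length(chain_synteny(pairs, cat, min_anchors = 5), 0)
  expect_length(chain_synteny(pairs[0, ], cat), 0)
  expect_error(chain_synteny(data.frame(gene_a = "nope", gene_b = "chr01_g1"),
                             cat), "unknown")
})

test_that("block extraction matches exhaustive maximal-chain search", {
  cat <- toy_catalog(60)
  for (seed in 1:4) {
    set.seed(seed)
    n <- 18
    ra <- sort(sample(0:59, n))
    rb <- sample(0:59, n)
    pairs <- data.frame(gene_a = paste0("chr01_g", ra + 1),
                        gene_b = paste0("chr02_g", rb + 1))
    got <- chain_synteny(pairs, cat, min_anchors = 4, max_rank_gap = 25)
    expect_equal(length(got),
                 oracle_block_count(ra, rb, min_anchors = 4, max_gap = 25),
                 info = paste("seed", seed))
  }
})

test_that("rank-distance rules separate TD, PD and DSD", {
  cat <- toy_catalog(40)
  pairs <- data.frame(
    gene_a = c("chr01_g8", "chr01_g4", "chr01_g4", "chr01_g4"),
    gene_b = c("chr01_g9", "chr01_g10", "chr01_g13", "chr01_g31"))
  asg <- classify_duplicates(cat, pairs, list())
  # ranks 7-8 adjacent -> TD; gap 6 -> PD; gap 9 (< 10) -> PD; gap 27 -> DSD
  expect_equal(asg$pairs$mode, c("TD", "PD", "PD", "DSD"))
  expect_error(classify_duplicates(cat, data.frame(gene_a = "zz",
                                                   gene_b = "chr01_g1"),
                                   list()), "unknown")
})

test_that("adding a block promotes a pair to WGD, never demotes", {
  cat <- toy_catalog(40)
  anchors <- data.frame(gene_a = paste0("chr01_g", 1:5),
                        gene_b = paste0("chr02_g", 1:5))
  pairs <- rbind(anchors,
                 data.frame(gene_a = "chr01_g3", gene_b = "chr02_g20"))
  no_blocks <- classify_duplicates(cat, pairs, list())
  expect_true(all(no_blocks$pairs$mode == "DSD"))
  blocks <- chain_synteny(pairs, cat)
  with_blocks <- classify_duplicates(cat, pairs, blocks)
  expect_equal(with_blocks$pairs$mode[1:5], rep("WGD", 5))
  # one anchored member -> transposed
  expect_equal(with_blocks$pairs$mode[6], "TRD")
  prio <- c(WGD = 1, TD = 2, PD = 3, TRD = 4, DSD = 5)
  expect_true(all(prio[with_blocks$pairs$mode] <= prio[no_blocks$pairs$mode]))
})

test_that("a gene in several pairs takes its highest-priority mode", {
  cat <- toy_catalog(40)
  pairs <- data.frame(gene_a = c("chr01_g5", "chr01_g5"),
                      gene_b = c("chr01_g6", "chr01_g20"))
  asg <- classify_duplicates(cat, pairs, list())
  g <- asg$genes[asg$genes$gene_id == "chr01_g5", ]
  expect_equal(g$mode, "TD")
  expect_equal(g$partner, "chr01_g6")
  # partition: each duplicated gene exactly one mode; singletons in no pair
  dup <- asg$genes$mode != "singleton"
  expect_setequal(asg$genes$gene_id[dup],
                  unique(c(pairs$gene_a, pairs$gene_b)))
})

test_that("classification equals the rule oracle and recovers planted modes", {
  cfg <- synthetic_config(seed = 5)
  g <- generate_genome(cfg)
  blocks <- chain_synteny(g$pairs, g$catalog)
  asg <- classify_duplicates(g$catalog, g$pairs, blocks)
  anchored <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))
  expect_equal(asg$pairs$mode,
               oracle_classify_pairs(g$catalog, asg$pairs, anchored))
  truth <- setNames(g$truth$mode_by_pair$mode,
                    pkey(g$truth$mode_by_pair$gene_a,
                         g$truth$mode_by_pair$gene_b))
  got <- setNames(asg$pairs$mode, pkey(asg$pairs$gene_a, asg$pairs$gene_b))
  expect_equal(unname(got[names(truth)]), unname(truth))
})

test_that("relabeling gene ids leaves mode counts unchanged", {
  cfg <- synthetic_config(seed = 6, genes_per_chromosome = 30,
                          n_chromosomes = 8, tfs_per_level = 4,
                          targets_per_level = 2, n_background_tfs = 2)
  g <- generate_genome(cfg)
  blocks <- chain_synteny(g$pairs, g$catalog)
  asg <- classify_duplicates(g$catalog, g$pairs, blocks)
  relabel <- setNames(paste0("X", seq_len(nrow(g$catalog))),
                      g$catalog$gene_id)
  cat2 <- g$catalog; cat2$gene_id <- relabel[cat2$gene_id]
  pairs2 <- data.frame(gene_a = relabel[g$pairs$gene_a],
                       gene_b = relabel[g$pairs$gene_b])
  asg2 <- classify_duplicates(cat2, pairs2, chain_synteny(pairs2, cat2))
  expect_equal(table(asg2$pairs$mode), table(asg$pairs$mode))
  expect_equal(table(asg2$genes$mode), table(asg$genes$mode))
})

test_that("mode proportions reproduce the published desk arithmetic", {
  mp <- mode_proportions(c(WGD = 6056, TD = 4746, PD = 3732, TRD = 6399,
                           DSD = 8463), 32999)
  expect_equal(mp$percentage, c(18.4, 14.4, 11.3, 19.4, 25.6))
  expect_equal(sum(mp$count), 29396)
  expect_error(mode_proportions(c(WGD = 10), 0), "positive")
  # degenerate: one mode holding every gene
  expect_equal(mode_proportions(c(WGD = 32999), 32999)$percentage[1], 100.0)
})

test_that("TD+PD fractions of gene sets match the printed ratios", {
  cat <- toy_catalog(40)
  pairs <- data.frame(gene_a = paste0("chr01_g", seq(1, 40, 2)[1:13]),
                      gene_b = paste0("chr01_g", seq(2, 40, 2)[1:13]))
  asg <- classify_duplicates(cat, pairs, list())   # 13 TD pairs = 26 TD genes
  tdpd <- asg$genes$gene_id[asg$genes$mode == "TD"]
  singles <- asg$genes$gene_id[asg$genes$mode == "singleton"]
  s1 <- c(tdpd[1:10], singles[1:9])
  expect_equal(set_td_pd_fraction(asg, s1)$percentage, 52.63)   # 10/19
  s2 <- c(tdpd[1:16], singles[1:17])
  expect_equal(set_td_pd_fraction(asg, s2)$percentage, 48.48)   # 16/33
  expect_equal(set_td_pd_fraction(asg, singles[1:5])$percentage, 0)
  expect_error(set_td_pd_fraction(asg, character(0)), "non-empty")
})

test_that("EGF overlaps equal direct set algebra", {
  cfg <- synthetic_config(seed = 8)
  g <- generate_genome(cfg)
  asg <- classify_duplicates(g$catalog, g$pairs,
                             chain_synteny(g$pairs, g$catalog))
  set.seed(1)
  egf <- sample(g$catalog$gene_id, 100)
  ov <- egf_mode_overlap(egf, asg)
  for (m in c("WGD", "TD", "PD", "TRD", "DSD")) {
    expect_equal(ov$counts[[m]],
                 length(intersect(egf,
                                  asg$genes$gene_id[asg$genes$mode == m])))
  }
  expect_equal(egf_mode_overlap(character(0), asg)$counts[["WGD"]], 0)
  td <- asg$genes$gene_id[asg$genes$mode == "TD"]
  expect_equal(egf_mode_overlap(td, asg)$td_pd_share, 100)
})
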