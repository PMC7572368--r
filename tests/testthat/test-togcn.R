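# TO-GCN construction: expression filter, DE gate, signed network, seed
# selection, BFS levels, stage mapping.

toy_tc <- function(profiles, n_rep = 3, noise = 0, seed = 1, tfs = NULL) {
  # profiles: named list gene -> per-stage mean TPM vector
  n_stage <- length(profiles[[1]])
  design <- data.frame(
    sample = paste0("T", rep(seq_len(n_stage), each = n_rep),
                    "_R", rep(seq_len(n_rep), n_stage)),
    stage = rep(seq_len(n_stage), each = n_rep),
    replicate = rep(seq_len(n_rep), n_stage))
  set.seed(seed)
  m <- do.call(rbind, lapply(profiles, function(p)
    pmax(rep(p, each = n_rep) + rnorm(n_stage * n_rep, 0, noise), 0)))
  rownames(m) <- names(profiles)
  timecourse(m, design, setNames(names(profiles) %in% (tfs %||% character(0)),
                                 names(profiles)))
}

test_that("the average-TPM filter keeps the boundary and logs removals", {
  tc <- toy_tc(list(lo = rep(0.4, 5), hi = rep(0.6, 5),
                    edge = rep(0.5, 5)), n_rep = 2)
  out <- suppressMessages(filter_expressed(tc))
  expect_setequal(rownames(out$tpm), c("hi", "edge"))
  expect_equal(attr(out, "removed"), 1)
  # zero floor is the identity
  all_kept <- suppressMessages(filter_expressed(tc, 0))
  expect_equal(nrow(all_kept$tpm), 3)
  # removal count equals direct recomputation on a random matrix
  set.seed(2)
  prof <- setNames(lapply(1:50, function(i) runif(5, 0, 2)),
                   paste0("g", 1:50))
  tc2 <- toy_tc(prof, n_rep = 2)
  out2 <- suppressMessages(filter_expressed(tc2))
  expect_equal(attr(out2, "removed"), sum(rowMeans(tc2$tpm) < 0.5))
})

test_that("the DE gate needs variation and respects replicate requirements", {
  flat <- toy_tc(setNames(lapply(1:10, function(i) rep(5, 5)),
                          paste0("g", 1:10)), n_rep = 3, noise = 0.1)
  expect_length(differential_genes(flat), 0)
  # noiseless 8-fold step between stages is always called
  step <- toy_tc(list(de = c(1, 1, 1, 1, 8), flat = rep(2, 5)), n_rep = 3)
  expect_equal(differential_genes(step), "de")
  one_rep <- timecourse(matrix(1:5, 1, 5, dimnames = list("g1", paste0(
    "T", 1:5, "_R1"))), data.frame(sample = paste0("T", 1:5, "_R1"),
    stage = 1:5, replicate = 1), c(g1 = FALSE))
  expect_error(differential_genes(one_rep), "replicates")
})

test_that("the DE gate is calibrated on planted signal", {
  recalls <- c(); fdrs <- c()
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200; n_de <- 20
    prof <- c(lapply(seq_len(n_de), function(i) c(2, 2, 2, 2, 2) *
                       c(1, 1, 1, 1, 8)),      # planted 8-fold late step
              lapply(seq_len(n - n_de), function(i) rep(runif(1, 1, 4), 5)))
    names(prof) <- paste0("g", seq_len(n))
    tc <- toy_tc(prof, n_rep = 5, noise = 0.5, seed = seed + 100)
    de <- differential_genes(tc)
    truth <- paste0("g", seq_len(n_de))
    recalls <- c(recalls, length(intersect(de, truth)) / n_de)
    fdrs <- c(fdrs, if (length(de)) mean(!(de %in% truth)) else 0)
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(fdrs), 0.1)
})

test_that("signed edges respect cutoffs, exclude self and constant genes", {
  tc <- toy_tc(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
                    anti = c(5, 4, 3, 2, 1), const = rep(2, 5)),
               n_rep = 2, tfs = c("a", "anti", "const"))
  gcn <- pearson_network(tc, c("a", "anti", "const"), c("b"))
  k <- pkey(gcn$edges$gene_a, gcn$edges$gene_b)
  expect_true(pkey("a", "b") %in% k)
  expect_true(pkey("a", "anti") %in% k)
  expect_equal(gcn$edges$sign[k == pkey("a", "anti")], "-")
  expect_false(any(gcn$edges$gene_a == gcn$edges$gene_b))
  expect_false(any(grepl("const", k)))
  # stored r values match recomputation to 1e-9
  x <- log2(tc$tpm + 1)
  for (i in seq_len(nrow(gcn$edges)))
    expect_equal(gcn$edges$r[i],
                 cor(x[gcn$edges$gene_a[i], ], x[gcn$edges$gene_b[i], ]),
                 tolerance = 1e-9)
  expect_error(pearson_network(toy_tc(list(a = 1:2, b = 2:1), n_rep = 1),
                               "a", "b"), "3 samples")
})

test_that("tightening cutoffs never adds edges", {
  cfg <- synthetic_config(seed = 31, genes_per_chromosome = 30,
                          n_chromosomes = 6, tfs_per_level = 3,
                          targets_per_level = 2, n_background_tfs = 2,
                          dup_mode_fractions = c(WGD = 0))
  study <- synthesize_study(cfg)
  tc <- suppressMessages(filter_expressed(study$tc))
  tfs <- rownames(tc$tpm)[tc$is_tf[rownames(tc$tpm)]]
  genes <- setdiff(rownames(tc$tpm), tfs)
  loose <- pearson_network(tc, tfs, genes, 0.81, -0.57)
  tight <- pearson_network(tc, tfs, genes, 0.85, -0.70)
  expect_true(all(pkey(tight$edges$gene_a, tight$edges$gene_b) %in%
                  pkey(loose$edges$gene_a, loose$edges$gene_b)))
  expect_true(all(abs(loose$edges$r) >= 0.57))
})

test_that("permutation calibration suggests usable cutoffs", {
  # pure noise: flat profiles, so any correlation is a sampling artifact
  set.seed(4)
  prof <- setNames(lapply(1:40, function(i) rep(runif(1, 4, 16), 5)),
                   paste0("g", 1:40))
  noise_tc <- toy_tc(prof, n_rep = 5, noise = 2, seed = 5)
  tfs <- paste0("g", 1:15); genes <- paste0("g", 16:40)
  cuts <- suppressWarnings(suggest_cutoffs(noise_tc, tfs, genes,
                                           n_permutations = 60, seed = 1))
  gcn <- pearson_network(noise_tc, tfs, genes, cuts["pos"], cuts["neg"])
  expect_lte(nrow(gcn$edges), 2)
  # planted cascade: the suggested positive cutoff admits planted edges
  cfg <- synthetic_config(seed = 32)
  study <- synthesize_study(cfg)
  tcf <- suppressMessages(filter_expressed(study$tc))
  casc <- names(study$truth$level_by_tf)
  cuts2 <- suggest_cutoffs(tcf, casc, character(0), n_permutations = 30,
                           seed = 2)
  expect_lte(cuts2[["pos"]], 0.81)
  expect_identical(cuts2, suggest_cutoffs(tcf, casc, character(0),
                                          n_permutations = 30, seed = 2))
  expect_error(suggest_cutoffs(tcf, casc, character(0), n_permutations = 5),
               "10 permutations")
})

test_that("seed selection prefers first-stage-only expression", {
  tc <- toy_tc(list(spike = c(10, 0.1, 0.1, 0.1, 0.1),
                    flat1 = rep(3, 5), flat2 = rep(4, 5),
                    late = c(0.1, 0.1, 0.1, 0.1, 10)),
               n_rep = 2, tfs = c("spike", "flat1", "flat2", "late"))
  expect_equal(select_seed(tc, c("spike", "flat1", "flat2", "late")), "spike")
  # tie between identical candidates: lexicographically smaller id
  tc2 <- toy_tc(list(b_tf = c(8, 1, 1, 1, 1), a_tf = c(8, 1, 1, 1, 1)),
                n_rep = 2, tfs = c("a_tf", "b_tf"))
  expect_equal(select_seed(tc2, c("b_tf", "a_tf")), "a_tf")
  low <- toy_tc(list(weak = c(0.2, 0.1, 0.1, 0.1, 0.1)), n_rep = 2,
                tfs = "weak")
  expect_error(select_seed(low, "weak"), "floor")
})

test_that("BFS levels follow shortest positive paths from the seed", {
  edges <- data.frame(gene_a = c("s", "b", "s", "c"),
                      gene_b = c("b", "c", "x", "x"),
                      r = c(0.9, 0.9, 0.95, 0.9),
                      sign = "+", stringsAsFactors = FALSE)
  gcn <- structure(list(
    nodes = data.frame(id = c("s", "b", "c", "x"), is_tf = TRUE),
    edges = edges, cutoffs = c(pos = 0.81, neg = -0.57)),
    class = "signed_gcn")
  lv <- assign_levels(gcn, "s", max_levels = 8, min_nodes = 0)
  got <- setNames(lv$levels$level, lv$levels$id)
  # chain s -> b -> c plus shortcut s -> x: x at level 2 despite the c-x edge
  expect_equal(got[["s"]], 1)
  expect_equal(got[["b"]], 2)
  expect_equal(got[["c"]], 3)
  expect_equal(got[["x"]], 2)
  expect_error(assign_levels(gcn, "nope"), "not in network")
})

test_that("level construction stops at a thin level and discards it", {
  # s - a1..a25 (level 2 rich), then a single level-3 TF: floor cuts it
  ids <- c("s", paste0("a", 1:25), "deep")
  edges <- rbind(
    data.frame(gene_a = "s", gene_b = paste0("a", 1:25), r = 0.9, sign = "+"),
    data.frame(gene_a = "a1", gene_b = "deep", r = 0.9, sign = "+"))
  gcn <- structure(list(nodes = data.frame(id = ids, is_tf = TRUE),
                        edges = edges, cutoffs = c(pos = 0.81, neg = -0.57)),
                   class = "signed_gcn")
  lv <- assign_levels(gcn, "s", max_levels = 8, min_nodes = 20)
  expect_false("deep" %in% lv$levels$id)
  expect_equal(max(lv$levels$level), 2)
})

test_that("planted cascade levels are recovered within one", {
  cfg <- synthetic_config(seed = 33)
  study <- synthesize_study(cfg)
  res <- run_togcn(study$tc)
  expect_true(res$seed_tf %in% study$truth$seed_candidates)
  lv <- setNames(res$levels$levels$level, res$levels$levels$id)
  tl <- study$truth$level_by_tf
  common <- intersect(names(tl), names(lv))
  expect_gte(length(common) / length(tl), 0.9)
  expect_gte(mean(abs(lv[common] - tl[common]) <= 1), 0.9)
  # level soundness: every level-k TF (k > 1) has a positive edge one level up
  tf_lv <- lv[res$levels$levels$id[res$levels$levels$is_tf]]
  pos <- res$gcn$edges[res$gcn$edges$sign == "+", ]
  for (tf in names(tf_lv)[tf_lv > 1]) {
    nb <- c(pos$gene_b[pos$gene_a == tf], pos$gene_a[pos$gene_b == tf])
    expect_true(any(lv[intersect(nb, names(tf_lv))] == tf_lv[tf] - 1),
                info = tf)
  }
})

test_that("levels map to stage groups monotonically on a planted cascade", {
  cfg <- synthetic_config(seed = 34)
  study <- synthesize_study(cfg)
  res <- run_togcn(study$tc)
  ls <- res$stage_map$level_stage
  expect_true(all(diff(ls$peak_stage) >= 0))
  ord <- c(initial = 1, transitional = 2, terminal = 3)
  expect_true(all(diff(ord[ls$group]) >= 0))
  expect_equal(ls$group[1], "initial")
  # conservation: group member counts sum to assigned network members
  expect_equal(sum(res$stage_map$group_counts$members),
               nrow(res$levels$levels))
})
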