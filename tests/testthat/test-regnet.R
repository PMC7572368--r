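# Regulator inference: sub-networks, direct regulators, chains, PWM scans,
# binding-site filtering.

toy_gcn <- function(nodes, is_tf, edges) {
  structure(list(nodes = data.frame(id = nodes, is_tf = is_tf,
                                    stringsAsFactors = FALSE),
                 edges = edges, cutoffs = c(pos = 0.81, neg = -0.57)),
            class = "signed_gcn")
}

toy_levels <- function(ids, levels, is_tf) {
  structure(list(levels = data.frame(id = ids, is_tf = is_tf,
                                     level = as.integer(levels),
                                     stringsAsFactors = FALSE),
                 level_counts = NULL, seed_tf = ids[1]),
            class = "level_assignment")
}

test_that("direct regulators obey the time-order level rule and the sign", {
  edges <- data.frame(
    gene_a = c("tf2", "tf5", "rep1"), gene_b = c("E", "E", "E"),
    r = c(0.9, 0.88, -0.7), sign = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  gcn <- toy_gcn(c("tf2", "tf5", "rep1", "E"), c(TRUE, TRUE, TRUE, FALSE),
                 edges)
  lv <- toy_levels(c("tf2", "tf5", "rep1", "E"), c(2, 5, 2, 2),
                   c(TRUE, TRUE, TRUE, FALSE))
  dr <- direct_regulators(gcn, lv, "E")
  expect_equal(dr$tf, "tf2")            # tf5 appears later than its target
  expect_equal(attr(dr, "repressors"), "rep1")
  expect_error(direct_regulators(gcn, toy_levels("E", NA, FALSE), "E"),
               "level")
})

test_that("a single linear hierarchy yields exactly one order-3 chain", {
  edges <- data.frame(gene_a = c("W", "G", "M"), gene_b = c("G", "M", "E"),
                      r = c(0.9, 0.85, 0.95), sign = "+",
                      stringsAsFactors = FALSE)
  gcn <- toy_gcn(c("W", "G", "M", "E"), c(TRUE, TRUE, TRUE, FALSE), edges)
  lv <- toy_levels(c("W", "G", "M", "E"), c(1, 2, 3, 3),
                   c(TRUE, TRUE, TRUE, FALSE))
  ch <- regulator_chains(gcn, lv, "E")
  expect_equal(sort(ch$tf_path), sort(c("M", "G,M", "W,G,M")))
  expect_equal(sum(ch$order == 3), 1)
  expect_equal(ch$tf_path[ch$order == 3], "W,G,M")
  # no TF-TF edges: only order-1 chains
  gcn2 <- toy_gcn(c("M", "E"), c(TRUE, FALSE),
                  edges[3, , drop = FALSE])
  lv2 <- toy_levels(c("M", "E"), c(3, 3), c(TRUE, FALSE))
  expect_true(all(regulator_chains(gcn2, lv2, "E")$order == 1))
})

test_that("chain enumeration equals the brute-force oracle on small nets", {
  for (seed in 1:4) {
    set.seed(seed)
    n_tf <- 12
    tfs <- paste0("tf", seq_len(n_tf))
    lvv <- sample(1:4, n_tf, replace = TRUE)
    all_pairs <- t(combn(tfs, 2))
    take <- runif(nrow(all_pairs)) < 0.3
    edges <- data.frame(gene_a = all_pairs[take, 1],
                        gene_b = all_pairs[take, 2],
                        r = runif(sum(take), 0.82, 0.99), sign = "+",
                        stringsAsFactors = FALSE)
    dir_tfs <- sample(tfs, 3)
    edges <- rbind(edges, data.frame(gene_a = dir_tfs, gene_b = "E",
                                     r = runif(3, 0.82, 0.99), sign = "+"))
    gcn <- toy_gcn(c(tfs, "E"), c(rep(TRUE, n_tf), FALSE), edges)
    lv <- toy_levels(c(tfs, "E"), c(lvv, 4), c(rep(TRUE, n_tf), FALSE))
    got <- regulator_chains(gcn, lv, "E")
    is_tf <- setNames(c(rep(TRUE, n_tf), FALSE), c(tfs, "E"))
    level <- setNames(c(lvv, 4), c(tfs, "E"))
    expect_equal(sort(got$tf_path),
                 oracle_chains(edges, is_tf, level, "E"),
                 info = paste("seed", seed))
  }
})

test_that("PWM scanning matches position-by-position rescoring", {
  pwms <- generate_pwms(c("MYB", "WRKY"), width = 6, seed = 2)
  set.seed(3)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1))
  for (s in seqs) for (pwm in pwms) for (thr in c(0.7, 0.85)) {
    got <- pwm_scan(s, pwm, thr)
    ora <- oracle_pwm_hits(s, pwm, thr)
    if (is.null(ora)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[order(got$offset, got$strand), c("offset", "strand")],
                   ora[order(ora$offset, ora$strand), c("offset", "strand")],
                   ignore_attr = TRUE)
    }
  }
  expect_equal(nrow(pwm_scan("ACG", pwms[[1]], 0.9)), 0)  # shorter than motif
  expect_error(pwm_scan("ACGTAG", pwms[[1]], 0), "threshold")
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  pwm <- generate_pwms("MYB", width = 8, seed = 4)[[1]]
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  cons <- paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)],
                collapse = "")
  substr(s, 51, 58) <- cons
  fwd <- pwm_scan(s, pwm, 1.0)
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$offset, 50)
  expect_equal(fwd$strand, "+")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rev_hits <- pwm_scan(rc, pwm, 1.0)
  expect_equal(nrow(rev_hits), 1)
  expect_equal(rev_hits$strand, "-")
  expect_equal(rev_hits$offset, nchar(s) - 8 - 50)
})

test_that("binding support keeps only hit families and flags the rest", {
  chains <- data.frame(target = "F3H",
                       order = c(1, 1, 2),
                       tf_path = c("myb1", "c2h2_1", "gras1,c2h2_1"),
                       direct_tf = c("myb1", "c2h2_1", "c2h2_1"),
                       corr_product = c(0.9, 0.88, 0.8),
                       head_level = c(3, 3, 2), stringsAsFactors = FALSE)
  hits <- data.frame(gene = "F3H", motif_id = "PWM_C2H2", family = "C2H2",
                     offset = 100, strand = "+", score = 12)
  fam <- c(myb1 = "MYB", c2h2_1 = "C2H2", gras1 = "GRAS")
  ann <- filter_chains_by_binding(chains, hits, fam)
  expect_equal(ann$supported, c(FALSE, TRUE, TRUE))
  expect_equal(ann$demoted, c(TRUE, FALSE, FALSE))
  # no hits at all: nothing supported, nothing demoted
  ann0 <- filter_chains_by_binding(chains, hits[0, ], fam)
  expect_false(any(ann0$supported))
  expect_false(any(ann0$demoted))
  # unknown family is never supported
  ann2 <- filter_chains_by_binding(chains, hits, fam[-1])
  expect_equal(ann2$flag[1], "unknown-family")
  expect_false(ann2$supported[1])
})

test_that("pathway sub-networks tally connected TF families", {
  tc <- local({
    design <- data.frame(sample = paste0("T", rep(1:5, each = 2), "_R",
                                         rep(1:2, 5)),
                         stage = rep(1:5, each = 2), replicate = rep(1:2, 5))
    m <- rbind(E = rep(c(10, 5, 3, 2, 1), each = 2),
               M = rep(c(9, 5, 3, 2, 1), each = 2),
               B = rep(c(8, 5, 3, 2, 1), each = 2))
    timecourse(m, design, c(E = FALSE, M = TRUE, B = TRUE))
  })
  edges <- data.frame(gene_a = c("M", "B"), gene_b = c("E", "E"),
                      r = c(0.9, 0.85), sign = "+", stringsAsFactors = FALSE)
  gcn <- toy_gcn(c("M", "B", "E"), c(TRUE, TRUE, FALSE), edges)
  lv <- toy_levels(c("M", "B", "E"), c(1, 1, 1), c(TRUE, TRUE, FALSE))
  sub <- pathway_subnetwork(gcn, lv, "E", "initial", tc,
                            family_of = c(M = "MYB", B = "bHLH"))
  expect_equal(sub$enzymes, "E")
  expect_setequal(sub$tfs, c("M", "B"))
  expect_equal(sub$family_tally[["MYB"]], 1)
  expect_equal(sub$family_tally[["bHLH"]], 1)
  expect_warning(pathway_subnetwork(gcn, lv, "E", "terminal", tc),
                 "no pathway gene")
})

test_that("planted regulator support is exact at zero noise", {
  cfg <- synthetic_config(seed = 41, noise_sd = 0)
  study <- synthesize_study(cfg)
  res <- run_togcn(study$tc)
  fam_of <- setNames(study$catalog$tf_family, study$catalog$gene_id)
  hits <- scan_promoters(study$promoters, study$pwms, threshold = 1.0)
  # all planted sites recovered, none invented
  k_hits <- paste(hits$gene, hits$family, hits$offset, hits$strand)
  k_truth <- with(study$truth$motif_sites,
                  paste(gene, family, offset, strand))
  expect_setequal(k_hits, k_truth)
  lv <- setNames(res$levels$levels$level, res$levels$levels$id)
  n_eval <- 0
  for (ch in study$truth$chains) {
    if (!(ch$target %in% names(lv)) || ch$sign == "-") next
    n_eval <- n_eval + 1
    direct <- regulator_chains(res$gcn, res$levels, ch$target, max_order = 1)
    ann <- filter_chains_by_binding(direct, hits, fam_of)
    sup <- unique(ann$direct_family[ann$supported])
    planted_direct <- ch$tfs[length(ch$tfs)]
    # recall: the planted direct regulator itself is supported
    expect_true(planted_direct %in% ann$direct_tf[ann$supported])
    # precision (family level): only the planted family is supported
    expect_equal(sup, unname(fam_of[planted_direct]))
    if (n_eval >= 25) break
  }
  expect_gte(n_eval, 10)
  # full chains on a few targets contain the planted hierarchy
  for (ch in study$truth$chains[1:3]) {
    if (!(ch$target %in% names(lv)) || ch$sign == "-") next
    chains <- regulator_chains(res$gcn, res$levels, ch$target)
    expect_true(paste(ch$tfs, collapse = ",") %in% chains$tf_path)
    # chain validity: levels non-decreasing toward the target
    for (p in strsplit(chains$tf_path[chains$order == 3][1:5], ",")) {
      if (any(is.na(p))) next
      expect_true(all(diff(lv[p]) >= 0))
    }
  }
})
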