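# Independent brute-force oracles. Each is written as a direct transcription
# of the rule being checked, sharing no code with the package implementation.

GC_TABLE <- Biostrings::GENETIC_CODE

# --- NG86 oracle ------------------------------------------------------------

# synonymous sites of one codon, by explicit enumeration of all 9 changes
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (nt in nts) {
    if (nt == ch[pos]) next
    alt <- ch; alt[pos] <- nt
    altc <- paste(alt, collapse = "")
    if (GC_TABLE[[altc]] != "*" && GC_TABLE[[altc]] == GC_TABLE[[codon]])
      s <- s + 1 / 3
  }
  s
}

# all substitution pathways between two codons, recursively
oracle_codon_paths <- function(from, to) {
  if (from == to) return(list())
  paths <- list()
  walk <- function(cur, sd, nd, blocked) {
    cf <- strsplit(cur, "")[[1]]; ct <- strsplit(to, "")[[1]]
    d <- which(cf != ct)
    if (!length(d)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd,
                                        blocked = as.numeric(blocked))
      return()
    }
    for (p in d) {
      nxt <- cf; nxt[p] <- ct[p]
      nxtc <- paste(nxt, collapse = "")
      hit_stop <- GC_TABLE[[nxtc]] == "*"
      syn <- !hit_stop && !blocked && GC_TABLE[[cur]] == GC_TABLE[[nxtc]]
      walk(nxtc, sd + as.numeric(syn), nd + as.numeric(!syn),
           blocked || hit_stop)
    }
  }
  walk(from, 0, 0, FALSE)
  paths
}

oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seq_a); cb <- split3(seq_b)
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
        sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pm <- do.call(rbind, oracle_codon_paths(ca[i], cb[i]))
    ok <- pm[, "blocked"] == 0
    if (any(ok)) pm <- pm[ok, , drop = FALSE]
    Sd <- Sd + mean(pm[, "sd"]); Nd <- Nd + mean(pm[, "nd"])
  }
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ks = jc(ps), ka = jc(pn))
}

# --- duplication rule oracle ------------------------------------------------

oracle_classify_pairs <- function(catalog, pairs, anchored_genes,
                                  proximal_max_gap = 10) {
  chrom <- setNames(catalog$chrom, catalog$gene_id)
  rank <- setNames(catalog$rank, catalog$gene_id)
  out <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    na <- (a %in% anchored_genes) + (b %in% anchored_genes)
    if (na == 2) { out[i] <- "WGD"; next }
    if (chrom[a] == chrom[b]) {
      gap <- abs(rank[a] - rank[b])
      if (gap == 1) { out[i] <- "TD"; next }
      if (gap > 1 && gap < proximal_max_gap) { out[i] <- "PD"; next }
    }
    out[i] <- if (na == 1) "TRD" else "DSD"
  }
  out
}

# greedy maximal-chain block count by exhaustive longest-chain search;
# a chain keeps one orientation throughout
oracle_block_count <- function(ra, rb, min_anchors = 5, max_gap = 25) {
  longest_from <- function(i, avail, dirn) {
    best <- c(i)
    for (j in avail) {
      da <- ra[j] - ra[i]; db <- dirn * (rb[j] - rb[i])
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
        cand <- c(i, longest_from(j, setdiff(avail, j), dirn))
        if (length(cand) > length(best)) best <- cand
      }
    }
    best
  }
  n_blocks <- 0
  avail <- seq_along(ra)
  repeat {
    best <- integer(0)
    for (i in avail) for (dirn in c(1, -1)) {
      ch <- longest_from(i, setdiff(avail, i), dirn)
      if (length(ch) > length(best)) best <- ch
    }
    if (length(best) < min_anchors) break
    n_blocks <- n_blocks + 1
    avail <- setdiff(avail, best)
  }
  n_blocks
}

# --- chain enumeration oracle -------------------------------------------

# all simple positive paths tf_k..tf_1 -> target with levels non-increasing
# upstream, as "tfk,...,tf1" strings (most upstream first)
oracle_chains <- function(edges, is_tf, level, target, max_order = 3) {
  pos <- edges[edges$sign == "+", , drop = FALSE]
  adj <- function(v) {
    c(pos$gene_b[pos$gene_a == v], pos$gene_a[pos$gene_b == v])
  }
  res <- character(0)
  direct <- intersect(adj(target), names(is_tf)[is_tf])
  direct <- direct[!is.na(level[direct]) & level[direct] <= level[target]]
  dig <- function(path) {
    res <<- c(res, paste(rev(path), collapse = ","))
    if (length(path) >= max_order) return()
    cur <- path[length(path)]
    for (up in intersect(adj(cur), names(is_tf)[is_tf])) {
      if (up %in% path || is.na(level[up])) next
      if (level[up] <= level[cur]) dig(c(path, up))
    }
  }
  for (d in direct) dig(d)
  sort(unique(res))
}

# --- PWM scan oracle ----------------------------------------------------

oracle_pwm_hits <- function(seq, pwm, threshold) {
  nts <- c("A", "C", "G", "T")
  f <- sweep(pwm$counts + 0.01, 2, colSums(pwm$counts + 0.01), "/")
  lo <- log2(f / 0.25)
  w <- ncol(lo)
  maxsc <- sum(apply(lo, 2, max))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_at <- function(s, i) {
    sub <- strsplit(substr(s, i, i + w - 1), "")[[1]]
    sum(lo[cbind(match(sub, nts), seq_len(w))])
  }
  hits <- NULL
  for (i in seq_len(nchar(seq) - w + 1)) {
    if (score_at(seq, i) >= threshold * maxsc - 1e-9)
      hits <- rbind(hits, data.frame(offset = i - 1L, strand = "+"))
    if (score_at(rc(seq), nchar(seq) - w - i + 2) >= threshold * maxsc - 1e-9)
      hits <- rbind(hits, data.frame(offset = i - 1L, strand = "-"))
  }
  hits
}

# --- stats oracles ------------------------------------------------------

oracle_hyper_upper <- function(N, K, n, k) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small helper: canonical pair keys for comparing pair tables
pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
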