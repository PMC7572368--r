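# Nei-Gojobori (1986) counting estimator of Ka and Ks with Jukes-Cantor
# multiple-hit correction, Ks kernel-density peak detection, and the
# rate-based conversion between Ks peaks and duplication ages.

NUCS <- c("A", "C", "G", "T")

.ng86 <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

is_stop <- function(codon) genetic_code()[codon] == "*"

# per-codon synonymous site count: at each position, the fraction of the three
# possible changes that preserve the amino acid; changes creating a stop codon
# count as nonsynonymous
syn_site_table <- function() {
  if (!is.null(.ng86$sites)) return(.ng86$sites)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  s <- vapply(sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      for (nt in setdiff(NUCS, ch[p])) {
        alt <- ch; alt[p] <- nt
        alt <- paste(alt, collapse = "")
        if (gc[alt] != "*" && gc[alt] == gc[cod]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))
  .ng86$sites <- s
  s
}

perms_of <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# average synonymous/nonsynonymous difference counts between two sense codons,
# over all minimal substitution pathways; pathways passing through a stop
# codon are excluded and the average renormalized (if every pathway is
# blocked, all pathways are used with stop-passing steps counted as
# nonsynonymous)
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .ng86$paths[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  res_valid <- NULL; res_all <- NULL
  for (ord in perms_of(k)) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in pos[ord]) {
      nxt <- cur; nxt[p] <- b[p]
      cod_cur <- paste(cur, collapse = ""); cod_nxt <- paste(nxt, collapse = "")
      if (gc[cod_nxt] == "*") blocked <- TRUE
      if (!blocked && gc[cod_cur] == gc[cod_nxt]) sd <- sd + 1 else
        nd <- nd + 1
      cur <- nxt
    }
    res_all <- rbind(res_all, c(sd, nd))
    if (!blocked) res_valid <- rbind(res_valid, c(sd, nd))
  }
  use <- if (!is.null(res_valid)) res_valid else res_all
  out <- c(sd = mean(use[, 1]), nd = mean(use[, 2]))
  if (is.null(.ng86$paths)) .ng86$paths <- new.env(parent = emptyenv())
  assign(key, out, envir = .ng86$paths)
  out
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

jc_correct <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

#' Ka/Ks for a codon-aligned pair by the Nei-Gojobori counting method
#'
#' Counts synonymous and nonsynonymous sites (averaged over both sequences)
#' and differences (averaged over minimal substitution pathways, excluding
#' pathways through stop codons), then applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4/3 p)` to each proportion. The estimator is symmetric
#' in its arguments.
#'
#' @param seq_a,seq_b aligned nucleotide sequences (equal length, multiple of
#'   3, alphabet ACGT, no in-frame stop codons; gap columns must already be
#'   removed).
#' @return an object of class `kaks_result`: list with `ka`, `ks`, `omega`,
#'   site counts `N`, `S`, difference counts `Nd`, `Sd`, and saturation flags
#'   `saturated_n`, `saturated_s` (a flagged distance is `NA`).
#' @export
ng86_kaks <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stopf("aligned sequences must have equal length")
  if (nchar(seq_a) %% 3 != 0)
    stopf("alignment length %d is not a multiple of 3 (frame violation)",
          nchar(seq_a))
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stopf("sequences must be over {A,C,G,T} with gap columns removed")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (any(is_stop(ca)) || any(is_stop(cb)))
    stopf("in-frame stop codon in input")
  sites <- syn_site_table()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  d <- vapply(which(ca != cb),
              function(i) codon_path_diffs(ca[i], cb[i]), numeric(2))
  Sd <- if (length(d)) sum(d[1, ]) else 0
  Nd <- if (length(d)) sum(d[2, ]) else 0
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  sat_s <- ps >= 3 / 4; sat_n <- pn >= 3 / 4
  ks <- if (sat_s) NA_real_ else jc_correct(ps)
  ka <- if (sat_n) NA_real_ else jc_correct(pn)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, omega = omega, N = N, S = S,
                 Nd = Nd, Sd = Sd, saturated_s = sat_s, saturated_n = sat_n),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (S = %.1f, N = %.1f)\n",
              x$ka, x$ks,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega),
              x$S, x$N))
  invisible(x)
}

#' Kernel-density model of a Ks distribution with peak detection
#'
#' Gaussian-kernel density on a uniform grid from 0; peaks are local maxima
#' whose height reaches at least `peak_min_frac` of the global maximum,
#' returned sorted by height.
#'
#' @param ks_values finite Ks values (saturated pairs must be excluded
#'   upstream); at least 30 are required.
#' @param bandwidth positive bandwidth, or `"auto"` for Silverman's rule.
#' @param peak_min_frac minimum peak height as a fraction of the global
#'   density maximum (default 0.05).
#' @param n_grid grid resolution (default 512).
#' @return a `ks_peak_model`: list with `grid`, `density`, `bandwidth`, and
#'   `peaks` (data.frame location/height, tallest first).
#' @export
ks_density <- function(ks_values, bandwidth = "auto", peak_min_frac = 0.05,
                       n_grid = 512L) {
  x <- ks_values[is.finite(ks_values)]
  if (length(x) < 30) stopf("need >= 30 finite Ks values, got %d", length(x))
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(x) else {
    if (!is.numeric(bandwidth) || bandwidth <= 0)
      stopf("bandwidth must be positive or 'auto'")
    bandwidth
  }
  d <- density(x, bw = bw, from = 0, to = max(x) + 3 * bw, n = n_grid)
  y <- d$y
  n <- length(y)
  loc_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  loc_max <- loc_max[y[loc_max] >= peak_min_frac * max(y)]
  peaks <- data.frame(location = d$x[loc_max], height = y[loc_max])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(grid = d$x, density = y, bandwidth = bw, peaks = peaks),
            class = "ks_peak_model")
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat(sprintf("Ks density (bw %.4f), %d peak(s); top at %.3f\n",
              x$bandwidth, nrow(x$peaks),
              if (nrow(x$peaks)) x$peaks$location[1] else NA))
  invisible(x)
}

#' Per-site synonymous substitution rate from an ortholog Ks peak
#'
#' `r = Ks / (2 T)` with `T` the divergence time in years: the synonymous
#' distance between orthologs accumulates along both lineages.
#'
#' @param ortholog_ks_peak Ks peak of an inter-species ortholog distribution.
#' @param divergence_time_years calibrated divergence time in years.
#' @return the rate `r` (substitutions per synonymous site per year).
#' @export
substitution_rate <- function(ortholog_ks_peak, divergence_time_years) {
  if (ortholog_ks_peak <= 0 || divergence_time_years <= 0)
    stopf("Ks peak and divergence time must be positive")
  ortholog_ks_peak / (2 * divergence_time_years)
}

#' Date a WGD event from a paralog Ks peak and a substitution rate
#'
#' `T = Ks / (2 r)`; the same per-lineage rate used for ortholog calibration
#' is applied to the within-genome paralog peak.
#'
#' @param paralog_ks_peak Ks peak of the paralog distribution (>= 0).
#' @param r substitution rate per synonymous site per year (> 0).
#' @return age of the duplication event in years.
#' @export
wgd_time <- function(paralog_ks_peak, r) {
  if (r <= 0) stopf("rate r must be positive")
  if (paralog_ks_peak < 0) stopf("Ks peak must be non-negative")
  paralog_ks_peak / (2 * r)
}

#' Per-duplication-mode summary of Ka/Ks ratios
#'
#' Boxplot-style summary per duplication mode: n, quartiles by linear
#' interpolation, 1.5 x IQR whisker bounds (clamped to observed values), and
#' the fraction of pairs with omega > 1 (the positive-selection subset).
#'
#' @param assignment a `dup_assignment` from [classify_duplicates()].
#' @param results data.frame with columns gene_a, gene_b, omega (NA omegas
#'   are dropped with a warning).
#' @return data.frame, one row per non-empty mode.
#' @export
class_kaks_summary <- function(assignment, results) {
  stopifnot(inherits(assignment, "dup_assignment"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  mode_of <- setNames(assignment$pairs$mode,
                      key(assignment$pairs$gene_a, assignment$pairs$gene_b))
  m <- mode_of[key(results$gene_a, results$gene_b)]
  omega <- results$omega
  if (anyNA(omega)) {
    warning(sprintf("dropping %d pairs with undefined omega",
                    sum(is.na(omega))))
    m <- m[!is.na(omega)]; omega <- omega[!is.na(omega)]
  }
  keep <- !is.na(m)
  m <- m[keep]; omega <- omega[keep]
  out <- lapply(split(omega, m), function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(n = length(x), q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
               frac_omega_gt1 = mean(x > 1))
  })
  res <- do.call(rbind, out)
  res <- cbind(mode = rownames(res), res)
  rownames(res) <- NULL
  res
}
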