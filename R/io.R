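# Readers and writers for the pipeline's plain-text interchange formats:
# catalog / pairs / anchors / expression TSVs, FASTA (via Biostrings),
# JASPAR-like PWM text, and JSON reports.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write / read a gene catalog TSV
#' @param catalog catalog data.frame.
#' @param path file path.
#' @return the path (write) or the catalog (read).
#' @export
write_catalog <- function(catalog, path) write_tsv(catalog, path)

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat <- read_tsv(path)
  validate_catalog(cat)
  cat
}

#' Write / read an expression matrix TSV with T{i}_R{j} sample headers
#'
#' @param tc a [timecourse()] (write) or file path (read).
#' @param path file path.
#' @param tf_ids TF ids used to rebuild the `is_tf` flag on read.
#' @return the path (write) or a `timecourse` (read).
#' @export
write_expression <- function(tc, path) {
  df <- data.frame(gene_id = rownames(tc$tpm), tc$tpm, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, tf_ids = character(0)) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  parts <- regmatches(colnames(m),
                      regexec("^T(\\d+)_R(\\d+)$", colnames(m)))
  if (any(lengths(parts) != 3))
    stopf("expression headers must look like T1_R1")
  design <- data.frame(sample = colnames(m),
                       stage = as.integer(vapply(parts, `[`, "", 2)),
                       replicate = as.integer(vapply(parts, `[`, "", 3)))
  timecourse(m, design, setNames(rownames(m) %in% tf_ids, rownames(m)))
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read PWMs in a JASPAR-like 4-row count format
#'
#' One record per motif: a `>id family` header followed by four rows
#' `A [ n n ... ]` etc.
#'
#' @param pwm_set named list of `pwm` objects (write) or file path (read).
#' @param path file path.
#' @return the path (write) or a named list of `pwm` objects (read).
#' @export
write_pwms <- function(pwm_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwm_set) {
    writeLines(sprintf(">%s %s", pwm$id, pwm$family), con)
    for (nt in NUCS)
      writeLines(sprintf("%s [ %s ]", nt,
                         paste(pwm$counts[nt, ], collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_pwms
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    parts <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    rows <- lapply(lines[h + 1:4], function(l) {
      as.numeric(strsplit(gsub("^[ACGT]\\s*\\[\\s*|\\s*\\]\\s*$", "", l),
                          "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- NUCS
    pwm <- structure(list(id = parts[1],
                          family = if (length(parts) > 1) parts[2]
                                   else parts[1],
                          counts = counts, bg = rep(0.25, 4)),
                     class = "pwm")
    out[[pwm$family]] <- pwm
  }
  out
}

#' Write a list/data structure as pretty JSON
#' @param x object serializable by jsonlite.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
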