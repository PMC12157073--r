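# Small in-code fixtures shared across tests.

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_report_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# deterministic random genome over A/C/G/T (no N)
random_genome <- function(n_chroms = 1L, len = 1000L, seed = 1L, gc = 0.5) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
  }, "")
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  structure(seqs, class = "genome_set")
}

# brute-force triplet context caller, written independently of call_context
oracle_context <- function(sequence, pos, strand) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  get <- function(p, st) {
    if (st == "+") { if (p < 1 || p > n) NA else chars[p] }
    else { if (p < 1 || p > n) NA else unname(comp[chars[p]]) }
  }
  b0 <- if (strand == "+") get(pos, "+") else get(pos, "-")
  if (is.na(b0) || b0 != "C") return("none")
  step <- if (strand == "+") 1L else -1L
  b1 <- if (strand == "+") get(pos + step, "+") else get(pos + step, "-")
  b2 <- if (strand == "+") get(pos + 2L * step, "+") else get(pos + 2L * step, "-")
  H <- c("A", "C", "T")
  if (!is.na(b1) && b1 == "G") return("CpG")
  if (is.na(b1) || b1 == "N") return("indeterminate")
  if (b1 %in% H) {
    if (!is.na(b2) && b2 == "G") return("CHG")
    if (is.na(b2) || b2 == "N") return("indeterminate")
    if (b2 %in% H) return("CHH")
  }
  "indeterminate"
}

# tiny labeled site table on one chromosome
toy_sites <- function(positions, labels, chrom = "chr1", strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(positions),
                         strand = strand, label = as.integer(labels))
}
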