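#' Read a FASTA genome
#'
#' Loads reference chromosome sequences for window extraction and context
#' calling. Sequences are uppercased; any base outside A/C/G/T is mapped to N.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named character vector of class `genome_set`: one uppercase
#'   sequence per chromosome, names are chromosome identifiers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  structure(seqs, class = "genome_set")
}

#' Read a Bismark-style cytosine report
#'
#' Expected tab-separated columns: chrom, pos (1-based), strand (+/-),
#' count methylated, count unmethylated, context, and an optional
#' trinucleotide column (ignored). Rows are returned sorted by
#' (chrom, pos, strand).
#'
#' @param path Path to the report (plain TSV, no header).
#' @return A `data.table` with columns chrom, pos, strand, n_meth, n_unmeth,
#'   context (NA when absent from the input).
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 5L) stop("cytosine report needs >= 5 tab-separated columns, got ", ncol(dt))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.table::data.table(
    chrom    = as.character(dt[[1]]),
    pos      = num(dt[[2]]),
    strand   = as.character(dt[[3]]),
    n_meth   = num(dt[[4]]),
    n_unmeth = num(dt[[5]]),
    context  = if (ncol(dt) >= 6L) as.character(dt[[6]]) else NA_character_
  )
  bad_pos <- which(!is.finite(out$pos) | out$pos < 1 | out$pos != floor(out$pos))
  if (length(bad_pos)) stop("invalid position at line ", bad_pos[1], ": ", dt[[2]][bad_pos[1]])
  bad_strand <- which(!out$strand %in% c("+", "-"))
  if (length(bad_strand)) stop("invalid strand at line ", bad_strand[1], ": '", out$strand[bad_strand[1]], "'")
  for (col in c("n_meth", "n_unmeth")) {
    v <- out[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) stop("invalid ", col, " at line ", bad[1], ": ", v[bad[1]])
  }
  out$pos <- as.integer(out$pos)
  out$n_meth <- as.integer(out$n_meth)
  out$n_unmeth <- as.integer(out$n_unmeth)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Write (and read back) a methylome prediction table
#'
#' Serializes a site table with observed, predicted-probability and imputed
#' state columns as plain TSV. NA is written as the literal "NA".
#'
#' @param table A `data.table` with columns chrom, pos, strand, context,
#'   observed_state, pred_prob, imputed_state.
#' @param path Output path.
#' @export
write_predictions <- function(table, path) {
  need <- c("chrom", "pos", "strand", "context", "observed_state", "pred_prob", "imputed_state")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("prediction table missing column(s): ", paste(miss, collapse = ", "))
  p <- table$pred_prob
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("pred_prob outside [0,1]")
  data.table::fwrite(table[, need, with = FALSE], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(NULL)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = c("chrom", "strand", "context")))
  dt$pos <- as.integer(dt$pos)
  dt$observed_state <- as.integer(dt$observed_state)
  dt$imputed_state <- as.integer(dt$imputed_state)
  dt[]
}

#' Write motifs in MEME minimal format
#'
#' One MOTIF block per convolutional filter, alphabet ACGT, letter
#' probability rows in A/C/G/T order.
#'
#' @param motifs A `motif_set` (see [extract_motifs()]) or a list of
#'   11 x 4 row-stochastic matrices with columns A,C,G,T.
#' @param path Output path.
#' @param background Background letter frequencies (A,C,G,T), default uniform.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  pwms <- if (inherits(motifs, "motif_set")) motifs$pwm else motifs
  if (is.matrix(pwms)) pwms <- list(pwms)
  nm <- names(pwms)
  if (is.null(nm)) nm <- sprintf("filter_%03d", seq_along(pwms) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3], background[4]),
               ""), con)
  for (i in seq_along(pwms)) {
    pwm <- pwms[[i]]
    if (!is.matrix(pwm) || ncol(pwm) != 4L) stop("PWM must be a w x 4 matrix: ", nm[i])
    if (any(abs(rowSums(pwm) - 1) > 1e-6)) stop("PWM rows must sum to 1 (motif ", nm[i], ")")
    writeLines(c(sprintf("MOTIF %s", nm[i]),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(pwm),
                         if (inherits(motifs, "motif_set")) max(1L, motifs$table$n_windows[i]) else 1L)),
               con)
    writeLines(apply(pwm, 1L, function(r) sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(NULL)
}

#' Export imputed probabilities as a bedGraph track
#'
#' @param table Prediction table as written by [write_predictions()].
#' @param path Output path.
#' @param value Which column to export: "pred_prob" or "imputed_state".
#' @export
write_bedgraph <- function(table, path, value = c("pred_prob", "imputed_state")) {
  value <- match.arg(value)
  v <- table[[value]]
  keep <- !is.na(v)
  bg <- data.table::data.table(
    chrom = table$chrom[keep],
    start = table$pos[keep] - 1L,
    end   = table$pos[keep],
    value = v[keep]
  )
  data.table::fwrite(bg, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(NULL)
}
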