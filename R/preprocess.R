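H_BASES <- c("A", "C", "T")

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Call the cytosine sequence context
#'
#' Classifies positions of one chromosome into the three plant methylation
#' contexts: CpG, CHG, CHH (H = A, C or T). On the minus strand the mirrored
#' logic applies to the reverse complement. Positions that are not a cytosine
#' on the requested strand return "none"; cytosines whose context window
#' contains N or runs off the chromosome end return "indeterminate".
#'
#' @param sequence One chromosome sequence (uppercase character scalar).
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector ("+"/"-"), recycled to `length(pos)`.
#' @return Character vector in {"CpG","CHG","CHH","none","indeterminate"}.
#' @export
call_context <- function(sequence, pos, strand) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (any(pos < 1L | pos > n)) stop("position out of range 1..", n)
  at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 1L & p <= n
    out[ok] <- chars[p[ok]]
    out
  }
  plus <- strand == "+"
  b0 <- at(pos)
  b1 <- ifelse(plus, at(pos + 1L), at(pos - 1L))
  b2 <- ifelse(plus, at(pos + 2L), at(pos - 2L))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b0[!plus] <- comp[b0[!plus]]
  b1[!plus] <- comp[b1[!plus]]
  b2[!plus] <- comp[b2[!plus]]
  out <- rep("none", length(pos))
  is_c <- !is.na(b0) & b0 == "C"
  out[is_c] <- "indeterminate"
  cpg <- is_c & !is.na(b1) & b1 == "G"
  out[cpg] <- "CpG"
  h1 <- is_c & !cpg & !is.na(b1) & b1 %in% H_BASES
  chg <- h1 & !is.na(b2) & b2 == "G"
  out[chg] <- "CHG"
  chh <- h1 & !is.na(b2) & b2 %in% H_BASES
  out[chh] <- "CHH"
  out
}

#' Enumerate all cytosines of a genome with their contexts
#'
#' Scans both strands of every chromosome: a plus-strand cytosine is a C in
#' the reference, a minus-strand cytosine a G.
#'
#' @param genome A `genome_set` from [read_fasta()] (or named character vector).
#' @return `data.table` with chrom, pos, strand, context, sorted by
#'   (chrom, pos, strand).
#' @export
genome_cytosines <- function(genome) {
  res <- lapply(names(genome), function(ch) {
    chars <- seq_chars(genome[[ch]])
    pp <- which(chars == "C")
    pm <- which(chars == "G")
    dt <- data.table::data.table(
      chrom  = ch,
      pos    = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))))
    dt$context <- call_context(genome[[ch]], dt$pos, dt$strand)
    dt
  })
  out <- data.table::rbindlist(res)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Label cytosine sites from read counts
#'
#' Applies the minimum-depth filter and rounds the methylation rate to a
#' binary state. Sites with depth below `min_depth` get label NA; otherwise
#' label 1 when rate >= 0.5 (round-half-up on observed input rates).
#'
#' @param rows `data.table` from [read_cytosine_report()].
#' @param min_depth Minimum aligned reads for a usable label (default 4).
#' @return The table with added columns depth, rate, label.
#' @export
label_site <- function(rows, min_depth = 4L) {
  out <- data.table::copy(rows)
  out$depth <- out$n_meth + out$n_unmeth
  out$rate <- ifelse(out$depth > 0L, out$n_meth / out$depth, NA_real_)
  out$label <- ifelse(out$depth < min_depth, NA_integer_,
                      as.integer(out$rate >= 0.5))
  out[]
}

#' Recompute context from the genome
#'
#' Contexts are always re-derived from the reference even when the report
#' supplies them; a mismatch count guards against genome/report drift.
#'
#' @param records Site table with chrom, pos, strand (and optionally context).
#' @param genome A `genome_set`.
#' @return The table with context replaced by the genome-derived call.
#' @export
annotate_context <- function(records, genome) {
  out <- data.table::copy(records)
  missing_chrom <- setdiff(unique(out$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", "))
  }
  newctx <- rep(NA_character_, nrow(out))
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    newctx[i] <- call_context(genome[[ch]], out$pos[i], out$strand[i])
  }
  if ("context" %in% names(out)) {
    have <- !is.na(out$context)
    n_mismatch <- sum(have & out$context != newctx)
    if (n_mismatch > 0L) {
      warning(n_mismatch, " site(s) had a report context differing from the genome-derived call")
    }
  }
  out$context <- newctx
  out[]
}

#' Build a chromosome split specification
#'
#' @param train_chroms,val_chroms,test_chroms Disjoint chromosome id vectors.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_chroms, val_chroms = character(), test_chroms = character()) {
  all3 <- c(train_chroms, val_chroms, test_chroms)
  if (anyDuplicated(all3)) {
    stop("split chromosome sets overlap: ", paste(unique(all3[duplicated(all3)]), collapse = ", "))
  }
  structure(list(train = as.character(train_chroms),
                 val = as.character(val_chroms),
                 test = as.character(test_chroms)),
            class = "split_spec")
}

#' Partition labeled sites by chromosome
#'
#' NA-labeled records are excluded from all three model subsets (they remain
#' in the imputation universe held by the caller); records on chromosomes
#' outside the spec are excluded too.
#'
#' @param records Labeled site table (from [label_site()]).
#' @param spec A [split_spec()].
#' @return List of three `data.table`s: train, val, test.
#' @export
split_sites <- function(records, spec) {
  if (!inherits(spec, "split_spec")) spec <- do.call(split_spec, unname(spec))
  keep <- !is.na(records$label)
  pick <- function(chroms) records[keep & records$chrom %in% chroms]
  out <- list(train = pick(spec$train), val = pick(spec$val), test = pick(spec$test))
  if (length(spec$val) == 0L || nrow(out$val) == 0L) {
    warning("validation subset is empty")
  }
  out
}

#' Maximum genome-wide gap between neighboring cytosines
#'
#' The largest distance between consecutive cytosine positions on any
#' chromosome, used to normalize neighbor distances into [0, 1]. Positions
#' count regardless of context, strand or label availability.
#'
#' @param records Site table with chrom and pos.
#' @return Positive integer distance.
#' @export
max_neighbor_gap <- function(records) {
  gaps <- vapply(split(records$pos, records$chrom), function(p) {
    p <- sort(unique(p))
    if (length(p) < 2L) return(NA_real_)
    max(diff(p))
  }, numeric(1))
  gaps <- gaps[!is.na(gaps)]
  if (!length(gaps)) stop("need at least two cytosines on some chromosome")
  as.integer(max(gaps))
}
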