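# One-hot base coding shared across the package. Column/code order A,T,G,C;
# 0 encodes N or an off-chromosome pad (an all-zero one-hot row).
BASE_CODES <- c(A = 1L, T = 2L, G = 3L, C = 4L)
BASE_ORDER <- c("A", "T", "G", "C")
COMP_CODE <- c(2L, 1L, 4L, 3L)   # A<->T, G<->C

#' Encoding specification
#'
#' Fixes the tensor geometry shared by encoder, models and imputation: the
#' DNA window half-width (default 500, window length 1001), the number of
#' neighbor cytosines per side (default 25, feature vector length 100) and
#' the genome-wide distance normalizer `d_max` (see [max_neighbor_gap()]).
#'
#' @param window_radius Bases up- and downstream of the target cytosine.
#' @param k_neighbors Labeled neighbor sites used on each side.
#' @param d_max Distance normalizer; neighbor distances are divided by it
#'   and clipped to 1.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(window_radius = 500L, k_neighbors = 25L, d_max = NULL) {
  stopifnot(window_radius >= 1L, k_neighbors >= 1L)
  structure(list(window_radius = as.integer(window_radius),
                 k_neighbors = as.integer(k_neighbors),
                 window_length = 2L * as.integer(window_radius) + 1L,
                 n_features = 4L * as.integer(k_neighbors),
                 d_max = if (is.null(d_max)) NULL else as.numeric(d_max)),
            class = "encoding_spec")
}

code_sequence <- function(sequence) {
  v <- BASE_CODES[seq_chars(sequence)]
  v[is.na(v)] <- 0L
  unname(v)
}

# batched window extraction: integer code matrix n x (2r+1), model
# orientation (minus-strand windows reverse-complemented so the center is C)
window_codes <- function(code_vec, pos, strand, radius) {
  n <- length(pos)
  L <- 2L * radius + 1L
  offs <- -radius:radius
  idx <- outer(as.integer(pos), offs, "+")
  minus <- strand == "-"
  if (any(minus)) idx[minus, ] <- idx[minus, L:1, drop = FALSE]
  flat <- as.vector(idx)
  ok <- flat >= 1L & flat <= length(code_vec)
  out <- integer(n * L)
  out[ok] <- code_vec[flat[ok]]
  codes <- matrix(out, n, L)
  if (any(minus)) {
    sub <- codes[minus, , drop = FALSE]
    nz <- sub > 0L
    sub[nz] <- COMP_CODE[sub[nz]]
    codes[minus, ] <- sub
  }
  codes
}

#' One-hot encode the DNA window around a cytosine
#'
#' Returns the (2r+1) x 4 binary matrix, columns A,T,G,C, covering
#' `[pos - r, pos + r]`. Minus-strand sites are reverse-complemented so the
#' central row always encodes C; N bases and positions beyond the chromosome
#' ends give all-zero rows.
#'
#' @param sequence One chromosome sequence.
#' @param pos 1-based position of the target cytosine.
#' @param strand "+" or "-".
#' @param spec An [encoding_spec()].
#' @return A `window_length` x 4 matrix of 0/1.
#' @export
one_hot_window <- function(sequence, pos, strand, spec = encoding_spec()) {
  codes <- window_codes(code_sequence(sequence), pos, strand, spec$window_radius)
  center <- codes[1L, spec$window_radius + 1L]
  if (center != BASE_CODES[["C"]]) {
    stop("position ", pos, " (", strand, ") is not a cytosine in model orientation")
  }
  oh <- matrix(0L, spec$window_length, 4L)
  nz <- which(codes[1L, ] > 0L)
  oh[cbind(nz, codes[1L, nz])] <- 1L
  colnames(oh) <- BASE_ORDER
  oh
}

#' Decode a one-hot window back to sequence
#'
#' All-zero rows decode to N.
#'
#' @param onehot A window matrix from [one_hot_window()].
#' @return Character scalar.
#' @export
decode_window <- function(onehot) {
  idx <- apply(onehot, 1L, function(r) {
    w <- which(r == 1)
    if (length(w) == 1L) w else 0L
  })
  paste(c("N", BASE_ORDER)[idx + 1L], collapse = "")
}

# Batched neighbor features for all targets on one chromosome.
# positions/labels describe the eligible-neighbor universe (labels non-NA);
# target_pos are the sites to encode (need not be part of the universe).
# Layout: 2k state slots then 2k distance slots, both in genomic order
# (upstream neighbors farthest-first, then downstream nearest-first).
# Missing neighbors pad with state 0.5, distance 1.0.
neighbor_feature_matrix <- function(positions, labels, target_pos, spec) {
  stopifnot(!is.null(spec$d_max))
  k <- spec$k_neighbors
  keep <- !is.na(labels)
  E <- positions[keep]
  lab <- labels[keep]
  o <- order(E)
  E <- E[o]; lab <- lab[o]
  n <- length(target_pos)
  states <- matrix(0.5, n, 2L * k)
  dists <- matrix(1.0, n, 2L * k)
  nE <- length(E)
  if (nE > 0L) {
    n_left <- findInterval(target_pos - 0.5, E)       # neighbors strictly left
    r_start <- findInterval(target_pos + 0.5, E) + 1L # first strictly right
    for (s in seq_len(k)) {
      # left slot s (1 = farthest): eligible index n_left - k + s
      li <- n_left - k + s
      ok <- li >= 1L
      if (any(ok)) {
        states[ok, s] <- lab[li[ok]]
        dists[ok, s] <- pmin(abs(target_pos[ok] - E[li[ok]]) / spec$d_max, 1)
      }
      # right slot s (slot k+s, 1 = nearest): eligible index r_start + s - 1
      ri <- r_start + s - 1L
      ok <- ri <= nE
      if (any(ok)) {
        states[ok, k + s] <- lab[ri[ok]]
        dists[ok, k + s] <- pmin(abs(E[ri[ok]] - target_pos[ok]) / spec$d_max, 1)
      }
    }
  }
  cbind(states, dists)
}

#' Neighbor state/distance features for one target site
#'
#' Encodes the methylation states of the `k` nearest labeled cytosines on
#' each side of the target and their distances (normalized by `d_max`,
#' clipped to 1) as a `4k`-long vector: `2k` states then `2k` distances, in
#' genomic order. Chromosome edges and sparse neighborhoods are padded with
#' the uninformative values state 0.5, distance 1.0. The target site itself
#' is never its own neighbor.
#'
#' @param positions Integer positions of all candidate sites on the chromosome.
#' @param labels Their labels (0/1/NA); NA sites are ineligible.
#' @param target_index Index of the target in `positions`.
#' @param spec An [encoding_spec()] with `d_max` set.
#' @param training When TRUE an NA-labeled target is an error.
#' @return Numeric vector of length `4 * k_neighbors`.
#' @export
neighbor_features <- function(positions, labels, target_index, spec, training = TRUE) {
  if (training && is.na(labels[target_index])) {
    stop("target site has NA label; training examples need a known state")
  }
  lab2 <- labels
  lab2[target_index] <- NA_integer_   # exclude target from its own universe
  neighbor_feature_matrix(positions, lab2, positions[target_index], spec)[1L, ]
}

#' Build a model-ready dataset
#'
#' Assembles, for each target record, the integer-coded DNA window and the
#' neighbor feature vector. Windows are stored as compact base codes and
#' expanded to one-hot inside the model forward pass.
#'
#' @param records Target site table (chrom, pos, strand, label, ...).
#' @param genome `genome_set` holding every chromosome in `records`.
#' @param spec [encoding_spec()] with `d_max` set.
#' @param neighbors Site table defining the eligible neighbor universe
#'   (default: `records` itself). NA-labeled rows are never eligible.
#' @param allow_na Allow NA target labels (imputation mode).
#' @return A `methyl_dataset`: list with `seq` (n x window_length code
#'   matrix), `nbr` (n x 4k), `label`, `site` (the record table), `spec`.
#' @export
build_dataset <- function(records, genome, spec, neighbors = records, allow_na = FALSE) {
  if (nrow(records) == 0L) stop("empty record set")
  if (is.null(spec$d_max)) stop("encoding_spec needs d_max (see max_neighbor_gap)")
  if (!allow_na && anyNA(records$label)) {
    stop("NA-labeled targets in a training dataset; set allow_na = TRUE for imputation")
  }
  missing_chrom <- setdiff(unique(records$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", "))
  }
  records <- data.table::as.data.table(records)
  data.table::setorder(records, chrom, pos, strand)
  n <- nrow(records)
  seqm <- matrix(0L, n, spec$window_length)
  nbrm <- matrix(0, n, spec$n_features)
  for (ch in unique(records$chrom)) {
    ti <- which(records$chrom == ch)
    code_vec <- code_sequence(genome[[ch]])
    seqm[ti, ] <- window_codes(code_vec, records$pos[ti], records$strand[ti],
                               spec$window_radius)
    ni <- which(neighbors$chrom == ch)
    # strict left/right selection in neighbor_feature_matrix means a target
    # at position p never picks itself (positions are unique per chromosome)
    nbrm[ti, ] <- neighbor_feature_matrix(neighbors$pos[ni], neighbors$label[ni],
                                          records$pos[ti], spec)
  }
  structure(list(seq = seqm, nbr = nbrm,
                 label = records$label, site = records, spec = spec),
            class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat("<methyl_dataset> ", nrow(x$seq), " sites, window ", ncol(x$seq),
      " bp, ", ncol(x$nbr), " neighbor features, ",
      sum(is.na(x$label)), " NA labels\n", sep = "")
  invisible(x)
}

dataset_subset <- function(ds, idx) {
  structure(list(seq = ds$seq[idx, , drop = FALSE],
                 nbr = ds$nbr[idx, , drop = FALSE],
                 label = ds$label[idx], site = ds$site[idx],
                 spec = ds$spec),
            class = "methyl_dataset")
}
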