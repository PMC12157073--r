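# Motif extraction from the first convolutional layer of the DNA model:
# activation maps, 50%-of-max window selection, PWM construction, activity
# scores, signed effect on methylation and a 2-D PCA of the activity table.

PWM_ORDER <- c("A", "C", "G", "T")
# map window codes (A,T,G,C = 1..4) to PWM column order A,C,G,T
CODE_TO_PWM <- c(1L, 4L, 3L, 2L)

#' First-layer filter activation maps
#'
#' Post-ReLU, pre-pooling activations of the first convolutional layer at
#' every valid position (receptive field fully inside the window).
#'
#' @param model A `methyl_model` with a DNA branch ("dna" or "joint").
#' @param windows A `methyl_dataset` (its `seq` codes are used) or an
#'   integer code matrix of windows.
#' @param batch_size Windows per forward chunk.
#' @return List of class `filter_activations`: `act` array
#'   (window, position, filter), `codes` the window code matrix, `kernel`.
#' @export
filter_activations <- function(model, windows, batch_size = 256L) {
  if (is.null(model$params$dna)) stop("model has no DNA branch (first-layer filters)")
  codes <- if (inherits(windows, "methyl_dataset")) windows$seq else windows
  if (nrow(codes) < 1L) stop("need at least one window")
  spec <- model$dna_spec
  k <- spec$kernel1
  n <- nrow(codes); L <- ncol(codes); out <- L - k + 1L
  act <- array(0, c(n, out, spec$n_filters1))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    P <- nn_im2col_codes(codes[idx, , drop = FALSE], k)
    Z <- sweep(P %*% model$params$dna$W1, 2L, model$params$dna$b1, "+")
    A <- Z * (Z > 0)
    dim(A) <- c(length(idx), out, spec$n_filters1)
    act[idx, , ] <- A
  }
  structure(list(act = act, codes = codes, kernel = k),
            class = "filter_activations")
}

#' Select maximally activating sequence windows per filter
#'
#' For each filter, the activation threshold is `fraction` of that filter's
#' global maximum across all windows and positions. From each window, the
#' position of maximal activation contributes its k-mer iff its activation
#' strictly exceeds the threshold and the k-mer contains no N/pad base --
#' at most one window per (sequence, filter).
#'
#' @param activations A `filter_activations`.
#' @param fraction Fraction of the per-filter global maximum, in (0, 1).
#' @return List (one element per filter) of character vectors of k-mers.
#' @export
select_windows <- function(activations, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  act <- activations$act
  codes <- activations$codes
  k <- activations$kernel
  n_filters <- dim(act)[3]
  out <- vector("list", n_filters)
  for (f in seq_len(n_filters)) {
    a <- act[, , f, drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, nrow = dim(act)[1])
    thr <- fraction * max(a)
    kmers <- character(0)
    if (max(a) > 0) {
      best_p <- max.col(a, ties.method = "first")
      best_v <- a[cbind(seq_len(nrow(a)), best_p)]
      sel <- which(best_v > thr)
      for (w in sel) {
        sub <- codes[w, best_p[w]:(best_p[w] + k - 1L)]
        if (all(sub > 0L)) {
          kmers <- c(kmers, paste(BASE_ORDER[sub], collapse = ""))
        }
      }
    }
    out[[f]] <- kmers
  }
  names(out) <- sprintf("filter_%03d", seq_len(n_filters) - 1L)
  out
}

#' Build a position weight matrix from selected k-mers
#'
#' Position-wise base counts plus a pseudocount, row-normalized; columns in
#' A,C,G,T order. Information content is `sum over positions of
#' (2 - entropy in bits)`. An empty selection yields the uniform PWM with
#' zero information content.
#'
#' @param kmers Character vector of equal-length A/C/G/T strings.
#' @param pseudocount Added to every count (default 0.5).
#' @param width Motif width used when `kmers` is empty.
#' @return List: `pwm` (width x 4 row-stochastic matrix), `ic`, `n_windows`.
#' @export
build_pwm <- function(kmers, pseudocount = 0.5, width = 11L) {
  if (length(kmers) == 0L) {
    pwm <- matrix(0.25, width, 4L, dimnames = list(NULL, PWM_ORDER))
    return(list(pwm = pwm, ic = 0, n_windows = 0L))
  }
  w <- unique(nchar(kmers))
  if (length(w) != 1L || w != width) {
    stop("k-mers must all have length ", width)
  }
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  if (!all(chars %in% PWM_ORDER)) stop("k-mers must be over A/C/G/T")
  counts <- sapply(PWM_ORDER, function(b) colSums(matrix(chars == b, nrow(chars))))
  counts <- matrix(counts, w, 4L, dimnames = list(NULL, PWM_ORDER))
  pwm <- (counts + pseudocount) / (length(kmers) + 4 * pseudocount)
  pl <- pwm * log2(pwm)
  pl[pwm == 0] <- 0
  ic <- sum(2 + rowSums(pl))
  list(pwm = pwm, ic = ic, n_windows = length(kmers))
}

#' Per-filter activity over windows
#'
#' Mean (and max) first-layer activation of each filter on each window.
#'
#' @param activations A `filter_activations`.
#' @return List of class `activity_table`: `mean` and `max`, both
#'   filters x windows matrices.
#' @export
motif_activity <- function(activations) {
  act <- activations$act
  mean_t <- t(apply(act, c(1L, 3L), mean))
  max_t <- t(apply(act, c(1L, 3L), max))
  structure(list(mean = mean_t, max = max_t), class = "activity_table")
}

#' Signed motif effect on methylation
#'
#' Defined here as the Pearson correlation between a filter's mean activity
#' across windows and the window labels; filters with zero activity variance
#' get effect 0 (flagged in the `zero_variance` attribute).
#'
#' @param activity An `activity_table`.
#' @param labels 0/1 label per window.
#' @return Numeric vector, one signed effect per filter.
#' @export
motif_effect <- function(activity, labels) {
  A <- activity$mean
  if (ncol(A) != length(labels)) stop("labels must match the number of windows")
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  sds <- apply(A, 1L, stats::sd)
  eff <- rep(0, nrow(A))
  ok <- sds > 0
  if (any(ok)) eff[ok] <- as.vector(stats::cor(t(A[ok, , drop = FALSE]), labels))
  attr(eff, "zero_variance") <- which(!ok)
  eff
}

#' PCA of motif activities
#'
#' Filters are the points, windows the features. Features are centered
#' (optionally unit-scaled) and the filters are projected on the top two
#' principal axes; each axis is oriented so its largest-magnitude loading
#' is positive.
#'
#' @param activity An `activity_table`.
#' @param scale Unit-scale the features.
#' @return Matrix filters x 2 (columns pc1, pc2).
#' @export
pca_motifs <- function(activity, scale = FALSE) {
  X <- activity$mean
  informative <- apply(X, 1L, stats::sd) > 0
  if (sum(informative) < 3L) stop("need >= 3 filters with nonzero activity variance")
  keep_feat <- apply(X, 2L, stats::sd) > 0
  if (scale && sum(keep_feat) < 2L) stop("fewer than 2 informative feature dimensions")
  Xs <- if (scale) X[, keep_feat, drop = FALSE] else X
  pc <- stats::prcomp(Xs, center = TRUE, scale. = scale, rank. = 2L)
  if (ncol(pc$x) < 2L) stop("fewer than 2 informative dimensions")
  coords <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (flip < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("pc1", "pc2")
  coords
}

#' Extract the motif set of a trained DNA model
#'
#' Full pipeline over a window set: activation maps, 50%-of-max window
#' selection, PWMs with information content, per-filter activity, signed
#' effect on the window labels, and 2-D PCA coordinates.
#'
#' @param model A trained `methyl_model` with a DNA branch.
#' @param dataset A `methyl_dataset` of labeled windows.
#' @param fraction Selection threshold fraction (default 0.5).
#' @param pseudocount PWM pseudocount.
#' @return A `motif_set`: `pwm` (named list of width x 4 matrices), `table`
#'   (`data.table`: filter, n_windows, ic, effect, pc1, pc2), `activity`.
#' @export
extract_motifs <- function(model, dataset, fraction = 0.5, pseudocount = 0.5) {
  fa <- filter_activations(model, dataset)
  sel <- select_windows(fa, fraction)
  width <- model$dna_spec$kernel1
  pw <- lapply(sel, build_pwm, pseudocount = pseudocount, width = width)
  activity <- motif_activity(fa)
  eff <- motif_effect(activity, dataset$label)
  coords <- tryCatch(pca_motifs(activity),
                     error = function(e) matrix(NA_real_, length(sel), 2L))
  tab <- data.table::data.table(
    filter = names(sel),
    n_windows = vapply(pw, `[[`, 0L, "n_windows"),
    ic = vapply(pw, `[[`, 0, "ic"),
    effect = eff,
    pc1 = coords[, 1], pc2 = coords[, 2])
  structure(list(pwm = lapply(pw, `[[`, "pwm"), table = tab, activity = activity),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set> ", length(x$pwm), " filters, ",
      sum(x$table$n_windows > 0), " with selected windows\n", sep = "")
  invisible(x)
}

#' Write the per-motif summary table
#'
#' @param motifs A `motif_set`.
#' @param path Output TSV path.
#' @export
write_motif_table <- function(motifs, path) {
  data.table::fwrite(motifs$table, path, sep = "\t")
  invisible(NULL)
}

consensus_matrix <- function(consensus) {
  chars <- seq_chars(consensus)
  m <- matrix(0, length(chars), 4L, dimnames = list(NULL, PWM_ORDER))
  m[cbind(seq_along(chars), match(chars, PWM_ORDER))] <- 1
  m
}

revcomp_pwm <- function(pwm) {
  # reverse positions, swap A<->T and C<->G columns
  pwm[nrow(pwm):1, c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Best alignment correlation between a PWM and a consensus
#'
#' Slides the PWM along the consensus one-hot matrix (both orientations,
#' minimum overlap of columns) and returns the maximum Pearson correlation
#' of the flattened overlapping entries.
#'
#' @param pwm A width x 4 PWM (columns A,C,G,T).
#' @param consensus Consensus string over A/C/G/T.
#' @param min_overlap Minimum overlapping positions per alignment.
#' @return Maximum correlation over alignments and orientations.
#' @export
match_motif <- function(pwm, consensus, min_overlap = 6L) {
  target <- consensus_matrix(consensus)
  best <- -1
  for (mat in list(pwm, revcomp_pwm(pwm))) {
    w1 <- nrow(mat); w2 <- nrow(target)
    for (off in (-(w1 - min_overlap)):(w2 - min_overlap)) {
      i1 <- max(1L, 1L - off):min(w1, w2 - off)
      i2 <- i1 + off
      a <- as.vector(mat[i1, , drop = FALSE])
      b <- as.vector(target[i2, , drop = FALSE])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      best <- max(best, stats::cor(a, b))
    }
  }
  best
}
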