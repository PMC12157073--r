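motif_enc <- function() encoding_spec(window_radius = 50, k_neighbors = 2, d_max = 100)
motif_spec <- function() dna_model_spec(4, 11, 4, 4, 3, 2, fc_units = 8, dropout = 0)

# model with hand-crafted first-layer filters; filter 1 is an exact detector
# for the given consensus, remaining filters are small random noise
planted_model <- function(consensus = "TATATATATAT", seed = 50) {
  set.seed(seed)
  m <- build_dna_model(motif_spec(), motif_enc())
  W1 <- matrix(rnorm(44 * 4, 0, 0.01), 44, 4)
  chars <- strsplit(consensus, "")[[1]]
  code <- c(A = 1L, T = 2L, G = 3L, C = 4L)[chars]
  for (j in 1:11) W1[(j - 1) * 4 + code[j], 1] <- 1
  m$params$dna$W1 <- W1
  m$params$dna$b1 <- c(-9.5, 0, 0, 0)  # detector fires only on >= 10/11 matches
  m
}

windows_with <- function(consensus, n_with = 4, n_without = 6, seed = 51) {
  set.seed(seed)
  L <- motif_enc()$window_length
  mk <- function(plant) {
    codes <- sample(1:4, L, replace = TRUE)
    if (plant) {
      at <- sample(10:(L - 20), 1)
      codes[at:(at + 10)] <- c(A = 1L, T = 2L, G = 3L, C = 4L)[strsplit(consensus, "")[[1]]]
    }
    codes
  }
  rbind(do.call(rbind, replicate(n_with, mk(TRUE), simplify = FALSE)),
        do.call(rbind, replicate(n_without, mk(FALSE), simplify = FALSE)))
}

test_that("activation maps have valid-position geometry and a closed form", {
  m <- planted_model()
  codes <- windows_with("TATATATATAT")
  fa <- filter_activations(m, codes)
  expect_equal(dim(fa$act), c(10L, 101L - 11L + 1L, 4L))
  # all-zero window: every activation is ReLU(bias)
  fa0 <- filter_activations(m, matrix(0L, 1, 101))
  for (f in 1:4) {
    expect_true(all(abs(fa0$act[1, , f] - max(0, m$params$dna$b1[f])) < 1e-12))
  }
  # activation equals the dot product of filter with the one-hot 11-mer
  md <- asNamespace("methydeep")
  P <- md$nn_im2col_codes(codes[1, , drop = FALSE], 11L)
  for (p in c(1, 40, 91)) {
    want <- max(0, sum(P[p, ] * m$params$dna$W1[, 2]) + m$params$dna$b1[2])
    expect_equal(fa$act[1, p, 2], want)
  }
  expect_error(filter_activations(build_meth_model(meth_model_spec(4, 5, 6), motif_enc()),
                                  codes), "DNA branch")
})

test_that("window selection finds exactly the planted occurrences", {
  consensus <- "TATATATATAT"
  m <- planted_model(consensus)
  codes <- windows_with(consensus)
  fa <- filter_activations(m, codes)
  sel <- select_windows(fa, 0.5)
  expect_equal(sort(sel[[1]]), sort(rep(consensus, 4)))
  expect_error(select_windows(fa, 1.5), "fraction")
  # a filter whose activations are all zero selects nothing
  m0 <- planted_model(consensus)
  m0$params$dna$W1[, 3] <- 0
  m0$params$dna$b1[3] <- -1
  sel0 <- select_windows(filter_activations(m0, codes), 0.5)
  expect_equal(length(sel0[[3]]), 0L)
})

test_that("window selection matches an independent brute-force rescan", {
  set.seed(52)
  m <- build_dna_model(motif_spec(), motif_enc())  # random filters
  codes <- matrix(sample(0:4, 20 * 101, replace = TRUE, prob = c(.02, rep(.245, 4))), 20)
  fa <- filter_activations(m, codes)
  sel <- select_windows(fa, 0.5)
  W1 <- m$params$dna$W1; b1 <- m$params$dna$b1
  base_order <- c("A", "T", "G", "C")
  for (f in 1:4) {
    # brute force: recompute every activation from scratch
    acts <- matrix(0, 20, 91)
    for (w in 1:20) for (p in 1:91) {
      z <- b1[f]
      for (j in 1:11) {
        cd <- codes[w, p + j - 1]
        if (cd > 0) z <- z + W1[(j - 1) * 4 + cd, f]
      }
      acts[w, p] <- max(0, z)
    }
    thr <- 0.5 * max(acts)
    want <- character(0)
    if (max(acts) > 0) for (w in 1:20) {
      p <- which.max(acts[w, ])
      if (acts[w, p] > thr && all(codes[w, p:(p + 10)] > 0)) {
        want <- c(want, paste(base_order[codes[w, p:(p + 10)]], collapse = ""))
      }
    }
    expect_equal(sel[[f]], want)
  }
})

test_that("PWM construction follows the pseudocount formula and conventions", {
  # identical k-mers, no pseudocount: one-hot rows, 22 bits
  p1 <- build_pwm(rep("ACGTACGTACG", 10), pseudocount = 0)
  expect_true(all(p1$pwm %in% c(0, 1)))
  expect_equal(p1$ic, 22)
  expect_equal(p1$n_windows, 10L)
  # empty selection: uniform, zero information
  p0 <- build_pwm(character(0), width = 11L)
  expect_true(all(p0$pwm == 0.25))
  expect_equal(p0$ic, 0)
  expect_equal(p0$n_windows, 0L)
  # 50/50 complementary pair, pseudocount 0.5: (c + 0.5) / (n + 4 * 0.5)
  p2 <- build_pwm(c("AAAAAAAAAAA", "TTTTTTTTTTT"), pseudocount = 0.5)
  expect_true(all(abs(p2$pwm[, "A"] - 1.5 / 4) < 1e-12))
  expect_true(all(abs(p2$pwm[, "T"] - 1.5 / 4) < 1e-12))
  expect_true(all(abs(p2$pwm[, "C"] - 0.5 / 4) < 1e-12))
  # permutation invariance
  set.seed(53)
  km <- replicate(8, paste(sample(c("A", "C", "G", "T"), 11, TRUE), collapse = ""))
  expect_equal(build_pwm(km)$pwm, build_pwm(rev(km))$pwm)
  expect_error(build_pwm("ACGT"), "length")
  expect_error(build_pwm(c("ACGTACGTACN")), "A/C/G/T")
  # rows always sum to one
  expect_true(all(abs(rowSums(build_pwm(km)$pwm) - 1) < 1e-9))
})

test_that("activity, effect and PCA behave per their definitions", {
  m <- planted_model()
  codes <- windows_with("TATATATATAT", n_with = 6, n_without = 6)
  fa <- filter_activations(m, codes)
  act <- motif_activity(fa)
  expect_equal(dim(act$mean), c(4L, 12L))
  # spot-check the mean against direct recomputation
  expect_equal(act$mean[2, 5], mean(fa$act[5, , 2]))
  expect_equal(act$max[1, 3], max(fa$act[3, , 1]))

  labels <- rep(c(1L, 0L), each = 6)
  eff <- motif_effect(act, labels)
  expect_equal(eff[1], cor(act$mean[1, ], labels))
  expect_gt(eff[1], 0.9)   # detector activity coincides with labels
  # zero-variance filter is flagged with effect 0
  act2 <- act
  act2$mean[3, ] <- 1
  eff2 <- motif_effect(act2, labels)
  expect_equal(eff2[3], 0)
  expect_true(3L %in% attr(eff2, "zero_variance"))
  # activity identical to labels gives effect exactly 1
  act3 <- act
  act3$mean[4, ] <- labels
  expect_equal(motif_effect(act3, labels)[4], 1)
  expect_error(motif_effect(act, rep(1L, 12)), "both classes")
})

test_that("activity PCA matches a from-scratch eigendecomposition oracle", {
  set.seed(54)
  A <- matrix(rnorm(5 * 20), 5, 20)
  act <- structure(list(mean = A, max = A), class = "activity_table")
  got <- pca_motifs(act)
  Xc <- scale(A, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Xc) / (nrow(A) - 1))
  want <- Xc %*% eg$vectors[, 1:2]
  for (j in 1:2) {
    r <- abs(cor(got[, j], want[, j]))
    expect_gt(r, 1 - 1e-9)
  }
  # coordinate covariance is diagonal with non-increasing variances
  cv <- cov(got)
  expect_lt(abs(cv[1, 2]), 1e-9)
  expect_gte(cv[1, 1], cv[2, 2])
  # duplicated filters land on identical coordinates
  A2 <- rbind(A, A[1, ])
  act2 <- structure(list(mean = A2, max = A2), class = "activity_table")
  got2 <- pca_motifs(act2)
  expect_equal(got2[1, ], got2[6, ])
  expect_error(pca_motifs(structure(list(mean = A[1:2, ], max = A[1:2, ]),
                                    class = "activity_table")), ">= 3 filters")
})

test_that("motif-consensus matching is high for faithful PWMs, low for noise", {
  cons <- "TATTTAAATAT"
  p <- build_pwm(rep(cons, 20), pseudocount = 0.5)
  expect_gt(match_motif(p$pwm, cons), 0.9)
  # reverse-complement occurrences match too
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
  p_rc <- build_pwm(rep(rc, 20), pseudocount = 0.5)
  expect_gt(match_motif(p_rc$pwm, cons), 0.9)
  set.seed(55)
  unif <- matrix(0.25, 11, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_lt(match_motif(unif + 1e-9 * matrix(rnorm(44), 11, 4), cons), 0.8)
})

test_that("extract_motifs assembles a coherent motif set and MEME export", {
  m <- planted_model()
  codes <- windows_with("TATATATATAT", n_with = 6, n_without = 6)
  ds <- structure(list(seq = codes, nbr = matrix(0.5, 12, 8),
                       label = rep(c(1L, 0L), each = 6),
                       site = NULL, spec = motif_enc()),
                  class = "methyl_dataset")
  ms <- extract_motifs(m, ds)
  expect_s3_class(ms, "motif_set")
  expect_equal(length(ms$pwm), 4L)
  expect_equal(nrow(ms$table), 4L)
  expect_gt(ms$table$n_windows[1], 0L)
  expect_gt(ms$table$effect[1], 0.5)
  path <- tempfile(fileext = ".meme")
  write_meme(ms, path)
  expect_equal(sum(grepl("^MOTIF ", readLines(path))), 4L)
  tab <- tempfile(fileext = ".tsv")
  write_motif_table(ms, tab)
  expect_equal(nrow(read.delim(tab)), 4L)
})
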