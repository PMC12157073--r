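test_that("one-hot windows center a C, pad edges and decode back", {
  g <- random_genome(1, 2000, seed = 5)
  s <- g[["chr1"]]
  spec <- encoding_spec(window_radius = 500, k_neighbors = 25, d_max = 100)
  cpos <- which(strsplit(s, "")[[1]] == "C")
  p <- cpos[cpos > 600 & cpos < 1400][1]
  oh <- one_hot_window(s, p, "+", spec)
  expect_equal(dim(oh), c(1001L, 4L))
  expect_equal(unname(oh[501, ]), c(0L, 0L, 0L, 1L))  # center row is C
  expect_true(all(rowSums(oh) %in% c(0L, 1L)))
  expect_equal(decode_window(oh), substr(s, p - 500, p + 500))

  # site near the chromosome start: rows before base 1 are all-zero
  p10 <- cpos[cpos >= 10][1]
  oh2 <- one_hot_window(s, p10, "+", spec)
  n_pad <- 500 - (p10 - 1)
  expect_true(all(oh2[seq_len(n_pad), ] == 0L))
  expect_true(all(rowSums(oh2[(n_pad + 1):1001, , drop = FALSE]) == 1L))

  # not a cytosine in model orientation -> error
  apos <- which(strsplit(s, "")[[1]] == "A")[1]
  expect_error(one_hot_window(s, apos, "+", spec), "not a cytosine")
})

test_that("minus-strand windows are the reverse complement view", {
  g <- random_genome(1, 400, seed = 6)
  s <- g[["chr1"]]
  spec <- encoding_spec(window_radius = 20, k_neighbors = 2, d_max = 10)
  gpos <- which(strsplit(s, "")[[1]] == "G")
  p <- gpos[gpos > 30 & gpos < 370][1]
  oh <- one_hot_window(s, p, "-", spec)
  expect_equal(unname(oh[21, ]), c(0L, 0L, 0L, 1L))
  # decode equals reverse complement of the plus-strand slice
  fwd <- substr(s, p - 20, p + 20)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fwd, "")[[1]]), collapse = ""))
  expect_equal(decode_window(oh), rc)
  # complement-strand plus-window at the same position is the row-reversed view
  oh_plus_at_comp <- one_hot_window(chartr("ACGT", "TGCA", s), p, "+", spec)
  expect_equal(unname(oh), unname(oh_plus_at_comp[41:1, ]))
  # and encoding the mirrored site of the reverse-complemented chromosome on
  # the minus strand reproduces the original plus-strand window exactly
  s_rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  q <- which(strsplit(s, "")[[1]] == "C")
  q <- q[q > 30 & q < 370][1]
  w_plus <- one_hot_window(s, q, "+", spec)
  w_mirror <- one_hot_window(s_rc, nchar(s) - q + 1L, "-", spec)
  expect_equal(w_plus, w_mirror)
})

test_that("neighbor features follow the documented layout and hand oracle", {
  spec <- encoding_spec(window_radius = 5, k_neighbors = 1, d_max = 100)
  pos <- c(10L, 20L, 35L)
  lab <- c(1L, NA, 0L)
  v <- neighbor_features(pos, lab, 2L, spec, training = FALSE)
  expect_equal(v, c(1, 0, 0.10, 0.15))

  # first site of a chromosome: left slots are pads
  spec2 <- encoding_spec(window_radius = 5, k_neighbors = 2, d_max = 50)
  v2 <- neighbor_features(c(10L, 20L, 30L), c(1L, 1L, 1L), 1L, spec2, training = FALSE)
  expect_equal(v2[1:2], c(0.5, 0.5))            # left states padded
  expect_equal(v2[5:6], c(1, 1))                # left distances padded
  expect_equal(v2[3:4], c(1, 1))                # right states
  expect_equal(v2[7:8], c(10 / 50, 20 / 50))    # right distances nearest-first

  # NA target is an error for training examples only
  expect_error(neighbor_features(pos, lab, 2L, spec, training = TRUE), "NA label")
})

test_that("neighbor features agree with a brute-force scan oracle", {
  brute <- function(pos, lab, i, k, dmax) {
    p <- pos[i]
    elig <- which(!is.na(lab) & seq_along(pos) != i)
    left <- elig[pos[elig] < p]; left <- left[order(pos[left])]
    right <- elig[pos[elig] > p]; right <- right[order(pos[right])]
    left <- tail(left, k); right <- head(right, k)
    st <- rep(0.5, 2 * k); di <- rep(1, 2 * k)
    if (length(left)) {
      sl <- (k - length(left) + 1):k
      st[sl] <- lab[left]; di[sl] <- pmin(abs(pos[left] - p) / dmax, 1)
    }
    if (length(right)) {
      sr <- k + seq_along(right)
      st[sr] <- lab[right]; di[sr] <- pmin(abs(pos[right] - p) / dmax, 1)
    }
    c(st, di)
  }
  set.seed(11)
  for (k in c(1L, 2L, 25L)) {
    pos <- sort(sample(10000L, 80L))
    lab <- sample(c(0L, 1L, NA), 80, replace = TRUE, prob = c(.45, .45, .1))
    spec <- encoding_spec(window_radius = 5, k_neighbors = k, d_max = 500)
    for (i in sample(which(!is.na(lab)), 10)) {
      expect_equal(neighbor_features(pos, lab, i, spec),
                   brute(pos, lab, i, k, 500))
    }
  }
})

test_that("emitted distances never exceed 1 when d_max comes from the data", {
  set.seed(12)
  pos <- sort(sample(5000L, 60L))
  lab <- sample(0:1, 60, replace = TRUE)
  rec <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+", label = lab)
  dmax <- max_neighbor_gap(rec)
  spec <- encoding_spec(window_radius = 5, k_neighbors = 3, d_max = dmax)
  for (i in sample(60, 10)) {
    v <- neighbor_features(pos, lab, i, spec)
    expect_true(all(v[7:12] <= 1))
  }
})

test_that("build_dataset assembles aligned tensors and rejects bad input", {
  g <- random_genome(1, 3000, seed = 7)
  chars <- strsplit(g[["chr1"]], "")[[1]]
  cpos <- which(chars == "C")[1:40]
  rec <- data.table::data.table(chrom = "chr1", pos = cpos, strand = "+",
                                label = rep(c(0L, 1L), 20))
  spec <- encoding_spec(window_radius = 10, k_neighbors = 2,
                        d_max = max_neighbor_gap(rec))
  ds <- build_dataset(rec, g, spec)
  expect_s3_class(ds, "methyl_dataset")
  expect_equal(dim(ds$seq), c(40L, 21L))
  expect_equal(dim(ds$nbr), c(40L, 8L))
  # every window's central code is C (code 4 in A,T,G,C order)
  expect_true(all(ds$seq[, 11] == 4L))
  # row i matches the single-site encoders
  i <- 17L
  oh <- one_hot_window(g[["chr1"]], ds$site$pos[i], "+", spec)
  expect_equal(decode_window(oh),
               paste(c("N", "A", "T", "G", "C")[ds$seq[i, ] + 1L], collapse = ""))
  expect_equal(unname(ds$nbr[i, ]),
               unname(neighbor_features(rec$pos, rec$label, i, spec)))

  expect_error(build_dataset(rec[0], g, spec), "empty")
  rec_na <- data.table::copy(rec); rec_na$label[1] <- NA_integer_
  expect_error(build_dataset(rec_na, g, spec), "NA-labeled")
  expect_silent(build_dataset(rec_na, g, spec, allow_na = TRUE))
  expect_error(build_dataset(data.table::data.table(
    chrom = "chrZ", pos = 5L, strand = "+", label = 1L), g, spec), "absent")
})
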