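small_enc <- function() encoding_spec(window_radius = 20, k_neighbors = 3, d_max = 100)
small_dna <- function(dropout = 0) dna_model_spec(8, 5, 2, 6, 3, 2, fc_units = 10, dropout = dropout)
small_meth <- function(dropout = 0) meth_model_spec(td_units = 4, gru1_units = 5, gru2_units = 6, dropout = dropout)

small_ds <- function(n = 60, seed = 30, spec = small_enc()) {
  g <- random_genome(1, 4000, seed = seed)
  cpos <- which(strsplit(g[["chr1"]], "")[[1]] == "C")[1:n]
  set.seed(seed)
  rec <- data.table::data.table(chrom = "chr1", pos = cpos, strand = "+",
                                label = sample(0:1, n, TRUE))
  build_dataset(rec, g, spec)
}

test_that("default architectures expose the canonical dimensions", {
  enc <- encoding_spec()
  expect_equal(enc$window_length, 1001L)
  expect_equal(enc$n_features, 100L)
  m <- build_dna_model(dna_model_spec(), enc)
  filt <- get_first_layer_filters(m)
  expect_equal(dim(filt), c(128L, 11L, 4L))
  expect_equal(dimnames(filt)[[3]], c("A", "T", "G", "C"))
  expect_equal(dna_model_spec()$fc_units, 256L)           # DNA embedding width
  expect_equal(meth_model_spec()$embedding_dim, 512L)     # BiGRU embedding width
  expect_equal(dna_model_spec()$fc_units + meth_model_spec()$embedding_dim, 768L)
})

test_that("parameter counts match hand-computed closed forms", {
  enc <- small_enc()  # window 41
  spec <- small_dna()
  m <- build_dna_model(spec, enc)
  out1 <- 41 - 5 + 1                      # 37
  o1p <- (out1 - 2) %/% 2 + 1             # 18
  out2 <- o1p - 3 + 1                     # 16
  o2p <- (out2 - 2) %/% 2 + 1             # 8
  flat <- o2p * 6
  want <- (5 * 4 * 8 + 8) + (3 * 8 * 6 + 6) + (flat * 10 + 10) + (10 + 1)
  expect_equal(n_params(m), want)

  ms <- small_meth()
  mm <- build_meth_model(ms, enc)
  gru <- function(d, h) d * 3 * h + h * 3 * h + 3 * h
  want_m <- (2 * 4 + 4) +                        # time-distributed dense
    2 * gru(4, 5) + 2 * gru(2 * 5, 6) +          # two BiGRU layers
    (2 * 6 + 1)                                  # head
  expect_equal(n_params(mm), want_m)
})

test_that("model heads give valid probabilities on degenerate input", {
  enc <- small_enc()
  set.seed(4)
  m <- build_dna_model(small_dna(), enc)
  zero_batch <- list(seq = matrix(0L, 2, enc$window_length),
                     nbr = matrix(0.5, 2, enc$n_features), label = c(0L, 1L))
  p <- methydeep:::model_forward(m, zero_batch)$prob
  expect_true(all(is.finite(p) & p > 0 & p < 1))
  mm <- build_meth_model(small_meth(), enc)
  pad <- list(seq = zero_batch$seq,
              nbr = cbind(matrix(0.5, 2, 6), matrix(1, 2, 6)), label = c(0L, 1L))
  pm <- methydeep:::model_forward(mm, pad)$prob
  expect_true(all(is.finite(pm) & pm > 0 & pm < 1))
})

test_that("joint model is the head applied to the concatenated branch embeddings", {
  md <- asNamespace("methydeep")
  enc <- small_enc()
  set.seed(9)
  jm <- build_joint_model(small_dna(), small_meth(), joint_model_spec(7L), enc)
  ds <- small_ds(8)
  b <- md$batch_of(ds, 1:8)
  full <- md$model_forward(jm, b)$prob
  e_dna <- md$dna_embed_forward(jm$params$dna, jm$dna_spec, b$seq, FALSE, enc)$emb
  e_meth <- md$meth_embed_forward(jm$params$meth, jm$meth_spec, b$nbr, FALSE)$emb
  emb <- cbind(e_dna, e_meth)
  expect_equal(ncol(emb), small_dna()$fc_units + small_meth()$embedding_dim)
  h1 <- pmax(sweep(emb %*% jm$params$joint$W1, 2, jm$params$joint$b1, "+"), 0)
  h2 <- pmax(sweep(h1 %*% jm$params$joint$W2, 2, jm$params$joint$b2, "+"), 0)
  by_hand <- as.vector(1 / (1 + exp(-(h2 %*% jm$params$head$Wo + jm$params$head$bo))))
  expect_equal(full, by_hand, tolerance = 1e-12)

  # zero head weights force sigmoid(0) = 0.5 exactly
  jm$params$head$Wo[] <- 0
  jm$params$head$bo <- 0
  expect_equal(md$model_forward(jm, b)$prob, rep(0.5, 8))
})

test_that("input dimension mismatches are rejected", {
  enc <- small_enc()
  set.seed(10)
  m <- build_dna_model(small_dna(), enc)
  bad <- list(seq = matrix(1L, 2, 10), nbr = matrix(0.5, 2, 12), label = c(0L, 1L))
  expect_error(methydeep:::model_forward(m, bad), "length")
  ds <- small_ds(5)
  other <- build_dna_model(small_dna(), encoding_spec(10, 3, 100))
  expect_error(predict(other, ds), "encoding")
})

test_that("training is reproducible, improves a separable task, and early-stops", {
  enc <- small_enc()
  # separable toy task: label = methylation state of the nearest right neighbor
  set.seed(21)
  g <- random_genome(1, 9000, seed = 21)
  cpos <- which(strsplit(g[["chr1"]], "")[[1]] == "C")[1:400]
  lab <- integer(400)
  lab[400] <- 1L
  for (i in 399:1) lab[i] <- if (runif(1) < 0.9) lab[i + 1] else 1L - lab[i + 1]
  rec <- data.table::data.table(chrom = "chr1", pos = cpos, strand = "+", label = lab)
  ds <- build_dataset(rec, g, enc)
  cfg <- train_config(learning_rate = 5e-3, batch_size = 64L, max_epochs = 10L,
                      patience = 10L, seed = 5L)
  set.seed(5)
  m1 <- train(build_meth_model(small_meth(), enc), ds, NULL, cfg)
  p1 <- predict(m1, ds)
  expect_gt(suppressWarnings(metrics(ds$label, p1))$auc, 0.9)
  # same seed, same data -> bit-identical history and predictions
  set.seed(5)
  m2 <- train(build_meth_model(small_meth(), enc), ds, NULL, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m2, ds), p1)

  # patience 0 stops right after the first non-improvement of the monitor
  cfg0 <- train_config(max_epochs = 10L, patience = 0L, seed = 5L)
  set.seed(5)
  m3 <- train(build_meth_model(small_meth(), enc), ds, NULL, cfg0)
  h <- m3$history$train_loss
  if (nrow(m3$history) < 10L) {
    expect_true(h[length(h)] >= min(h[-length(h)]))      # stopped on a non-improvement
    if (length(h) > 2L) expect_true(all(diff(h[1:(length(h) - 1)]) < 0))
  }
})

test_that("single-class training warns and prediction is batch-invariant", {
  enc <- small_enc()
  ds <- small_ds(20, seed = 33)
  ds$label[] <- 1L
  cfg <- train_config(max_epochs = 1L, seed = 2L)
  set.seed(2)
  expect_warning(train(build_meth_model(small_meth(), enc), ds, NULL, cfg),
                 "single-class")
  ds2 <- small_ds(30, seed = 34)
  set.seed(3)
  m <- build_dna_model(small_dna(), enc)
  p_all <- predict(m, ds2, batch_size = 512L)
  p_one <- vapply(seq_len(30), function(i) {
    predict(m, methydeep:::dataset_subset(ds2, i))
  }, 0)
  expect_equal(p_all, p_one, tolerance = 1e-12)
})

test_that("checkpoints round-trip weights bit-exactly", {
  enc <- small_enc()
  set.seed(6)
  m <- build_dna_model(small_dna(), enc)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(get_first_layer_filters(m2), get_first_layer_filters(m))
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$kind, "dna")
  # a methylation-only model has no first-layer filters
  mm <- build_meth_model(small_meth(), enc)
  expect_error(get_first_layer_filters(mm), "DNA branch")
})
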