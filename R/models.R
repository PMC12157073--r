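# The three architectures: a CNN over the one-hot DNA window, a
# bidirectional-GRU model over neighbor methylation states/distances, and a
# joint classifier over the concatenated embeddings.

#' DNA model architecture specification
#'
#' Defaults follow the reference architecture: conv(128 filters, kernel 11,
#' stride 1) + ReLU, max-pool 4, conv(256, kernel 3) + ReLU, max-pool 2,
#' flatten, dense(`fc_units`) + ReLU, dropout, sigmoid head. The post-dropout
#' dense output is the model's embedding; its default width of 256 makes the
#' joint model's 768-long concatenated input come out exactly.
#'
#' @param n_filters1,kernel1,pool1 First convolution block.
#' @param n_filters2,kernel2,pool2 Second convolution block.
#' @param fc_units Dense embedding width.
#' @param dropout Dropout rate after the dense layer.
#' @return A `dna_model_spec`.
#' @export
dna_model_spec <- function(n_filters1 = 128L, kernel1 = 11L, pool1 = 4L,
                           n_filters2 = 256L, kernel2 = 3L, pool2 = 2L,
                           fc_units = 256L, dropout = 0.25) {
  stopifnot(kernel1 %% 2L == 1L, fc_units > 0L, dropout >= 0, dropout < 1)
  structure(list(n_filters1 = as.integer(n_filters1), kernel1 = as.integer(kernel1),
                 pool1 = as.integer(pool1), n_filters2 = as.integer(n_filters2),
                 kernel2 = as.integer(kernel2), pool2 = as.integer(pool2),
                 fc_units = as.integer(fc_units), dropout = dropout),
            class = "dna_model_spec")
}

#' Methylation (neighbor) model architecture specification
#'
#' Defaults follow the reference architecture: the 4k-long neighbor vector is
#' reshaped to 2k timesteps x 2 features (state, distance), passed through a
#' time-distributed dense layer, then two bidirectional GRU layers (128 and
#' 256 units; L1 and L2 penalties of 1e-4 on the first layer's weights),
#' dropout, and a sigmoid head. The embedding is the final 2 x `gru2_units`
#' concatenated last hidden state (512 by default).
#'
#' @param td_units Time-distributed dense width.
#' @param gru1_units,gru2_units Units per direction of the two BiGRU layers.
#' @param l1,l2 Weight-penalty coefficients on the first GRU layer.
#' @param dropout Dropout rate before the head.
#' @return A `meth_model_spec`.
#' @export
meth_model_spec <- function(td_units = 32L, gru1_units = 128L, gru2_units = 256L,
                            l1 = 1e-4, l2 = 1e-4, dropout = 0.25) {
  structure(list(td_units = as.integer(td_units), gru1_units = as.integer(gru1_units),
                 gru2_units = as.integer(gru2_units), l1 = l1, l2 = l2,
                 dropout = dropout, embedding_dim = 2L * as.integer(gru2_units)),
            class = "meth_model_spec")
}

#' Joint model architecture specification
#'
#' Two dense layers (512 units each, ReLU) over the concatenated DNA and
#' methylation embeddings (256 + 512 = 768 by default), then a sigmoid head.
#'
#' @param fc_units Width of the two dense layers.
#' @return A `joint_model_spec`.
#' @export
joint_model_spec <- function(fc_units = 512L) {
  structure(list(fc_units = as.integer(fc_units)), class = "joint_model_spec")
}

#' Training configuration
#'
#' All optimization settings: Adam learning rate, batch size, epoch budget,
#' early stopping on validation loss, optional inverse-frequency class
#' weighting, and the seed governing shuffling, initialization of dropout
#' masks and any other training randomness.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on epochs.
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param lr_decay Factor applied to the learning rate after any epoch whose
#'   monitored loss did not improve (1 = constant rate).
#' @param class_weight Weight positive examples by inverse class frequency.
#' @param seed Integer seed for all training randomness.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 128L, max_epochs = 20L,
                         patience = 5L, lr_decay = 0.5, class_weight = FALSE,
                         seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 0L, lr_decay > 0, lr_decay <= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 lr_decay = lr_decay,
                 class_weight = isTRUE(class_weight), seed = as.integer(seed)),
            class = "train_config")
}

dna_out_sizes <- function(spec, window_length) {
  out1 <- window_length - spec$kernel1 + 1L
  o1p <- (out1 - spec$pool1) %/% spec$pool1 + 1L
  out2 <- o1p - spec$kernel2 + 1L
  o2p <- (out2 - spec$pool2) %/% spec$pool2 + 1L
  list(out1 = out1, o1p = o1p, out2 = out2, o2p = o2p,
       flat = o2p * spec$n_filters2)
}

dna_params_init <- function(spec, window_length) {
  sz <- dna_out_sizes(spec, window_length)
  list(W1 = nn_glorot(spec$kernel1 * 4L, spec$n_filters1),
       b1 = rep(0, spec$n_filters1),
       W2 = nn_glorot(spec$kernel2 * spec$n_filters1, spec$n_filters2),
       b2 = rep(0, spec$n_filters2),
       Wf = nn_glorot(sz$flat, spec$fc_units),
       bf = rep(0, spec$fc_units))
}

meth_params_init <- function(spec) {
  list(Wtd = nn_glorot(2L, spec$td_units),
       btd = rep(0, spec$td_units),
       g1f = nn_gru_init(spec$td_units, spec$gru1_units),
       g1b = nn_gru_init(spec$td_units, spec$gru1_units),
       g2f = nn_gru_init(2L * spec$gru1_units, spec$gru2_units),
       g2b = nn_gru_init(2L * spec$gru1_units, spec$gru2_units))
}

head_params_init <- function(d_in) {
  list(Wo = nn_glorot(d_in, 1L), bo = 0)
}

new_methyl_model <- function(kind, params, encoding, dna_spec = NULL,
                             meth_spec = NULL, joint_spec = NULL) {
  structure(list(kind = kind, params = params, encoding = encoding,
                 dna_spec = dna_spec, meth_spec = meth_spec,
                 joint_spec = joint_spec, history = NULL, trained = FALSE),
            class = "methyl_model")
}

#' Build an untrained DNA (sequence CNN) model
#'
#' @param spec A [dna_model_spec()].
#' @param encoding The [encoding_spec()] the model will consume.
#' @return A `methyl_model` of kind "dna". Initialization draws from the
#'   current RNG; call `set.seed()` first for reproducibility.
#' @export
build_dna_model <- function(spec = dna_model_spec(), encoding = encoding_spec()) {
  sz <- dna_out_sizes(spec, encoding$window_length)
  if (sz$o2p < 1L) stop("window too short for this architecture")
  params <- list(dna = dna_params_init(spec, encoding$window_length),
                 head = head_params_init(spec$fc_units))
  new_methyl_model("dna", params, encoding, dna_spec = spec)
}

#' Build an untrained methylation (neighbor BiGRU) model
#'
#' @param spec A [meth_model_spec()].
#' @param encoding The [encoding_spec()] the model will consume.
#' @return A `methyl_model` of kind "meth".
#' @export
build_meth_model <- function(spec = meth_model_spec(), encoding = encoding_spec()) {
  params <- list(meth = meth_params_init(spec),
                 head = head_params_init(spec$embedding_dim))
  new_methyl_model("meth", params, encoding, meth_spec = spec)
}

#' Build an untrained joint model
#'
#' Concatenates the DNA and methylation embeddings (768 dimensions with the
#' default specs) and classifies through two dense layers. Trained end-to-end
#' from scratch by default; pass pretrained single models as `init_from` to
#' warm-start the two branches.
#'
#' @param dna_spec,meth_spec,joint_spec Architecture specs.
#' @param encoding The [encoding_spec()].
#' @param init_from Optional list(dna = , meth = ) of trained single models.
#' @return A `methyl_model` of kind "joint".
#' @export
build_joint_model <- function(dna_spec = dna_model_spec(), meth_spec = meth_model_spec(),
                              joint_spec = joint_model_spec(),
                              encoding = encoding_spec(), init_from = NULL) {
  d_in <- dna_spec$fc_units + meth_spec$embedding_dim
  params <- list(dna = dna_params_init(dna_spec, encoding$window_length),
                 meth = meth_params_init(meth_spec),
                 joint = list(W1 = nn_glorot(d_in, joint_spec$fc_units),
                              b1 = rep(0, joint_spec$fc_units),
                              W2 = nn_glorot(joint_spec$fc_units, joint_spec$fc_units),
                              b2 = rep(0, joint_spec$fc_units)),
                 head = head_params_init(joint_spec$fc_units))
  if (!is.null(init_from)) {
    if (!is.null(init_from$dna)) params$dna <- init_from$dna$params$dna
    if (!is.null(init_from$meth)) params$meth <- init_from$meth$params$meth
  }
  new_methyl_model("joint", params, encoding,
                   dna_spec = dna_spec, meth_spec = meth_spec, joint_spec = joint_spec)
}

#' @export
print.methyl_model <- function(x, ...) {
  cat("<methyl_model> kind=", x$kind,
      if (x$trained) " (trained)" else " (untrained)",
      ", ", format(n_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `methyl_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(unlist(rapply(model$params, length, how = "list")))
}

# --- forward / backward -------------------------------------------------

dna_embed_forward <- function(p, spec, codes, training, encoding) {
  B <- nrow(codes)
  if (ncol(codes) != encoding$window_length) {
    stop("sequence input has length ", ncol(codes),
         ", model expects ", encoding$window_length)
  }
  sz <- dna_out_sizes(spec, encoding$window_length)
  P1 <- nn_im2col_codes(codes, spec$kernel1)
  Z1 <- nn_conv_forward(P1, p$W1, p$b1, B, sz$out1)
  m1 <- nn_maxpool_forward(Z1, spec$pool1)
  mask1 <- m1$M > 0
  A1 <- m1$M * mask1                      # ReLU on the pooled tensor
  P2 <- nn_im2col(A1, spec$kernel2)
  Z2 <- nn_conv_forward(P2, p$W2, p$b2, B, sz$out2)
  m2 <- nn_maxpool_forward(Z2, spec$pool2)
  mask2 <- m2$M > 0
  flat <- m2$M * mask2
  dim(flat) <- c(B, sz$flat)
  fc <- nn_dense_forward(flat, p$Wf, p$bf, relu = TRUE)
  dr <- nn_dropout_forward(fc$A, spec$dropout, training)
  list(emb = dr$A,
       cache = list(B = B, sz = sz, P1 = P1, m1 = m1, mask1 = mask1,
                    P2 = P2, m2 = m2, mask2 = mask2, fc = fc, dr = dr))
}

dna_embed_backward <- function(p, spec, cache, dEmb) {
  dFc <- nn_dropout_backward(dEmb, cache$dr)
  dd <- nn_dense_backward(dFc, cache$fc, p$Wf)
  dM2 <- dd$dX
  dim(dM2) <- c(cache$B, cache$sz$o2p, spec$n_filters2)
  dZ2 <- nn_maxpool_backward(dM2 * cache$mask2, cache$m2, spec$pool2, spec$n_filters2)
  cb2 <- nn_conv_backward(dZ2, cache$P2, p$W2)
  dA1 <- nn_im2col_backward(cb2$dP, cache$B, cache$sz$o1p, spec$n_filters1, spec$kernel2)
  dZ1 <- nn_maxpool_backward(dA1 * cache$mask1, cache$m1, spec$pool1, spec$n_filters1)
  cb1 <- nn_conv_backward(dZ1, cache$P1, p$W1)
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db, Wf = dd$dW, bf = dd$db)
}

nbr_to_steps <- function(nbr) {
  B <- nrow(nbr); TT <- ncol(nbr) %/% 2L
  X <- array(0, c(B, TT, 2L))
  X[, , 1L] <- nbr[, 1:TT]
  X[, , 2L] <- nbr[, TT + 1:TT]
  X
}

meth_embed_forward <- function(p, spec, nbr, training) {
  B <- nrow(nbr)
  X <- nbr_to_steps(nbr)
  TT <- dim(X)[2]
  Xm <- X; dim(Xm) <- c(B * TT, 2L)
  td <- nn_dense_forward(Xm, p$Wtd, p$btd, relu = TRUE)
  TD <- td$A; dim(TD) <- c(B, TT, spec$td_units)
  g1f <- nn_gru_forward(TD, p$g1f)
  g1b <- nn_gru_forward(nn_reverse_time(TD), p$g1b)
  H1 <- array(0, c(B, TT, 2L * spec$gru1_units))
  H1[, , 1:spec$gru1_units] <- g1f$H
  H1[, , spec$gru1_units + 1:spec$gru1_units] <- nn_reverse_time(g1b$H)
  g2f <- nn_gru_forward(H1, p$g2f)
  g2b <- nn_gru_forward(nn_reverse_time(H1), p$g2b)
  pre <- cbind(g2f$h_T, g2b$h_T)
  dr <- nn_dropout_forward(pre, spec$dropout, training)
  list(emb = dr$A,
       cache = list(B = B, TT = TT, td = td, g1f = g1f, g1b = g1b,
                    g2f = g2f, g2b = g2b, dr = dr))
}

meth_embed_backward <- function(p, spec, cache, dEmb) {
  B <- cache$B; TT <- cache$TT
  H2 <- spec$gru2_units; H1u <- spec$gru1_units
  dPre <- nn_dropout_backward(dEmb, cache$dr)
  dHf <- array(0, c(B, TT, H2)); dHf[, TT, ] <- dPre[, 1:H2, drop = FALSE]
  dHb <- array(0, c(B, TT, H2)); dHb[, TT, ] <- dPre[, H2 + 1:H2, drop = FALSE]
  b2f <- nn_gru_backward(dHf, cache$g2f, p$g2f)
  b2b <- nn_gru_backward(dHb, cache$g2b, p$g2b)
  dH1 <- b2f$dX + nn_reverse_time(b2b$dX)
  dH1f <- dH1[, , 1:H1u, drop = FALSE]
  dH1b <- nn_reverse_time(dH1[, , H1u + 1:H1u, drop = FALSE])
  b1f <- nn_gru_backward(dH1f, cache$g1f, p$g1f)
  b1b <- nn_gru_backward(dH1b, cache$g1b, p$g1b)
  dTD <- b1f$dX + nn_reverse_time(b1b$dX)
  dim(dTD) <- c(B * TT, spec$td_units)
  dtd <- nn_dense_backward(dTD, cache$td, p$Wtd)
  list(Wtd = dtd$dW, btd = dtd$db,
       g1f = list(W = b1f$dW, U = b1f$dU, b = b1f$db),
       g1b = list(W = b1b$dW, U = b1b$dU, b = b1b$db),
       g2f = list(W = b2f$dW, U = b2f$dU, b = b2f$db),
       g2b = list(W = b2b$dW, U = b2b$dU, b = b2b$db))
}

model_forward <- function(model, batch, training = FALSE) {
  p <- model$params
  if (model$kind == "dna") {
    br <- dna_embed_forward(p$dna, model$dna_spec, batch$seq, training, model$encoding)
    z <- sweep(br$emb %*% p$head$Wo, 2L, p$head$bo, "+")
    list(prob = as.vector(nn_sigmoid(z)), emb = br$emb, cache = list(dna = br$cache, emb = br$emb))
  } else if (model$kind == "meth") {
    br <- meth_embed_forward(p$meth, model$meth_spec, batch$nbr, training)
    z <- sweep(br$emb %*% p$head$Wo, 2L, p$head$bo, "+")
    list(prob = as.vector(nn_sigmoid(z)), emb = br$emb, cache = list(meth = br$cache, emb = br$emb))
  } else {
    bd <- dna_embed_forward(p$dna, model$dna_spec, batch$seq, training, model$encoding)
    bm <- meth_embed_forward(p$meth, model$meth_spec, batch$nbr, training)
    emb <- cbind(bd$emb, bm$emb)
    f1 <- nn_dense_forward(emb, p$joint$W1, p$joint$b1, relu = TRUE)
    f2 <- nn_dense_forward(f1$A, p$joint$W2, p$joint$b2, relu = TRUE)
    z <- sweep(f2$A %*% p$head$Wo, 2L, p$head$bo, "+")
    list(prob = as.vector(nn_sigmoid(z)), emb = emb,
         cache = list(dna = bd$cache, meth = bm$cache, f1 = f1, f2 = f2,
                      d_dna = ncol(bd$emb)))
  }
}

model_backward <- function(model, cache, dlogit) {
  p <- model$params
  dZ <- matrix(dlogit, ncol = 1L)
  if (model$kind == "dna") {
    dEmb <- dZ %*% t(p$head$Wo)
    list(dna = dna_embed_backward(p$dna, model$dna_spec, cache$dna, dEmb),
         head = list(Wo = crossprod(cache$emb, dZ), bo = sum(dZ)))
  } else if (model$kind == "meth") {
    dEmb <- dZ %*% t(p$head$Wo)
    list(meth = meth_embed_backward(p$meth, model$meth_spec, cache$meth, dEmb),
         head = list(Wo = crossprod(cache$emb, dZ), bo = sum(dZ)))
  } else {
    dF2 <- dZ %*% t(p$head$Wo)
    d2 <- nn_dense_backward(dF2, cache$f2, p$joint$W2)
    d1 <- nn_dense_backward(d2$dX, cache$f1, p$joint$W1)
    dd <- ncol(d1$dX); k <- cache$d_dna
    list(dna = dna_embed_backward(p$dna, model$dna_spec, cache$dna,
                                  d1$dX[, 1:k, drop = FALSE]),
         meth = meth_embed_backward(p$meth, model$meth_spec, cache$meth,
                                    d1$dX[, (k + 1L):dd, drop = FALSE]),
         joint = list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db),
         head = list(Wo = crossprod(cache$f2$A, dZ), bo = sum(dZ)))
  }
}

# L1/L2 penalty on the first-GRU weights of the methylation branch
reg_loss <- function(model) {
  if (is.null(model$params$meth)) return(0)
  sp <- model$meth_spec
  w <- model$params$meth
  mats <- list(w$g1f$W, w$g1f$U, w$g1b$W, w$g1b$U)
  sp$l1 * sum(vapply(mats, function(m) sum(abs(m)), 0)) +
    sp$l2 * sum(vapply(mats, function(m) sum(m * m), 0))
}

add_reg_grads <- function(model, grads) {
  if (is.null(model$params$meth)) return(grads)
  sp <- model$meth_spec
  for (g in c("g1f", "g1b")) for (m in c("W", "U")) {
    w <- model$params$meth[[g]][[m]]
    grads$meth[[g]][[m]] <- grads$meth[[g]][[m]] + sp$l1 * sign(w) + 2 * sp$l2 * w
  }
  grads
}

batch_of <- function(ds, idx) list(seq = ds$seq[idx, , drop = FALSE],
                                   nbr = ds$nbr[idx, , drop = FALSE],
                                   label = ds$label[idx])

#' Train a model
#'
#' Minimizes binary cross-entropy with Adam, early-stopping on validation
#' loss; the weights from the best validation epoch are kept. With no
#' validation set, training loss drives the stopping rule. Fully reproducible
#' under a fixed `config$seed`.
#'
#' @param model An untrained (or trained) `methyl_model`.
#' @param train_set,val_set `methyl_dataset`s from [build_dataset()];
#'   `val_set` may be NULL.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `methyl_model` with a `history` data.frame.
#' @export
train <- function(model, train_set, val_set = NULL, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "methyl_model"))
  y <- train_set$label
  if (length(y) == 0L) stop("empty training set")
  if (anyNA(y)) stop("training labels contain NA")
  if (length(unique(y)) < 2L) {
    warning("single-class training set; ranking metrics on it are undefined")
  }
  set.seed(config$seed)
  if (!model$trained) {
    # start the head at the base-rate logit so early epochs refine ranking
    # instead of first learning the class prior
    pr <- min(max(mean(y), 1e-4), 1 - 1e-4)
    model$params$head$bo <- stats::qlogis(pr)
  }
  w_pos <- 1; w_neg <- 1
  if (config$class_weight) {
    pr <- mean(y)
    w_pos <- 1 / (2 * max(pr, 1e-6)); w_neg <- 1 / (2 * max(1 - pr, 1e-6))
  }
  opt <- nn_adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  bad <- 0L
  hist <- list()
  n <- length(y)
  lr <- config$learning_rate
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tl <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      b <- batch_of(train_set, idx)
      fw <- model_forward(model, b, training = TRUE)
      wts <- ifelse(b$label == 1L, w_pos, w_neg)
      loss <- -mean(wts * (b$label * log(pmax(fw$prob, 1e-7)) +
                             (1 - b$label) * log(pmax(1 - fw$prob, 1e-7))))
      dlogit <- wts * (fw$prob - b$label) / length(idx)
      grads <- model_backward(model, fw$cache, dlogit)
      grads <- add_reg_grads(model, grads)
      stepped <- nn_adam_step(model$params, grads, opt, lr = lr)
      model$params <- stepped$params
      opt <- stepped$opt
      tl <- tl + loss; nb <- nb + 1L
    }
    train_loss <- tl / nb + reg_loss(model)
    if (!is.null(val_set)) {
      vp <- predict(model, val_set)
      monitor <- nn_bce(vp, val_set$label) + reg_loss(model)
    } else {
      monitor <- train_loss
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = if (is.null(val_set)) NA_real_ else monitor,
                                lr = lr)
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  monitor %.4f  lr %.2e",
                      epoch, train_loss, monitor, lr))
    }
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = model$params, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) break
      lr <- lr * config$lr_decay
    }
  }
  model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model
}

#' Predict methylation probabilities
#'
#' @param object A `methyl_model`.
#' @param newdata A `methyl_dataset` encoded with the model's own
#'   [encoding_spec()] (window length and neighbor count must match).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1], one per site.
#' @export
predict.methyl_model <- function(object, newdata, batch_size = 512L, ...) {
  if (ncol(newdata$seq) != object$encoding$window_length ||
      ncol(newdata$nbr) != object$encoding$n_features) {
    stop("dataset encoding does not match the model's encoding_spec")
  }
  n <- nrow(newdata$seq)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- model_forward(object, batch_of(newdata, idx), training = FALSE)$prob
  }
  out
}

#' Binarize predicted probabilities
#'
#' The prediction-side rounding rule: probabilities strictly greater than
#' the threshold become 1; values at or below it become 0.
#'
#' @param prob Probabilities in [0, 1].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1.
#' @export
binarize_prob <- function(prob, threshold = 0.5) as.integer(prob > threshold)

#' First-layer convolutional filters
#'
#' @param model A trained or untrained `methyl_model` of kind "dna" or "joint".
#' @return Array (filter, position, channel) with channels A,T,G,C.
#' @export
get_first_layer_filters <- function(model) {
  if (is.null(model$params$dna)) stop("model has no DNA branch")
  spec <- model$dna_spec
  W1 <- model$params$dna$W1            # (kernel*4) x F
  arr <- array(0, c(spec$n_filters1, spec$kernel1, 4L),
               dimnames = list(NULL, NULL, BASE_ORDER))
  for (j in seq_len(spec$kernel1)) {
    arr[, j, ] <- t(W1[(j - 1L) * 4L + 1:4, , drop = FALSE])
  }
  arr
}

#' Save / load a trained model
#'
#' Writes the model (weights, specs, encoding metadata including `d_max`) as
#' an RDS checkpoint plus a human-readable JSON sidecar of the architecture
#' and encoding settings at `<path>.json`.
#'
#' @param model A `methyl_model`.
#' @param path Output path for the checkpoint.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(kind = model$kind,
               dna_spec = unclass(model$dna_spec),
               meth_spec = unclass(model$meth_spec),
               joint_spec = unclass(model$joint_spec),
               encoding = unclass(model$encoding),
               trained = model$trained,
               n_params = n_params(model))
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "methyl_model")) stop("not a methyl_model checkpoint: ", path)
  m
}
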