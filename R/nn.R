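# Minimal batched neural-network engine: the building blocks used by the DNA
# (CNN), methylation (bidirectional GRU) and joint models. All tensors are
# base-R arrays; heavy lifting is BLAS matrix multiplication. Every backward
# pass here is covered by finite-difference gradient checks in the test suite.

nn_glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_orthogonal <- function(n) {
  a <- matrix(stats::rnorm(n * n), n, n)
  qr.Q(qr(a))
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# --- one-hot / im2col ---------------------------------------------------

# codes: B x L integer matrix, 0 = N/off-chromosome pad, 1..4 = A,T,G,C
# returns patch matrix (B*out) x (k*4); row r corresponds to (batch b, output
# position p) with b varying fastest (r = b + (p-1)*B)
nn_im2col_codes <- function(codes, k) {
  B <- nrow(codes); L <- ncol(codes)
  out <- L - k + 1L
  nr <- B * out
  P <- matrix(0, nr, k * 4L)
  rows <- seq_len(nr)
  for (j in seq_len(k)) {
    cv <- as.vector(codes[, j:(j + out - 1L), drop = FALSE])
    nz <- which(cv > 0L)
    P[nz + ((j - 1L) * 4L + cv[nz] - 1L) * nr] <- 1
  }
  P
}

# A: (B, L, C) array -> patches (B*out) x (k*C), same row mapping as above
nn_im2col <- function(A, k) {
  d <- dim(A); B <- d[1]; L <- d[2]; C <- d[3]
  out <- L - k + 1L
  P <- array(0, c(B, out, k * C))
  for (j in seq_len(k)) {
    P[, , ((j - 1L) * C + 1L):(j * C)] <- A[, j:(j + out - 1L), , drop = FALSE]
  }
  dim(P) <- c(B * out, k * C)
  P
}

# scatter patch-gradients back onto the input grid
nn_im2col_backward <- function(dP, B, L, C, k) {
  out <- L - k + 1L
  dim(dP) <- c(B, out, k * C)
  dA <- array(0, c(B, L, C))
  for (j in seq_len(k)) {
    dA[, j:(j + out - 1L), ] <- dA[, j:(j + out - 1L), , drop = FALSE] +
      dP[, , ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dA
}

# --- conv / pool --------------------------------------------------------

# patches: (B*out) x (kC); W: kC x F; linear conv output (B, out, F).
# ReLU is applied after pooling (max commutes with a nondecreasing function),
# which keeps the full-resolution tensor free of elementwise temporaries.
nn_conv_forward <- function(patches, W, b, B, out) {
  Z <- sweep(patches %*% W, 2L, b, "+")
  dim(Z) <- c(B, out, ncol(W))
  Z
}

# dZ: (B, out, F) gradient on the linear conv output
nn_conv_backward <- function(dZ, patches, W) {
  f <- ncol(W)
  dim(dZ) <- c(length(dZ) / f, f)
  list(dW = crossprod(patches, dZ), db = colSums(dZ), dP = dZ %*% t(W))
}

# non-overlapping max pooling over the length axis (Keras "valid");
# the forward pass stores linear argmax indices for a one-shot scatter in
# the backward pass
nn_maxpool_forward <- function(A, pool) {
  d <- dim(A); B <- d[1]; L <- d[2]; C <- d[3]
  out <- (L - pool) %/% pool + 1L
  Lt <- out * pool
  At <- if (Lt == L) A else A[, 1:Lt, , drop = FALSE]
  # reinterpret as (B*pool) x (out*C): rows with pool-offset j form the
  # contiguous row block (j-1)*B + 1:B, so the max runs over cheap slices
  dim(At) <- c(B * pool, out * C)
  M <- At[1:B, , drop = FALSE]
  arg <- matrix(1L, B, out * C)
  if (pool > 1L) for (j in 2:pool) {
    S <- At[(j - 1L) * B + 1:B, , drop = FALSE]
    upd <- S > M
    M[upd] <- S[upd]
    arg[upd] <- j
  }
  pgrid <- rep(rep((seq_len(out) - 1L) * pool, each = B), C)
  cgrid <- rep(seq_len(C) - 1L, each = B * out)
  src <- seq_len(B) + (pgrid + as.vector(arg) - 1L) * B + cgrid * (B * L)
  dim(M) <- c(B, out, C)
  list(M = M, src = src, L = L)
}

nn_maxpool_backward <- function(dM, cache, pool, C) {
  B <- dim(dM)[1]
  dA <- numeric(B * cache$L * C)
  dA[cache$src] <- as.vector(dM)
  array(dA, c(B, cache$L, C))
}

# --- dense / dropout ----------------------------------------------------

nn_dense_forward <- function(X, W, b, relu = FALSE) {
  Z <- sweep(X %*% W, 2L, b, "+")
  if (relu) list(A = Z * (Z > 0), mask = Z > 0, X = X)
  else list(A = Z, mask = NULL, X = X)
}

nn_dense_backward <- function(dA, cache, W) {
  dZ <- if (is.null(cache$mask)) dA else dA * cache$mask
  list(dW = crossprod(cache$X, dZ), db = colSums(dZ), dX = dZ %*% t(W))
}

# inverted dropout; identity when training = FALSE or rate = 0
nn_dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(A = X, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(X), 1L, keep), nrow(X)) / keep
  list(A = X * mask, mask = mask)
}

nn_dropout_backward <- function(dA, cache) {
  if (is.null(cache$mask)) dA else dA * cache$mask
}

# --- GRU ----------------------------------------------------------------
# Gate layout in the 3H-wide matrices: [update z | reset r | candidate n].
# h_t = z_t * h_{t-1} + (1 - z_t) * tanh(W_n x_t + r_t * (U_n h_{t-1}) + b_n)

nn_gru_init <- function(d_in, h) {
  list(W = nn_glorot(d_in, 3L * h),
       U = cbind(nn_orthogonal(h), nn_orthogonal(h), nn_orthogonal(h)),
       b = rep(0, 3L * h))
}

# X: (B, T, D). Returns H_seq (B, T, H), h_T, and per-step caches.
nn_gru_forward <- function(X, p) {
  d <- dim(X); B <- d[1]; TT <- d[2]
  h_units <- ncol(p$U) / 3L
  zi <- 1:h_units; ri <- h_units + zi; ni <- 2L * h_units + zi
  h <- matrix(0, B, h_units)
  H_seq <- array(0, c(B, TT, h_units))
  steps <- vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- X[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B)
    xW <- sweep(xt %*% p$W, 2L, p$b, "+")
    hU <- h %*% p$U
    z <- nn_sigmoid(xW[, zi, drop = FALSE] + hU[, zi, drop = FALSE])
    r <- nn_sigmoid(xW[, ri, drop = FALSE] + hU[, ri, drop = FALSE])
    hUn <- hU[, ni, drop = FALSE]
    hh <- tanh(xW[, ni, drop = FALSE] + r * hUn)
    steps[[t]] <- list(x = xt, h_prev = h, z = z, r = r, hh = hh, hUn = hUn)
    h <- z * h + (1 - z) * hh
    H_seq[, t, ] <- h
  }
  list(H = H_seq, h_T = h, steps = steps, h_units = h_units)
}

# dH: (B, T, H) gradient on the full hidden sequence (zero slices allowed).
nn_gru_backward <- function(dH, cache, p) {
  steps <- cache$steps
  TT <- length(steps)
  h_units <- cache$h_units
  zi <- 1:h_units; ri <- h_units + zi; ni <- 2L * h_units + zi
  B <- nrow(steps[[1]]$x)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, h_units, 3L * h_units)
  db <- rep(0, 3L * h_units)
  dX <- array(0, c(B, TT, nrow(p$W)))
  dh <- matrix(0, B, h_units)
  for (t in TT:1) {
    st <- steps[[t]]
    dh <- dh + dH[, t, , drop = TRUE]
    if (is.null(dim(dh))) dh <- matrix(dh, B)
    dz <- dh * (st$h_prev - st$hh)
    dhh <- dh * (1 - st$z)
    dpre_n <- dhh * (1 - st$hh^2)
    dr <- dpre_n * st$hUn
    dpre_z <- dz * st$z * (1 - st$z)
    dpre_r <- dr * st$r * (1 - st$r)
    dgates <- cbind(dpre_z, dpre_r, dpre_n)
    dW <- dW + crossprod(st$x, dgates)
    db <- db + colSums(dgates)
    dhU <- cbind(dpre_z, dpre_r, dpre_n * st$r)
    dU <- dU + crossprod(st$h_prev, dhU)
    dX[, t, ] <- dgates %*% t(p$W)
    dh <- dh * st$z + dhU %*% t(p$U)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

nn_reverse_time <- function(X) {
  X[, dim(X)[2]:1, , drop = FALSE]
}

# --- loss / optimizer ---------------------------------------------------

nn_bce <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradient of mean BCE wrt the pre-sigmoid logit
nn_bce_dlogit <- function(prob, y) (prob - y) / length(y)

nn_adam_init <- function(params) {
  flat <- rapply(params, function(x) list(m = x * 0, v = x * 0), how = "list")
  list(state = flat, t = 0L)
}

nn_adam_step <- function(params, grads, opt, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  upd <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r[[1]]; out_s[[nm]] <- r[[2]]
      }
      return(list(out_p, out_s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p - lr * mhat / (sqrt(vhat) + eps), s)
  }
  r <- upd(params, grads, opt$state)
  list(params = r[[1]], opt = list(state = r[[2]], t = t))
}
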