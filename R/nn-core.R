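# Minimal reverse-mode neural-network primitives on BLAS matrix ops.
#
# Dense batched tensors: a batch of H x W x C feature maps is a B x (H*W*C)
# matrix whose columns are channel blocks of column-major pixels; an LSTM
# input sequence is a list of L matrices B x D. Convolution is im2col +
# GEMM with a precomputed sparse scatter matrix for the backward pass.

sigmoid <- function(x) 1 / (1 + exp(-x))

# fan-in uniform initialisation (the classic default of torch linear/conv)
init_mat <- function(nin, nout) {
  b <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -b, b), nin, nout)
}
init_vec <- function(nin, nout) {
  b <- 1 / sqrt(nin)
  stats::runif(nout, -b, b)
}

# --- convolution plumbing -------------------------------------------------
#
# Hot loops live in src/conv.cpp; this file keeps a plain-R im2col
# reference used as the independent oracle in the test suite.

conv_fwd <- function(x, K, b, insize, k, cin) {
  list(y = gf_conv_fwd(x, K, b, insize, k, cin),
       x = x, insize = insize, k = k, cin = cin)
}

conv_bwd <- function(cache, dy, K) {
  gf_conv_bwd(cache$x, K, dy, cache$insize, cache$k, cache$cin)
}

pool_fwd <- function(x, insize, cin) gf_pool_fwd(x, insize, cin)
pool_bwd <- function(dy, insize, cin) gf_pool_bwd(dy, insize, cin)

# im2col reference convolution (oracle for the compiled kernels)
conv_fwd_ref <- function(x, K, b, insize, k, cin) {
  o <- insize - k + 1L
  npix <- o * o
  B <- nrow(x)
  oi <- rep(seq_len(o), times = o); oj <- rep(seq_len(o), each = o)
  idx <- matrix(0L, npix, k * k * cin)
  q <- 0L
  for (c in seq_len(cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    q <- q + 1L
    idx[, q] <- (c - 1L) * insize * insize + (oj + kj - 2L) * insize + (oi + ki - 1L)
  }
  P <- x[, as.vector(idx)]
  dim(P) <- c(B * npix, k * k * cin)
  out <- sweep(P %*% K, 2, b, "+")
  matrix(out, B, npix * ncol(K))
}

# --- LSTM -----------------------------------------------------------------

# one direction over a list of L input matrices (B x D); returns hidden
# states per step plus the cache needed for BPTT
lstm_dir_fwd <- function(X, Wx, Wh, b) {
  L <- length(X); B <- nrow(X[[1]]); H <- nrow(Wh)
  Hh <- matrix(0, B, H); C <- matrix(0, B, H)
  hs <- vector("list", L); cache <- vector("list", L)
  for (t in seq_len(L)) {
    Z <- X[[t]] %*% Wx + Hh %*% Wh
    Z <- sweep(Z, 2, b, "+")
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    C_prev <- C
    C <- f * C_prev + i * g
    tC <- tanh(C)
    H_prev <- Hh
    Hh <- o * tC
    hs[[t]] <- Hh
    cache[[t]] <- list(i = i, f = f, g = g, o = o, C_prev = C_prev,
                       tC = tC, H_prev = H_prev, t = t)
  }
  list(hs = hs, cache = cache)
}

# BPTT for one direction. dH: list of L gradients (B x H, zeros allowed).
lstm_dir_bwd <- function(X, fwd, Wx, Wh, dH) {
  L <- length(X); B <- nrow(X[[1]]); H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- vector("list", L)
  dH_carry <- matrix(0, B, H); dC_next <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    cc <- fwd$cache[[t]]
    dHt <- dH[[t]] + dH_carry
    do <- dHt * cc$tC
    dC <- dC_next + dHt * cc$o * (1 - cc$tC^2)
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$C_prev
    dC_next <- dC * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(X[[t]], dZ)
    dWh <- dWh + crossprod(cc$H_prev, dZ)
    db <- db + colSums(dZ)
    dX[[t]] <- dZ %*% t(Wx)
    dH_carry <- dZ %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# bidirectional layer: returns per-step concatenated [fwd, bwd] hidden
bilstm_fwd <- function(X, p) {
  L <- length(X)
  fw <- lstm_dir_fwd(X, p$Wx_f, p$Wh_f, p$b_f)
  bw <- lstm_dir_fwd(rev(X), p$Wx_b, p$Wh_b, p$b_b)
  out <- vector("list", L)
  for (t in seq_len(L)) out[[t]] <- cbind(fw$hs[[t]], bw$hs[[L - t + 1L]])
  list(out = out, fw = fw, bw = bw)
}

bilstm_bwd <- function(X, cache, p, dOut) {
  L <- length(X); H <- nrow(p$Wh_f)
  dH_f <- lapply(dOut, function(m) m[, 1:H, drop = FALSE])
  dH_b_orig <- lapply(dOut, function(m) m[, (H + 1):(2 * H), drop = FALSE])
  g_f <- lstm_dir_bwd(X, cache$fw, p$Wx_f, p$Wh_f, dH_f)
  g_b <- lstm_dir_bwd(rev(X), cache$bw, p$Wx_b, p$Wh_b, rev(dH_b_orig))
  dX <- vector("list", L)
  for (t in seq_len(L)) dX[[t]] <- g_f$dX[[t]] + g_b$dX[[L - t + 1L]]
  list(grads = list(Wx_f = g_f$dWx, Wh_f = g_f$dWh, b_f = g_f$db,
                    Wx_b = g_b$dWx, Wh_b = g_b$dWh, b_b = g_b$db),
       dX = dX)
}

# --- optimiser ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# torch-style Adam with L2 weight decay folded into the gradient
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
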