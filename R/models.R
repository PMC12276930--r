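#' Estimator architecture specification
#'
#' Describes one of the three AP GRF estimator configurations:
#'
#' * `insole_only`: a LeNet-style CNN on the 28 x 28 pressure map (two
#'   convolutions with kernels 5 and 3, average pooling after each, then a
#'   fully connected layer with 84 neurons) alongside a bidirectional LSTM
#'   on the CoP time series; their 84-neuron outputs are merged.
#' * `imu_only`: the bidirectional LSTM branch on the 21 IMU channels
#'   (three layers of 128 hidden features, then FC layers 256-256-84).
#' * `fusion`: both branches; the two 84-neuron branch outputs are
#'   concatenated and merged.
#'
#' The merge layer has 168 neurons in fusion mode and 84 in the
#' single-modality modes, followed by a 10-neuron FC layer and a final
#' linear unit producing the signed AP GRF estimate in %BW. All layers
#' before the final unit use ReLU activations.
#'
#' Width parameters are configurable so that reduced (desk-scale) variants
#' of the same architecture can be trained quickly; defaults are the
#' full-size network.
#'
#' @param mode one of `"fusion"`, `"imu_only"`, `"insole_only"`.
#' @param conv_channels output channels of the two convolutions.
#' @param cnn_fc width of the CNN branch output layer.
#' @param lstm_hidden hidden features per LSTM direction.
#' @param lstm_layers number of stacked bidirectional LSTM layers.
#' @param lstm_fc widths of the LSTM branch FC stack (last entry is the
#'   branch output width).
#' @param penultimate width of the next-to-last FC layer.
#' @param sequence_len LSTM sequence length (frames).
#' @param map_size pressure-map side length.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(mode = c("fusion", "imu_only", "insole_only"),
                       conv_channels = c(6L, 16L), cnn_fc = 84L,
                       lstm_hidden = 128L, lstm_layers = 3L,
                       lstm_fc = c(256L, 256L, 84L),
                       penultimate = 10L, sequence_len = 5L,
                       map_size = 28L) {
  mode <- match.arg(mode)
  assert_that(length(conv_channels) == 2, "need two conv channel counts")
  assert_that(length(lstm_fc) >= 1, "lstm_fc needs at least one width")
  merge_width <- if (mode == "fusion") 2L * cnn_fc else cnn_fc
  structure(list(mode = mode, conv_channels = as.integer(conv_channels),
                 conv_kernels = c(5L, 3L), cnn_fc = as.integer(cnn_fc),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 lstm_fc = as.integer(lstm_fc),
                 merge_width = as.integer(merge_width),
                 penultimate = as.integer(penultimate),
                 sequence_len = as.integer(sequence_len),
                 map_size = as.integer(map_size)),
            class = "model_spec")
}

# sequence channel count per mode: IMU (21) and/or CoP (2)
seq_channels <- function(mode) {
  switch(mode, fusion = 23L, imu_only = 21L, insole_only = 2L)
}

uses_cnn <- function(mode) mode %in% c("fusion", "insole_only")
uses_lstm <- function(mode) TRUE

#' Build an untrained estimator
#'
#' Instantiates all weight tensors of a [model_spec()] with seeded fan-in
#' uniform initialisation, so two builds from the same spec and seed have
#' identical initial weights.
#'
#' @param spec a `model_spec`.
#' @param seed integer init seed.
#' @return list of class `gf_model` with `spec`, `params` and `geom`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  ms <- spec$map_size
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  k1 <- spec$conv_kernels[1]; k2 <- spec$conv_kernels[2]
  s1 <- ms - k1 + 1L          # after conv1
  p1 <- s1 %/% 2L             # after pool1
  s2 <- p1 - k2 + 1L          # after conv2
  p2 <- s2 %/% 2L             # after pool2
  assert_that(p2 >= 1, "map too small for the convolution stack")
  flat <- p2 * p2 * c2
  H <- spec$lstm_hidden
  D1 <- seq_channels(spec$mode)
  params <- list()
  geom <- list(s1 = s1, p1 = p1, s2 = s2, p2 = p2, flat = flat, D1 = D1)
  with_seed(sub_seed(seed, paste0("init_", spec$mode)), {
    if (uses_cnn(spec$mode)) {
      params$conv1_K <- init_mat(k1 * k1 * 1L, c1)
      params$conv1_b <- init_vec(k1 * k1 * 1L, c1)
      params$conv2_K <- init_mat(k2 * k2 * c1, c2)
      params$conv2_b <- init_vec(k2 * k2 * c1, c2)
      params$cnn_fc_W <- init_mat(flat, spec$cnn_fc)
      params$cnn_fc_b <- init_vec(flat, spec$cnn_fc)
    }
    for (l in seq_len(spec$lstm_layers)) {
      D <- if (l == 1L) D1 else 2L * H
      for (dir in c("f", "b")) {
        params[[sprintf("lstm%d_Wx_%s", l, dir)]] <- init_mat(D, 4L * H)
        params[[sprintf("lstm%d_Wh_%s", l, dir)]] <- init_mat(H, 4L * H)
        params[[sprintf("lstm%d_b_%s", l, dir)]] <- init_vec(H, 4L * H)
      }
    }
    din <- 2L * H
    for (j in seq_along(spec$lstm_fc)) {
      params[[sprintf("lfc%d_W", j)]] <- init_mat(din, spec$lstm_fc[j])
      params[[sprintf("lfc%d_b", j)]] <- init_vec(din, spec$lstm_fc[j])
      din <- spec$lstm_fc[j]
    }
    concat <- if (spec$mode == "fusion") spec$cnn_fc + spec$lstm_fc[length(spec$lstm_fc)]
    else if (spec$mode == "insole_only") spec$cnn_fc + spec$lstm_fc[length(spec$lstm_fc)]
    else spec$lstm_fc[length(spec$lstm_fc)]
    params$merge_W <- init_mat(concat, spec$merge_width)
    params$merge_b <- init_vec(concat, spec$merge_width)
    params$pen_W <- init_mat(spec$merge_width, spec$penultimate)
    params$pen_b <- init_vec(spec$merge_width, spec$penultimate)
    params$out_W <- init_mat(spec$penultimate, 1L)
    params$out_b <- init_vec(spec$penultimate, 1L)
  })
  structure(list(spec = spec, params = params, geom = geom), class = "gf_model")
}

#' Count trainable parameters
#'
#' @param model a `gf_model`.
#' @return integer total number of scalar weights.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.gf_model <- function(x, ...) {
  cat(sprintf("<gf_model> %s: %d parameters (LSTM %dx%d bi, seq %d)\n",
              x$spec$mode, count_parameters(x), x$spec$lstm_layers,
              x$spec$lstm_hidden, x$spec$sequence_len))
  invisible(x)
}

# validate batch shapes against the model_spec
check_batch <- function(model, batch) {
  sp <- model$spec
  if (uses_cnn(sp$mode)) {
    assert_that(!is.null(batch$map) && ncol(batch$map) == sp$map_size^2,
                "batch$map must be B x %d", sp$map_size^2)
    assert_that(all(is.finite(batch$map)), "non-finite values in pressure maps")
  }
  assert_that(length(batch$seq) == sp$sequence_len,
              "batch$seq must have %d timesteps", sp$sequence_len)
  assert_that(ncol(batch$seq[[1]]) == model$geom$D1,
              "sequence channels: expected %d, got %d",
              model$geom$D1, ncol(batch$seq[[1]]))
  for (m in batch$seq) assert_that(all(is.finite(m)), "non-finite values in sequence")
  invisible(TRUE)
}

#' Forward pass of an estimator
#'
#' @param model a `gf_model`.
#' @param batch list with `map` (B x map_size^2, CNN modes) and `seq`
#'   (list of `sequence_len` matrices B x channels, oldest first).
#' @param keep_cache retain intermediates for [model_backward()].
#' @return numeric vector of B AP GRF estimates (%BW); with
#'   `keep_cache = TRUE`, a list(yhat, cache).
#' @export
model_forward <- function(model, batch, keep_cache = FALSE) {
  check_batch(model, batch)
  sp <- model$spec; p <- model$params; g <- model$geom
  cache <- list()
  branch <- NULL
  if (uses_cnn(sp$mode)) {
    cv1 <- conv_fwd(batch$map, p$conv1_K, p$conv1_b, sp$map_size,
                    sp$conv_kernels[1], 1L)
    r1 <- pmax(cv1$y, 0)
    pl1 <- pool_fwd(r1, g$s1, sp$conv_channels[1])
    cv2 <- conv_fwd(pl1, p$conv2_K, p$conv2_b, g$p1, sp$conv_kernels[2],
                    sp$conv_channels[1])
    r2 <- pmax(cv2$y, 0)
    pl2 <- pool_fwd(r2, g$s2, sp$conv_channels[2])
    z_cnn <- pl2 %*% p$cnn_fc_W
    z_cnn <- sweep(z_cnn, 2, p$cnn_fc_b, "+")
    a_cnn <- pmax(z_cnn, 0)
    cache$cnn <- list(cv1 = cv1, r1 = r1, pl1 = pl1, cv2 = cv2, r2 = r2,
                      pl2 = pl2, z_cnn = z_cnn)
    branch <- a_cnn
  }
  X <- batch$seq
  lstm_caches <- vector("list", sp$lstm_layers)
  layer_in <- vector("list", sp$lstm_layers)
  for (l in seq_len(sp$lstm_layers)) {
    pl <- list(Wx_f = p[[sprintf("lstm%d_Wx_f", l)]],
               Wh_f = p[[sprintf("lstm%d_Wh_f", l)]],
               b_f = p[[sprintf("lstm%d_b_f", l)]],
               Wx_b = p[[sprintf("lstm%d_Wx_b", l)]],
               Wh_b = p[[sprintf("lstm%d_Wh_b", l)]],
               b_b = p[[sprintf("lstm%d_b_b", l)]])
    layer_in[[l]] <- X
    out <- bilstm_fwd(X, pl)
    lstm_caches[[l]] <- out
    X <- out$out
  }
  # sequence summary: forward direction's final state (time L) and the
  # backward direction's final state (time 1) — both see the full window
  H <- sp$lstm_hidden
  h_last <- cbind(X[[sp$sequence_len]][, 1:H, drop = FALSE],
                  X[[1L]][, (H + 1L):(2L * H), drop = FALSE])
  acts <- list(); zs <- list()
  a <- h_last
  for (j in seq_along(sp$lstm_fc)) {
    z <- a %*% p[[sprintf("lfc%d_W", j)]]
    z <- sweep(z, 2, p[[sprintf("lfc%d_b", j)]], "+")
    zs[[j]] <- z
    acts[[j]] <- a
    a <- pmax(z, 0)
  }
  a_lstm <- a
  cache$lstm <- list(caches = lstm_caches, layer_in = layer_in,
                     h_last = h_last, fc_z = zs, fc_in = acts)
  concat <- if (uses_cnn(sp$mode)) cbind(branch, a_lstm) else a_lstm
  zm <- sweep(concat %*% p$merge_W, 2, p$merge_b, "+")
  am <- pmax(zm, 0)
  zp <- sweep(am %*% p$pen_W, 2, p$pen_b, "+")
  ap <- pmax(zp, 0)
  y <- as.numeric(ap %*% p$out_W + p$out_b)
  if (!keep_cache) return(y)
  cache$head <- list(concat = concat, zm = zm, am = am, zp = zp, ap = ap)
  cache$batch <- batch
  list(yhat = y, cache = cache)
}

#' Backward pass (gradients of the mean loss w.r.t. all parameters)
#'
#' @param model a `gf_model`.
#' @param cache cache from `model_forward(..., keep_cache = TRUE)`.
#' @param dy gradient of the loss w.r.t. the output vector (length B).
#' @return named list of gradients matching `model$params`.
#' @export
model_backward <- function(model, cache, dy) {
  sp <- model$spec; p <- model$params; g <- model$geom
  gr <- list()
  hd <- cache$head
  dY <- matrix(dy, ncol = 1L)
  gr$out_W <- crossprod(hd$ap, dY)
  gr$out_b <- sum(dY)
  dap <- dY %*% t(p$out_W)
  dzp <- dap * (hd$zp > 0)
  gr$pen_W <- crossprod(hd$am, dzp)
  gr$pen_b <- colSums(dzp)
  dam <- dzp %*% t(p$pen_W)
  dzm <- dam * (hd$zm > 0)
  gr$merge_W <- crossprod(hd$concat, dzm)
  gr$merge_b <- colSums(dzm)
  dconcat <- dzm %*% t(p$merge_W)
  if (uses_cnn(sp$mode)) {
    d_cnn <- dconcat[, 1:sp$cnn_fc, drop = FALSE]
    d_lstm <- dconcat[, (sp$cnn_fc + 1L):ncol(dconcat), drop = FALSE]
  } else {
    d_cnn <- NULL
    d_lstm <- dconcat
  }
  # LSTM branch FC stack
  lc <- cache$lstm
  da <- d_lstm
  for (j in rev(seq_along(sp$lstm_fc))) {
    dz <- da * (lc$fc_z[[j]] > 0)
    gr[[sprintf("lfc%d_W", j)]] <- crossprod(lc$fc_in[[j]], dz)
    gr[[sprintf("lfc%d_b", j)]] <- colSums(dz)
    da <- dz %*% t(p[[sprintf("lfc%d_W", j)]])
  }
  # BPTT through the stacked bidirectional LSTM
  B <- nrow(da); H <- sp$lstm_hidden; H2 <- 2L * H
  dOut <- rep(list(matrix(0, B, H2)), sp$sequence_len)
  dOut[[sp$sequence_len]][, 1:H] <- da[, 1:H, drop = FALSE]
  dOut[[1L]][, (H + 1L):H2] <- dOut[[1L]][, (H + 1L):H2] +
    da[, (H + 1L):H2, drop = FALSE]
  for (l in rev(seq_len(sp$lstm_layers))) {
    pl <- list(Wx_f = p[[sprintf("lstm%d_Wx_f", l)]],
               Wh_f = p[[sprintf("lstm%d_Wh_f", l)]],
               b_f = p[[sprintf("lstm%d_b_f", l)]],
               Wx_b = p[[sprintf("lstm%d_Wx_b", l)]],
               Wh_b = p[[sprintf("lstm%d_Wh_b", l)]],
               b_b = p[[sprintf("lstm%d_b_b", l)]])
    bb <- bilstm_bwd(lc$layer_in[[l]], lc$caches[[l]], pl, dOut)
    for (nm in names(bb$grads)) {
      gr[[sprintf("lstm%d_%s", l, nm)]] <- bb$grads[[nm]]
    }
    dOut <- bb$dX
  }
  # CNN branch
  if (uses_cnn(sp$mode)) {
    cn <- cache$cnn
    dz_cnn <- d_cnn * (cn$z_cnn > 0)
    gr$cnn_fc_W <- crossprod(cn$pl2, dz_cnn)
    gr$cnn_fc_b <- colSums(dz_cnn)
    dpl2 <- dz_cnn %*% t(p$cnn_fc_W)
    dr2 <- pool_bwd(dpl2, g$s2, sp$conv_channels[2])
    dcv2 <- dr2 * (cn$cv2$y > 0)
    b2 <- conv_bwd(cn$cv2, dcv2, p$conv2_K)
    gr$conv2_K <- b2$dK; gr$conv2_b <- b2$db
    dpl1 <- b2$dx
    dr1 <- pool_bwd(dpl1, g$s1, sp$conv_channels[1])
    dcv1 <- dr1 * (cn$cv1$y > 0)
    b1 <- conv_bwd(cn$cv1, dcv1, p$conv1_K)
    gr$conv1_K <- b1$dK; gr$conv1_b <- b1$db
  }
  gr
}
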