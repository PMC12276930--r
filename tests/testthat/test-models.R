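# Network architecture, forward/backward correctness, parameter counts.

tiny_spec <- function(mode) {
  model_spec(mode, conv_channels = c(2L, 3L), cnn_fc = 8L, lstm_hidden = 4L,
             lstm_layers = 2L, lstm_fc = c(6L, 8L), penultimate = 5L)
}

rand_batch <- function(mode, B = 4L, seed = 1) {
  set.seed(seed)
  ch <- switch(mode, fusion = 23L, imu_only = 21L, insole_only = 2L)
  b <- list(seq = lapply(1:5, function(i) matrix(rnorm(B * ch), B)))
  if (mode != "imu_only") b$map <- matrix(runif(B * 784), B)
  b
}

test_that("compiled convolution and pooling match the im2col reference", {
  set.seed(3)
  x <- matrix(runif(32 * 784), 32)
  K <- matrix(rnorm(25 * 6), 25); b <- rnorm(6)
  expect_equal(gaitfuse:::gf_conv_fwd(x, K, b, 28L, 5L, 1L),
               gaitfuse:::conv_fwd_ref(x, K, b, 28L, 5L, 1L),
               tolerance = 1e-12)
  x2 <- matrix(runif(8 * 144 * 6), 8)
  K2 <- matrix(rnorm(54 * 4), 54); b2 <- rnorm(4)
  expect_equal(gaitfuse:::gf_conv_fwd(x2, K2, b2, 12L, 3L, 6L),
               gaitfuse:::conv_fwd_ref(x2, K2, b2, 12L, 3L, 6L),
               tolerance = 1e-12)
  # pooling: constant-preserving average over 2x2 blocks
  xc <- matrix(3, 5, 16 * 2)
  expect_equal(as.vector(gaitfuse:::gf_pool_fwd(xc, 4L, 2L)),
               rep(3, 5 * 4 * 2))
})

test_that("analytic gradients match numeric gradients in all three modes", {
  for (mode in c("fusion", "imu_only", "insole_only")) {
    m <- build_model(tiny_spec(mode), seed = 9)
    batch <- rand_batch(mode, B = 3L, seed = 4)
    y <- c(0.3, -1.1, 0.5)
    fw <- model_forward(m, batch, keep_cache = TRUE)
    gr <- model_backward(m, fw$cache, 2 * (fw$yhat - y) / 3)
    lossfun <- function(mm) mean((model_forward(mm, batch) - y)^2)
    set.seed(10)
    for (nm in sample(names(m$params), 8)) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   label = paste(mode, nm))
    }
  }
})

test_that("gradient reaches every parameter (no dead branch)", {
  for (mode in c("fusion", "imu_only", "insole_only")) {
    m <- build_model(tiny_spec(mode), seed = 2)
    batch <- rand_batch(mode, B = 8L, seed = 6)
    fw <- model_forward(m, batch, keep_cache = TRUE)
    gr <- model_backward(m, fw$cache, rep(1, 8) / 8)
    for (nm in names(m$params)) {
      expect_gt(max(abs(gr[[nm]])), 0, label = paste(mode, nm))
    }
  }
})

test_that("head layer widths follow the architecture contract", {
  full <- build_model(model_spec("fusion"), seed = 1)
  # fusion: [84 + 84] -> 168 -> 10 -> 1
  expect_equal(dim(full$params$merge_W), c(168L, 168L))
  expect_equal(dim(full$params$pen_W), c(168L, 10L))
  expect_equal(dim(full$params$out_W), c(10L, 1L))
  imu <- build_model(model_spec("imu_only"), seed = 1)
  # single mode: 84-neuron layer replaces the 168-neuron merge
  expect_equal(dim(imu$params$merge_W), c(84L, 84L))
  expect_equal(dim(imu$params$pen_W), c(84L, 10L))
  ins <- build_model(model_spec("insole_only"), seed = 1)
  expect_equal(dim(ins$params$merge_W), c(168L, 84L))
  # LSTM input channels: IMU 21 + CoP 2 in fusion, 21 alone, CoP alone
  expect_equal(nrow(full$params$lstm1_Wx_f), 23L)
  expect_equal(nrow(imu$params$lstm1_Wx_f), 21L)
  expect_equal(nrow(ins$params$lstm1_Wx_f), 2L)
})

test_that("parameter counts match the shape-arithmetic oracle", {
  count_oracle <- function(spec) {
    g <- list(s1 = 24L, p1 = 12L, s2 = 10L, p2 = 5L)
    n <- 0L
    c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
    if (spec$mode != "imu_only") {
      n <- n + (25 * 1 + 1) * c1 + (9 * c1 + 1) * c2 +
        (g$p2^2 * c2 + 1) * spec$cnn_fc
    }
    H <- spec$lstm_hidden
    D <- switch(spec$mode, fusion = 23L, imu_only = 21L, insole_only = 2L)
    for (l in seq_len(spec$lstm_layers)) {
      din <- if (l == 1) D else 2 * H
      n <- n + 2 * ((din + H + 1) * 4 * H)
    }
    din <- 2 * H
    for (w in spec$lstm_fc) { n <- n + (din + 1) * w; din <- w }
    concat <- if (spec$mode == "imu_only") spec$lstm_fc[length(spec$lstm_fc)]
    else spec$cnn_fc + spec$lstm_fc[length(spec$lstm_fc)]
    n + (concat + 1) * spec$merge_width +
      (spec$merge_width + 1) * spec$penultimate + (spec$penultimate + 1) * 1
  }
  for (mode in c("fusion", "imu_only", "insole_only")) {
    sp <- model_spec(mode)
    expect_equal(count_parameters(build_model(sp, 1)), count_oracle(sp),
                 label = mode)
  }
  # fusion has strictly more parameters than IMU-only; width grows counts
  expect_gt(count_parameters(build_model(model_spec("fusion"), 1)),
            count_parameters(build_model(model_spec("imu_only"), 1)))
  expect_gt(count_parameters(build_model(model_spec("fusion",
                                                    lstm_hidden = 256L), 1)),
            count_parameters(build_model(model_spec("fusion"), 1)))
})

test_that("seeded initialisation is reproducible and forward is well-behaved", {
  m1 <- build_model(tiny_spec("fusion"), seed = 33)
  m2 <- build_model(tiny_spec("fusion"), seed = 33)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_spec("fusion"), seed = 34)
  expect_false(identical(m1$params, m3$params))
  batch <- rand_batch("fusion", B = 6L)
  y <- model_forward(m1, batch)
  expect_length(y, 6L)
  expect_true(all(is.finite(y)))
  # zeroed final layer: every output equals the output bias
  m0 <- m1
  m0$params$out_W[] <- 0
  m0$params$out_b[] <- 4.2
  expect_equal(model_forward(m0, batch), rep(4.2, 6))
  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 6, 2, 5, 4)
  bp <- list(map = batch$map[perm, ],
             seq = lapply(batch$seq, function(s) s[perm, ]))
  expect_equal(model_forward(m1, bp), y[perm], tolerance = 1e-12)
  # non-finite inputs are rejected
  bad <- batch; bad$map[1, 1] <- NaN
  expect_error(model_forward(m1, bad), "finite")
  # channel mismatch is rejected
  wrong <- list(map = batch$map,
                seq = lapply(1:5, function(i) matrix(0, 6, 5)))
  expect_error(model_forward(m1, wrong), "channels")
})

test_that("the network can overfit a small stance sample (capacity check)", {
  set.seed(21)
  sp <- model_spec("fusion", conv_channels = c(3L, 6L), cnn_fc = 24L,
                   lstm_hidden = 12L, lstm_layers = 1L, lstm_fc = c(24L),
                   penultimate = 8L)
  m <- build_model(sp, seed = 5)
  B <- 48L
  batch <- rand_batch("fusion", B = B, seed = 7)
  y <- rnorm(B)
  state <- gaitfuse:::adam_init(m$params)
  loss <- NA
  for (step in 1:800) {
    fw <- model_forward(m, batch, keep_cache = TRUE)
    err <- fw$yhat - y
    loss <- mean(err^2)
    if (loss < 1e-3) break
    gr <- model_backward(m, fw$cache, 2 * err / B)
    upd <- gaitfuse:::adam_step(m$params, gr, state, 3e-3)
    m$params <- upd$params; state <- upd$state
  }
  expect_lt(loss, 1e-3)
})
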