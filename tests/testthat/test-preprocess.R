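# Preprocessing: filtering, smoothing, resizing, events, alignment.

test_that("zero-phase Butterworth has unit DC gain, half-power at cutoff, no lag", {
  expect_identical(lowpass_zero_phase(rep(3.3, 200), 100), rep(3.3, 200))
  fs <- 2000
  t <- seq(0, 10, 1 / fs)
  y <- lowpass_zero_phase(sin(2 * pi * 10 * t), fs, 10, 2)
  core <- 2000:18000
  # forward-backward filtering applies |H|^2; 2nd-order Butterworth has
  # |H(fc)|^2 = 1/2
  expect_equal(max(abs(y[core])), 0.5, tolerance = 1e-3)
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_zero_phase(x1, fs, 10, 2)
  cc <- stats::ccf(y1, x1, lag.max = 40, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass_zero_phase(1:5, 100), "short")
})

test_that("filtering is near-idempotent for signals well below the cutoff", {
  t <- seq(0, 20, 1 / 100)
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 3 * t)
  a <- lowpass_zero_phase(x, 100)
  b <- lowpass_zero_phase(a, 100)
  expect_lt(sqrt(mean((b - a)^2)) / sqrt(mean(a^2)), 0.01)
})

test_that("insole zeroing removes constant offsets exactly", {
  subj <- clin_subject(quiet_noise())
  kin <- fx_quiet_kin()
  ins <- simulate_insole(kin, subj, "left", seed = 4)
  shifted <- ins
  shifted$pressure <- ins$pressure + 2.5
  z <- zero_insole(shifted)
  expect_equal(z$pressure, ins$pressure, tolerance = 1e-10)
  # zero input stays zero
  zz <- ins; zz$pressure <- ins$pressure * 0
  expect_equal(max(abs(zero_insole(zz)$pressure)), 0)
  # random per-sensel offsets + noise: swing-window means shrink below the
  # noise std
  noisy <- clin_subject()
  insn <- simulate_insole(kin, noisy, "left", seed = 4)
  zn <- zero_insole(insn)
  w <- zn$zero_window
  sel <- insn$t >= w[1] & insn$t <= w[2]
  expect_lt(max(abs(colMeans(zn$pressure[sel, , drop = FALSE]))), 1e-9)
  sw_mean <- colMeans(zn$pressure[rowSums(insn$pressure) <
                                    stats::quantile(rowSums(insn$pressure), 0.1), ])
  expect_lt(stats::median(abs(sw_mean)), noisy$noise_levels$insole)
})

test_that("masked spatial Gaussian preserves uniform frames and impulse mass", {
  u <- spatial_gaussian(rep(1, 233), 0.5)
  expect_equal(u, rep(1, 233), tolerance = 1e-12)
  # interior impulse keeps its mass
  lay <- sensel_layout()
  interior <- which(vapply(seq_len(233), function(i) {
    sum(abs(lay$rows - lay$rows[i]) <= 2 & abs(lay$cols - lay$cols[i]) <= 2) == 25
  }, logical(1)))
  imp <- rep(0, 233); imp[interior[5]] <- 7
  expect_equal(sum(spatial_gaussian(imp, 0.5)), 7, tolerance = 1e-6)
  # sigma -> 0 is the identity
  x <- runif(233)
  expect_equal(spatial_gaussian(x, 0), x)
})

test_that("area resize matches the brute-force overlap oracle", {
  lay <- sensel_layout()
  brute <- function(F, n = 28) {
    H <- nrow(F); W <- ncol(F); out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      rlo <- (i - 1) * H / n; rhi <- i * H / n
      clo <- (j - 1) * W / n; chi <- j * W / n
      s <- 0
      for (r in ceiling(rlo + 1e-12):min(ceiling(rhi), H)) {
        for (cc in ceiling(clo + 1e-12):min(ceiling(chi), W)) {
          ov <- max(0, min(rhi, r) - max(rlo, r - 1)) *
            max(0, min(chi, cc) - max(clo, cc - 1))
          s <- s + ov * F[r, cc]
        }
      }
      out[i, j] <- s / ((H / n) * (W / n))
    }
    out
  }
  set.seed(77)
  frames <- matrix(runif(20 * 233), 20)
  maps <- resize_pressure_map(frames)
  emb <- embed_frames(frames)
  for (i in sample(20, 20)) {
    expect_lt(max(abs(matrix(maps[i, ], 28, 28) -
                        brute(matrix(emb[i, ], 31, 11)))), 1e-6)
  }
  # a constant embedded grid stays constant; means preserved; zero -> zero
  const_out <- rep(2.5, 341) %*% gaitfuse:::resize_operator()
  expect_equal(range(const_out), c(2.5, 2.5), tolerance = 1e-12)
  expect_equal(rowMeans(maps), rowMeans(emb), tolerance = 1e-12)
  expect_equal(max(abs(resize_pressure_map(rep(0, 233)))), 0)
})

test_that("heel-strike detection matches ground truth within 10 ms", {
  kin <- fx_quiet_kin()
  vf <- lowpass_zero_phase(kin$plate$v, kin$plate$fs)
  ev <- detect_heel_strikes(vf, kin$plate$fs)
  expect_equal(length(ev$hs), nrow(kin$events))
  hs_t <- kin$plate$t[ev$hs]; to_t <- kin$plate$t[ev$to]
  expect_lt(max(abs(hs_t - kin$events$hs)), 0.010)
  expect_lt(max(abs(to_t - kin$events$to)), 0.015)
  # force-plate vs insole detectors agree per stride
  ins <- simulate_insole(kin, clin_subject(quiet_noise()), "left", seed = 1,
                         clock_offset = 0)
  evi <- detect_heel_strikes(rowSums(ins$pressure), ins$fs)
  n <- min(length(evi$hs), length(ev$hs))
  offs <- abs(ins$t[evi$hs[1:n]] - hs_t[1:n])
  expect_lt(stats::median(offs), 0.020)
  # degenerate input: no events, with a warning
  expect_warning(ev0 <- detect_heel_strikes(rep(0, 1000), 100), "no gait")
  expect_length(ev0$hs, 0)
})

test_that("grouped min-max normalization follows the training-range contract", {
  set.seed(5)
  x <- cbind(matrix(rnorm(50 * 21), 50), matrix(runif(50 * 2, -3, 9), 50))
  cons <- fit_minmax(x, feature_groups())
  xn <- apply_minmax(x, cons)
  for (g in names(feature_groups())) {
    cols <- feature_groups()[[g]]
    expect_equal(min(xn[, cols]), 0, tolerance = 1e-12)
    expect_equal(max(xn[, cols]), 1, tolerance = 1e-12)
  }
  # test data beyond the training range exceeds [0, 1] (no clipping)
  x2 <- x; x2[1, 1] <- max(x[, 1:3]) + 5
  expect_gt(max(apply_minmax(x2, cons)[, 1]), 1)
  # degenerate constant group maps to 0 with a warning
  xc <- x; xc[, 22:23] <- 4
  expect_warning(cc <- fit_minmax(xc, feature_groups()), "degenerate")
  expect_equal(unique(as.vector(apply_minmax(xc, cc)[, 22:23])), 0)
})

test_that("sequence construction pads at stance starts and emits one sample per frame", {
  seg <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 5L)
  idx <- make_sequences(seg, L = 5L)
  expect_equal(nrow(idx), length(seg))
  expect_equal(idx[1, ], rep(1L, 5))            # stance start: repeat frame
  expect_equal(idx[3, ], c(1L, 1L, 1L, 2L, 3L)) # partial left-padding
  expect_equal(idx[4, ], rep(4L, 5))            # new segment resets
  expect_equal(idx[7, ], c(4L, 4L, 5L, 6L, 7L))
  expect_equal(idx[8, ], rep(8L, 5))
  # L = 1 is just the frame itself
  expect_equal(as.vector(make_sequences(seg, 1L)), seq_along(seg))
})

test_that("alignment recovers injected clock offsets within one frame", {
  subj <- clin_subject()
  ses <- simulate_session(subj, seed = 17, duration_scale = 0.25,
                          clock_offsets = list(insole = 0.04, imu = 0.02))
  al <- align_streams(ses$bouts[[1]], "left", preproc_config())
  expect_lt(abs(al$offsets_est["insole"] - 0.04), 0.010)
  expect_lt(abs(al$offsets_est["imu"] - 0.02), 0.010)
  # post-alignment: total map pressure and the detected stance pattern
  # are lag-free on the common 100 Hz clock
  al_all <- align_streams(ses$bouts[[1]], "left",
                          preproc_config(stance_only = FALSE))
  tot <- rowSums(al_all$maps)
  stance <- as.numeric(al_all$frames$stance)
  expect_equal(round(gaitfuse:::xcorr_lag(tot, stance, 8)), 0)
})

test_that("aligned targets stay faithful to the simulated AP GRF", {
  ds <- fx_dataset("left")
  tr <- session_truth(fx_session())
  tr <- tr[tr$side == "left" & tr$bout_id == 1, ]
  b1 <- which(ds$meta$bout_id == 1)
  # per-stride peak of the aligned target matches the simulator truth
  peaks <- vapply(split(ds$meta$target[b1], ds$meta$stride_id[b1]), max,
                  numeric(1))
  m <- min(length(peaks), nrow(tr))
  expect_lt(stats::median(abs(peaks[1:m] - tr$peak[1:m])), 0.25)
})

test_that("strides overlapping stream gaps are dropped", {
  ses <- simulate_session(clin_subject(), seed = 23, duration_scale = 0.25)
  bout <- ses$bouts[[1]]
  al0 <- align_streams(bout, "left", preproc_config())
  ev <- bout$sides$left$events
  # remove one stride's worth of insole samples mid-bout
  gap <- c(ev$hs[10], ev$hs[10] + 1.5 * (ev$hs[11] - ev$hs[10]))
  keep <- bout$sides$left$insole$t < gap[1] | bout$sides$left$insole$t > gap[2]
  bout$sides$left$insole$t <- bout$sides$left$insole$t[keep]
  bout$sides$left$insole$pressure <- bout$sides$left$insole$pressure[keep, ]
  bout$sides$left$insole$cop <- bout$sides$left$insole$cop[keep, ]
  expect_message(al1 <- align_streams(bout, "left", preproc_config()),
                 "dropped")
  n0 <- length(unique(al0$frames$stride_id))
  n1 <- length(unique(al1$frames$stride_id))
  expect_lt(n1, n0)
  expect_gte(n1, n0 - 3)
})

test_that("swing baseline subtraction removes residual offsets", {
  frames <- matrix(0, 100, 233)
  ev <- list(hs = c(10L, 60L), to = c(40L, 90L))
  frames <- frames + rep(runif(233, 1, 2), each = 100)  # constant residual
  out <- swing_baseline_subtract(frames, ev)
  expect_lt(max(abs(out)), 1e-12)
})
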