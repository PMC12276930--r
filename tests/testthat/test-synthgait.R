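# Simulator: speed profiles, stride kinetics, insole and IMU streams.

test_that("speed profiles follow the cohort protocol", {
  pr <- make_speed_profile("clinical", cws = 1.0, center = 70, a1_sign = 1)
  expect_equal(c(pr$v1, pr$v2, pr$v3), c(0.5, 0.7, 0.9))
  expect_equal(c(pr$t1, pr$t4, pr$hold), c(120, 240, 15))
  ph <- make_speed_profile("healthy", cws = 1.2, center = 0.6, a1_sign = -1)
  expect_equal(c(ph$v1, ph$v2, ph$v3), c(0.4, 0.6, 0.8))
  expect_equal(c(ph$t1, ph$t4, ph$hold), c(180, 600, 60))
  # ramp slope: v2 - v1 in 30 s
  p2 <- make_speed_profile("clinical", cws = 0.5, center = 100, a1_sign = 1)
  kn <- p2$knots
  ramp1 <- which(diff(kn$v) != 0)[1]
  slope <- abs(diff(kn$v)[ramp1] / diff(kn$t)[ramp1])
  expect_equal(slope, (0.5 - 0.4) / 30, tolerance = 1e-12)
  # constant until t1, continuous everywhere
  expect_true(all(speed_at(p2, seq(0, p2$t1 - 0.1, 0.5)) == p2$v2))
  tt <- seq(0, p2$t4, 0.05)
  expect_lt(max(abs(diff(speed_at(p2, tt)))), 2 * (0.1 / 30) * 0.05 + 1e-9)
})

test_that("off-grid bout centers are rejected", {
  expect_error(make_speed_profile("clinical", 1, 75), "center")
  expect_error(make_speed_profile("healthy", 1, 0.7), "center")
})

test_that("stance kinetics carry exact closed-form ground truth", {
  kin <- fx_quiet_kin()
  ev <- kin$events; pl <- kin$plate
  expect_gt(nrow(ev), 30)
  # swing is exactly zero
  sw <- rep(TRUE, length(pl$t))
  for (i in seq_len(nrow(ev))) sw[pl$t >= ev$hs[i] & pl$t <= ev$to[i]] <- FALSE
  expect_equal(max(abs(pl$ap[sw])), 0)
  expect_equal(max(abs(pl$v[sw])), 0)
  expect_true(all(pl$v >= 0))
  # per-stride impulse equals the trapezoidal integral of the positive
  # region at 2000 Hz (closed-form half-sine: 2*A*d/pi)
  rel <- vapply(seq_len(nrow(ev)), function(i) {
    w <- pl$t >= ev$hs[i] & pl$t <= ev$to[i]
    est <- pracma::trapz(pl$t[w], pmax(pl$ap[w], 0))
    abs(est - ev$impulse[i]) / ev$impulse[i]
  }, numeric(1))
  expect_lt(max(rel), 1e-3)
  # events strictly increasing, toe-off inside the stride
  expect_true(all(diff(ev$hs) > 0))
  expect_true(all(ev$to > ev$hs))
  expect_true(all(ev$to[-nrow(ev)] < ev$hs[-1]))
})

test_that("stride periods are stable at constant speed", {
  subj <- clin_subject()
  pr <- make_speed_profile("clinical", 0.8, 100, 1)  # 120 s constant period
  kin <- simulate_kinetics(pr, subj, "right", seed = 5)
  ev <- kin$events
  const <- ev$hs < pr$t1 - 2
  periods <- diff(ev$hs[const])
  expect_gt(length(periods), 50)
  cv <- stats::sd(periods) / mean(periods)
  expect_lt(cv, 2.5 * default_noise_levels()$stride_cv)
})

test_that("paretic impairment scales propulsion; zero impairment is symmetric", {
  imp <- subject_spec("i", 85, 0.8, "clinical", "left", 0.4, quiet_noise())
  pr <- make_speed_profile("clinical", 0.8, 100, 1, duration_scale = 0.5)
  kL <- simulate_kinetics(pr, imp, "left", seed = 3)
  kR <- simulate_kinetics(pr, imp, "right", seed = 3)
  expect_lt(mean(kL$events$peak), 0.75 * mean(kR$events$peak))
  sym <- subject_spec("s", 85, 0.8, "clinical", "left", 0, quiet_noise())
  mL <- mean(simulate_kinetics(pr, sym, "left", seed = 7)$events$impulse)
  mR <- mean(simulate_kinetics(pr, sym, "right", seed = 7)$events$impulse)
  # Monte-Carlo CI on the stride-impulse mean difference
  s2 <- stats::var(simulate_kinetics(pr, sym, "left", seed = 7)$events$impulse)
  n <- nrow(simulate_kinetics(pr, sym, "left", seed = 7)$events)
  expect_lt(abs(mL - mR), 4 * sqrt(2 * s2 / n))
})

test_that("propulsion loads on separate kinematic and loading latents", {
  kin <- simulate_kinetics(make_speed_profile("clinical", 0.8, 100, 1),
                           clin_subject(), "left", seed = 5)
  s <- kin$strides
  base <- gaitfuse:::gf_gait_constants()$P0(s$v)
  single <- sum(resid(stats::lm(s$P ~ base + base:s$g_k))^2)
  both <- sum(resid(stats::lm(s$P ~ base + base:s$g_k + base:s$g_l))^2)
  expect_gt(single / max(both, 1e-12), 2)
})

test_that("insole frames track vertical load and carry a travelling CoP", {
  subj <- clin_subject(quiet_noise())
  kin <- fx_quiet_kin()
  ins <- simulate_insole(kin, subj, "left", seed = 2, clock_offset = 0)
  expect_equal(ncol(ins$pressure), 233L)
  v50 <- stats::approx(kin$plate$t, kin$plate$v, ins$t, rule = 2)$y
  expect_gt(stats::cor(rowSums(ins$pressure), v50), 0.99)
  # CoP equals the centroid and moves heel -> toe (row decreases) in stance
  lay <- sensel_layout()
  mid <- which(v50 > 0.5 * max(v50))[1]
  expect_equal(ins$cop[mid, ], cop_from_frames(ins$pressure[mid, ])[1, ],
               ignore_attr = TRUE, tolerance = 1e-10)
  st <- kin$events[5, ]
  rows_in_stance <- ins$cop[ins$t >= st$hs & ins$t <= st$to, 1]
  expect_lt(tail(rows_in_stance, 1), head(rows_in_stance, 1) - 10)
  # CoP inside the layout bounding box whenever pressure is positive
  pos <- rowSums(ins$pressure) > 0
  expect_true(all(ins$cop[pos, 1] >= 0 & ins$cop[pos, 1] <= 30))
  expect_true(all(ins$cop[pos, 2] >= 0 & ins$cop[pos, 2] <= 10))
  # single active sensel: centroid is that sensel's coordinates
  one <- rep(0, 233); one[50] <- 3.3
  expect_equal(cop_from_frames(one)[1, ],
               c(row = lay$rows[50], col = lay$cols[50]))
})

test_that("IMU channels obey their construction identities", {
  subj <- clin_subject(quiet_noise())
  kin <- fx_quiet_kin()
  imu <- simulate_imu(kin, subj, "left", seed = 2, clock_offset = 0)
  expect_identical(colnames(imu$channels), imu_channels())
  expect_equal(ncol(imu$channels), 21L)
  # pitch rate channel equals the finite difference of the pitch angle
  fd <- function(x, dt) {
    n <- length(x); d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt; d[n] <- (x[n] - x[n - 1]) / dt
    d
  }
  for (seg in c("foot", "shank", "thigh")) {
    p <- imu$channels[, paste0(seg, "_pitch")]
    r <- imu$channels[, paste0(seg, "_gyr_y")]
    expect_lt(max(abs(fd(p, 0.01) - r)), 1e-6 * diff(range(p)))
  }
  # angles bounded in (-180, 180]
  ang <- imu$channels[, grep("_(pitch|roll)$", colnames(imu$channels))]
  expect_true(all(ang > -180 & ang <= 180))
  # static (no strides): accelerometer norm equals gravity
  kin0 <- kin; kin0$strides <- kin0$strides[0, ]
  imu0 <- simulate_imu(kin0, subj, "left", seed = 2)
  nrm <- sqrt(rowSums(imu0$channels[, c("foot_acc_x", "foot_acc_y",
                                        "foot_acc_z")]^2))
  expect_equal(max(abs(nrm - 9.80665)), 0, tolerance = 1e-9)
})

test_that("sessions are deterministic and follow the bout protocol", {
  subj <- clin_subject()
  s1 <- simulate_session(subj, seed = 12, duration_scale = 0.25)
  s2 <- simulate_session(subj, seed = 12, duration_scale = 0.25)
  expect_identical(s1, s2)
  s3 <- simulate_session(subj, seed = 13, duration_scale = 0.25)
  expect_false(identical(s1$bouts[[1]]$sides$left$plate$ap,
                         s3$bouts[[1]]$sides$left$plate$ap))
  # full-protocol durations (structural check at scale 1)
  clin <- simulate_session(clin_subject(), n_bouts = 4L, seed = 1,
                           duration_scale = 1)
  expect_equal(length(clin$bouts), 4L)
  for (b in clin$bouts) expect_equal(b$profile$t4, 240)
  healthy <- subject_spec("h", 70, 1.1, "healthy")
  hses <- simulate_session(healthy, n_bouts = 6L, seed = 1, duration_scale = 1)
  expect_equal(length(hses$bouts), 6L)
  for (b in hses$bouts) expect_equal(b$profile$t4, 600)
})

test_that("propulsion perturbation shifts truth coherently and clamps", {
  subj <- clin_subject(quiet_noise())
  ses <- simulate_session(subj, seed = 9, duration_scale = 0.25)
  expect_identical(perturb_propulsion(ses, c(10, 50), 0)$bouts, ses$bouts)
  win <- c(5, 55)
  pert <- perturb_propulsion(ses, win, 1.0)
  tr0 <- session_truth(ses); tr1 <- session_truth(pert)
  inside <- tr0$hs >= win[1] & tr0$hs <= win[2] & tr0$side == "left"
  outside <- !inside & tr0$side == "left"
  d_in <- mean(tr1$peak[inside] - tr0$peak[inside])
  d_out <- mean(abs(tr1$peak[outside] - tr0$peak[outside]))
  expect_equal(d_in, 1.0, tolerance = 0.05)
  expect_equal(d_out, 0)
  # strongly negative delta: peaks clamp at the positive floor
  neg <- perturb_propulsion(ses, win, -50)
  expect_true(all(session_truth(neg)$peak > 0))
  # the kinematic latent carries the shift into the IMU stream
  b1 <- which(vapply(ses$bouts, function(b) b$t_offset <= win[1] &&
                       b$t_offset + b$profile$t4 > win[1], logical(1)))[1]
  ch0 <- ses$bouts[[b1]]$sides$left$imu$channels[, "shank_pitch"]
  ch1 <- pert$bouts[[b1]]$sides$left$imu$channels[, "shank_pitch"]
  expect_false(identical(ch0, ch1))
  expect_error(perturb_propulsion(ses, c(-5, 10), 1), "window")
})
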