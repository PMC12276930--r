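# Insole and IMU stream synthesis.

# unit-sum masked Gaussian blob on the sensel layout
sensel_blob <- function(center_row, center_col, sd_row, sd_col,
                        layout = sensel_layout()) {
  w <- exp(-((layout$rows - center_row)^2 / (2 * sd_row^2) +
               (layout$cols - center_col)^2 / (2 * sd_col^2)))
  w / sum(w)
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate a 50 Hz pressure-insole stream
#'
#' Total pressure is proportional to the analytic vertical GRF of the stride
#' model, scaled per stride by the loading latent `1 + g_l`; the spatial
#' distribution is a mixture of a heel blob and a forefoot blob whose weights
#' shift smoothly heel-to-toe across stance, so the pressure centroid (CoP)
#' travels forward under the foot. Each sensel then receives a constant
#' offset (drawn once per stream) and white noise. The recorded CoP is the
#' pressure-weighted centroid of the noise- and offset-free frame, held at
#' its last value during swing.
#'
#' A non-zero `clock_offset` means the device clock lags truth: the value
#' recorded at timestamp `t` was physically sampled at `t + clock_offset`.
#'
#' @param kin result of [simulate_kinetics()] for the same side.
#' @param subject a [subject_spec()].
#' @param side `"left"` or `"right"`.
#' @param seed integer seed (noise and per-sensel offsets).
#' @param clock_offset seconds; see above.
#' @return class `insole_stream`: `t` (50 Hz timestamps), `pressure`
#'   (frames x 233), `cop` (frames x 2, grid row/col), `side`, `fs`,
#'   `clock_offset`.
#' @export
simulate_insole <- function(kin, subject, side = c("left", "right"),
                            seed = 1L, clock_offset = 0) {
  side <- match.arg(side)
  lay <- sensel_layout()
  strides <- kin$strides
  fs <- 50
  t_rec <- seq(0, max(kin$plate$t), by = 1 / fs)
  t_phys <- t_rec + clock_offset
  g <- grf_at(strides, t_phys)
  gain <- rep(1, length(t_phys))
  ok <- !is.na(g$stride)
  gain[ok] <- 1 + strides$g_l[g$stride[ok]]
  c_ins <- 0.35  # pressure units per %BW of vertical load
  tot <- c_ins * g$v * gain
  tau <- ifelse(is.na(g$tau) | g$tau > 1, NA_real_, g$tau)
  wf <- smoothstep(ifelse(is.na(tau), 0, tau))
  heel <- sensel_blob(25.5, 5.0, 2.2, 1.6, lay)
  fore <- sensel_blob(7.0, 5.2, 3.0, 2.2, lay)
  # frames = tot*(1-wf) (x) heel + tot*wf (x) fore  (rank-2 outer product)
  frames <- cbind(tot * (1 - wf), tot * wf) %*% rbind(heel, fore)
  cop <- cop_from_frames(frames, lay)
  # zero-order hold through swing (device behaviour); backfill leading NAs
  for (j in 1:2) {
    x <- cop[, j]
    if (all(is.na(x))) x <- rep(0, length(x)) else {
      filled <- !is.na(x)
      idx <- cummax(ifelse(filled, seq_along(x), 0L))
      first <- which(filled)[1]
      idx[idx == 0L] <- first
      x <- x[idx]
    }
    cop[, j] <- x
  }
  nl <- subject$noise_levels
  noisy <- with_seed(sub_seed(seed, paste0("insole_", side)), {
    offs <- stats::runif(233, nl$insole_offset[1], nl$insole_offset[2])
    fr <- sweep(frames, 2, offs, "+")
    if (nl$insole > 0) {
      fr <- fr + matrix(stats::rnorm(length(fr), sd = nl$insole),
                        nrow(fr), ncol(fr))
    }
    pmax(fr, 0)
  })
  structure(list(t = t_rec, pressure = noisy, cop = cop, side = side,
                 fs = fs, clock_offset = clock_offset),
            class = "insole_stream")
}

#' IMU channel names
#'
#' The 21 per-side channels retained for modelling: 3-axis local
#' acceleration of the foot and shank; 3-axis angular rate of the foot,
#' shank and thigh; pitch and roll Euler angles of the foot, shank and
#' thigh. The gyroscope y axis is the pitch axis and x the roll axis.
#'
#' @return character vector of length 21.
#' @export
imu_channels <- function() {
  segs3 <- c("foot", "shank", "thigh")
  c(paste0(rep(c("foot", "shank"), each = 3), "_acc_", c("x", "y", "z")),
    paste0(rep(segs3, each = 3), "_gyr_", c("x", "y", "z")),
    paste0(rep(segs3, each = 2), c("_pitch", "_roll")))
}

# central finite difference (one-sided at the ends); used for angular rates
fd_rate <- function(x, dt) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Simulate a 100 Hz IMU stream for one side
#'
#' Segment pitch/roll angles are smooth periodic functions of stride phase
#' whose ranges grow with walking speed and are scaled per stride by the
#' kinematic latent `1 + g_k` (the same latent that modulates propulsion
#' amplitude in [simulate_kinetics()]); all phase shapes vanish at phase 0
#' so angles are continuous across stride boundaries. Angular-rate channels
#' are the discrete time-derivative of the corresponding (noise-free)
#' angles. Accelerometer channels combine the exact gravity projection
#' through the segment's pitch/roll attitude with a speed-scaled periodic
#' motion term and, on the foot z axis, a decaying heel-strike impact
#' transient used for clock alignment. With zero commanded speed there are
#' no strides and the stream reduces to a static posture whose acceleration
#' norm equals gravity.
#'
#' @inheritParams simulate_insole
#' @return class `imu_stream`: `t`, `channels` (frames x 21 matrix with
#'   [imu_channels()] names), `side`, `fs`, `clock_offset`.
#' @export
simulate_imu <- function(kin, subject, side = c("left", "right"),
                         seed = 1L, clock_offset = 0) {
  side <- match.arg(side)
  strides <- kin$strides
  fs <- 100; dt <- 1 / fs
  t_rec <- seq(0, max(kin$plate$t), by = dt)
  t_phys <- t_rec + clock_offset
  sp <- stride_phase(strides, t_phys)
  n <- length(t_rec)
  phi <- ifelse(is.na(sp$phi), 0, sp$phi)
  amp <- rep(0, n)  # motion amplitude multiplier; 0 outside strides
  ok <- !is.na(sp$idx)
  v <- rep(0, n)
  if (any(ok)) {
    v[ok] <- strides$v[sp$idx[ok]]
    amp[ok] <- 1 + strides$g_k[sp$idx[ok]]
  }
  s2 <- sin(2 * pi * phi); s4 <- sin(4 * pi * phi); s6 <- sin(6 * pi * phi)
  grav <- 9.80665
  ang <- list(
    foot_pitch  = -5 + (10 + 12 * v) * amp * (s2 + 0.30 * s4),
    foot_roll   =  2 + (2 + 2 * v) * amp * (s2 - 0.50 * s4),
    shank_pitch =  3 + (14 + 14 * v) * amp * (s2 - 0.40 * s4 + 0.10 * s6),
    shank_roll  = -1 + (2 + 1.5 * v) * amp * (s4),
    thigh_pitch =  1 + (3 + 2 * v) * amp * (s4 + 0.3 * s6),
    thigh_roll  = -4 + (12 + 10 * v) * amp * (s2 + 0.20 * s6)
  )
  # internal yaw-like angles drive the third gyro axis (yaw orientation
  # itself is not an output channel: it drifts on real hardware)
  yaw <- list(foot = (3 + 2 * v) * amp * s2,
              shank = (2 + 2 * v) * amp * (s2 - 0.3 * s4),
              thigh = (2 + 1 * v) * amp * s4)
  gyr <- list()
  for (seg in c("foot", "shank", "thigh")) {
    gyr[[paste0(seg, "_gyr_x")]] <- fd_rate(ang[[paste0(seg, "_roll")]], dt)
    gyr[[paste0(seg, "_gyr_y")]] <- fd_rate(ang[[paste0(seg, "_pitch")]], dt)
    gyr[[paste0(seg, "_gyr_z")]] <- fd_rate(yaw[[seg]], dt)
  }
  acc <- list()
  for (seg in c("foot", "shank")) {
    th <- ang[[paste0(seg, "_pitch")]] * pi / 180
    ro <- ang[[paste0(seg, "_roll")]] * pi / 180
    Ma <- (if (seg == "foot") 3 else 2.2) * v * amp
    acc[[paste0(seg, "_acc_x")]] <- -grav * sin(th) + Ma * s2
    acc[[paste0(seg, "_acc_y")]] <- grav * cos(th) * sin(ro) + 0.2 * Ma * s4
    acc[[paste0(seg, "_acc_z")]] <- grav * cos(th) * cos(ro) + 0.6 * Ma * s4
  }
  # heel-strike impact transient on the foot z accelerometer
  if (nrow(strides)) {
    az <- acc$foot_acc_z
    for (i in seq_len(nrow(strides))) {
      d <- t_phys - strides$hs[i]
      w <- which(d >= 0 & d < 0.08)
      if (length(w)) az[w] <- az[w] + 12 * exp(-d[w] / 0.02)
    }
    acc$foot_acc_z <- az
  }
  ch <- cbind(do.call(cbind, acc), do.call(cbind, gyr), do.call(cbind, ang))
  colnames(ch) <- c(names(acc), names(gyr), names(ang))
  ch <- ch[, imu_channels(), drop = FALSE]
  nl <- subject$noise_levels
  if (any(c(nl$imu_acc, nl$imu_gyr, nl$imu_ang) > 0)) {
    sds <- c(rep(nl$imu_acc, 6), rep(nl$imu_gyr, 9), rep(nl$imu_ang, 6))
    noise <- with_seed(sub_seed(seed, paste0("imu_", side)),
                       matrix(stats::rnorm(n * 21), n, 21))
    ch <- ch + sweep(noise, 2, sds, "*")
  }
  # Euler angles live in (-180, 180]
  angcols <- grep("_(pitch|roll)$", colnames(ch))
  wrapped <- ch[, angcols] %% 360
  wrapped[wrapped > 180] <- wrapped[wrapped > 180] - 360
  ch[, angcols] <- wrapped
  structure(list(t = t_rec, channels = ch, side = side, fs = fs,
                 clock_offset = clock_offset),
            class = "imu_stream")
}
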