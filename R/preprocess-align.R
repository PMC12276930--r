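# Multi-rate synchronization and dataset assembly.

#' Zero the insole sensels using a foot-off window
#'
#' Measures the constant per-sensel offset during a detected foot-off
#' (swing) interval and subtracts it from every frame, so swing-phase
#' pressures have zero mean per sensel over that window.
#'
#' @param stream an `insole_stream`.
#' @param window optional c(t0, t1) explicit foot-off window (seconds on
#'   the stream clock); when `NULL` the longest low-pressure run is found
#'   automatically and a `window_s`-long window at its centre is used.
#' @param window_s automatic window length, seconds.
#' @return the stream with offsets removed (and the window used attached
#'   as `zero_window`).
#' @export
zero_insole <- function(stream, window = NULL, window_s = 0.3) {
  tot <- rowSums(stream$pressure)
  if (is.null(window)) {
    lo <- stats::quantile(tot, 0.02, names = FALSE)
    hi <- stats::quantile(tot, 0.98, names = FALSE)
    if (hi - lo < .Machine$double.eps) {
      # flat signal (e.g. all-zero input): whole stream is "foot off"
      low <- rep(TRUE, length(tot))
    } else {
      low <- tot < lo + 0.15 * (hi - lo)
    }
    r <- rle(low)
    if (!any(r$values)) {
      stop_gf("no foot-off interval found in insole stream (side %s)", stream$side)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    mid <- (starts[best] + ends[best]) / 2
    half <- max(1L, round(window_s * stream$fs / 2))
    i0 <- max(starts[best], floor(mid) - half)
    i1 <- min(ends[best], floor(mid) + half)
  } else {
    i0 <- findInterval(window[1], stream$t) + 1L
    i1 <- findInterval(window[2], stream$t)
    assert_that(i1 > i0, "explicit zeroing window contains no frames")
  }
  offs <- colMeans(stream$pressure[i0:i1, , drop = FALSE])
  stream$pressure <- sweep(stream$pressure, 2, offs, "-")
  stream$zero_window <- c(stream$t[i0], stream$t[i1])
  stream
}

#' Subtract the first-stride swing baseline from sensel frames
#'
#' Removes the per-sensel mean over the swing phase of the first stride
#' (fallback: the first available swing, with a warning) from every frame
#' of the trial.
#'
#' @param frames n x 233 matrix on the 100 Hz timeline.
#' @param events list(hs, to) frame indices from [detect_heel_strikes()].
#' @return frames with the baseline removed.
#' @export
swing_baseline_subtract <- function(frames, events) {
  n <- nrow(frames)
  swings <- list()
  for (i in seq_along(events$to)) {
    s0 <- events$to[i] + 1L
    s1 <- if (i < length(events$hs)) events$hs[i + 1L] - 1L else n
    if (s1 > s0) swings[[length(swings) + 1L]] <- c(s0, s1)
  }
  if (!length(swings)) {
    warning("no swing interval available; baseline not subtracted")
    return(frames)
  }
  if (length(events$to) && swings[[1]][1] != events$to[1] + 1L) {
    warning("first-stride swing unavailable; using first available swing")
  }
  w <- swings[[1]]
  base <- colMeans(frames[w[1]:w[2], , drop = FALSE])
  sweep(frames, 2, base, "-")
}

# intervals (start, end) where a stream's timestamps jump by more than one
# stride period
stream_gaps <- function(t, stride_len) {
  d <- diff(t)
  i <- which(d > stride_len)
  if (!length(i)) return(matrix(numeric(0), 0, 2))
  cbind(t[i], t[i + 1L])
}

# median offset between two sorted event-time vectors (NA if unmatched)
match_offset <- function(t_ref, t_obs, max_lag = 0.25) {
  if (!length(t_ref) || !length(t_obs)) return(NA_real_)
  d <- sapply(t_obs, function(x) {
    dd <- t_ref - x
    dd[which.min(abs(dd))]
  })
  d <- d[abs(d) <= max_lag]
  if (length(d) < 3) return(NA_real_)
  stats::median(d)
}

# cross-correlation lag (in samples, parabolic sub-sample refinement)
# between two equal-length series; positive lag means `a` leads `b`
xcorr_lag <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[1:(n - l)] * b[(1 + l):n]) else sum(a[(1 - l):n] * b[1:(n + l)])
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  if (i > 1 && i < length(lags)) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  lag
}

# estimate the insole clock offset against the force plate by
# cross-correlating total pressure with vertical GRF on a common grid
estimate_insole_offset <- function(total_pressure, t_ins, fs_ins,
                                   v_plate, t_plate, fs_plate, config,
                                   max_offset = 0.1) {
  dt <- 1 / config$target_rate_hz
  tg <- seq(max(min(t_ins), min(t_plate)), min(max(t_ins), max(t_plate)), by = dt)
  a <- interp1_flat(t_ins, total_pressure, tg)
  b <- interp1_flat(t_plate, v_plate, tg)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  # recorded insole timeline lags truth by the clock offset, so pressure
  # events appear earlier than the matching force-plate events
  -xcorr_lag(b, a, round(max_offset / dt)) * dt
}

# estimate the IMU clock offset from heel-strike impact transients on the
# foot z accelerometer
estimate_imu_offset <- function(acc_z, t_imu, fs_imu, hs_times_plate) {
  if (!length(hs_times_plate)) return(0)
  # residual above a slow baseline isolates the impact spikes
  k <- max(3L, round(0.35 * fs_imu)); if (k %% 2L == 0L) k <- k + 1L
  resid <- acc_z - stats::runmed(acc_z, k)
  thr <- 0.5 * stats::quantile(resid, 0.999, names = FALSE)
  if (thr <= 0) return(0)
  above <- resid > thr
  d <- diff(above)
  rises <- which(d == 1L) + 1L
  keep <- c(TRUE, diff(rises) >= 0.4 * fs_imu)
  while (!all(keep)) { rises <- rises[keep]; keep <- c(TRUE, diff(rises) >= 0.4 * fs_imu) }
  if (length(rises) < 3) return(0)
  # +dt/2 removes the uniform quantization bias of sample-resolution spikes
  off <- match_offset(hs_times_plate, t_imu[rises] - 0.5 / fs_imu)
  if (is.na(off)) 0 else off
}

#' Align one bout's streams onto the common 100 Hz clock
#'
#' Implements the synchronization stage for one (bout, side): force-plate
#' signals are zero-phase low-pass filtered and bin-averaged onto the
#' 100 Hz grid; insole frames are zeroed, filtered, spatially smoothed,
#' clock-corrected (the offset is estimated from heel-strike crossings
#' against the force plate), linearly interpolated stride-by-stride onto
#' the force-plate clock and decimated to 100 Hz; IMU channels are
#' filtered, clock-corrected via heel-strike impact transients, and
#' interpolated onto the same grid. Gait events are then detected on the
#' 100 Hz vertical GRF, the first-stride swing baseline is removed from
#' the sensel frames, and stance frames are resized to pressure maps.
#'
#' @param bout one element of a `gait_session`'s `bouts` list.
#' @param side `"left"` or `"right"`.
#' @param config a [preproc_config()].
#' @return list with `frames` (data.frame: time, stance, stride_id,
#'   frame_idx, target), `maps` (n x 784, stance frames only unless
#'   `config$stance_only` is FALSE), `cop`, `imu`, `events`,
#'   `offsets_est`, `n_frames_bout`.
#' @export
align_streams <- function(bout, side, config = preproc_config()) {
  st <- bout$sides[[side]]
  plate <- st$plate; ins <- st$insole; imu <- st$imu
  # --- force plate ---
  ap_f <- lowpass_zero_phase(plate$ap, plate$fs, config$cutoff_hz, config$butter_order)
  v_f <- lowpass_zero_phase(plate$v, plate$fs, config$cutoff_hz, config$butter_order)
  dt <- 1 / config$target_rate_hz
  t100 <- seq(0, max(plate$t), by = dt)
  n100 <- length(t100)
  bin <- pmin(floor(plate$t / dt) + 1L, n100)
  ap100 <- as.numeric(tapply(ap_f, bin, mean))
  v100 <- as.numeric(tapply(v_f, bin, mean))
  # --- insole ---
  ins <- zero_insole(ins, window_s = config$insole_zero_window)
  pr <- lowpass_zero_phase(ins$pressure, ins$fs, config$cutoff_hz, config$butter_order)
  pr <- spatial_gaussian(pr, config$gaussian_sigma)
  cop_f <- lowpass_zero_phase(ins$cop, ins$fs, config$cutoff_hz, config$butter_order)
  d_ins <- estimate_insole_offset(rowSums(pr), ins$t, ins$fs,
                                  v_f, plate$t, plate$fs, config)
  t_ins <- ins$t + d_ins
  pr100 <- apply(pr, 2, function(col) interp1_flat(t_ins, col, t100))
  cop100 <- apply(cop_f, 2, function(col) interp1_flat(t_ins, col, t100))
  # --- IMU ---
  hs_plate <- crossing_times(v_f, plate$t, plate$fs,
                             config$stance_threshold, config$min_gap_s)
  d_imu <- estimate_imu_offset(imu$channels[, "foot_acc_z"], imu$t, imu$fs, hs_plate)
  ch_f <- lowpass_zero_phase(imu$channels, imu$fs, config$cutoff_hz, config$butter_order)
  t_imu <- imu$t + d_imu
  imu100 <- apply(ch_f, 2, function(col) interp1_flat(t_imu, col, t100))
  colnames(imu100) <- colnames(imu$channels)
  # --- events on the common clock ---
  ev <- detect_heel_strikes(v100, config$target_rate_hz,
                            config$stance_threshold, config$min_gap_s)
  stance <- rep(FALSE, n100); stride_id <- rep(NA_integer_, n100)
  for (i in seq_along(ev$hs)) {
    stance[ev$hs[i]:ev$to[i]] <- TRUE
    stride_id[ev$hs[i]:ev$to[i]] <- i
  }
  # strides overlapping a recording gap longer than one stride are dropped
  if (length(ev$hs) >= 2L) {
    stride_len <- stats::median(diff(t100[ev$hs]))
    gaps <- rbind(stream_gaps(t_ins, stride_len), stream_gaps(t_imu, stride_len))
    if (nrow(gaps)) {
      dropped <- integer(0)
      for (i in seq_along(ev$hs)) {
        a <- t100[ev$hs[i]]; b2 <- t100[ev$to[i]]
        if (any(gaps[, 1] < b2 & gaps[, 2] > a)) {
          stance[ev$hs[i]:ev$to[i]] <- FALSE
          stride_id[ev$hs[i]:ev$to[i]] <- NA_integer_
          dropped <- c(dropped, i)
        }
      }
      if (length(dropped)) {
        message(sprintf("align_streams: dropped %d stride(s) overlapping stream gaps (side %s)",
                        length(dropped), side))
      }
    }
  }
  # --- insole baseline + maps ---
  pr100 <- swing_baseline_subtract(pr100, ev)
  keep <- if (config$stance_only) which(stance) else seq_len(n100)
  maps <- resize_pressure_map(pr100[keep, , drop = FALSE],
                              map_size = config$map_size)
  maps <- pmax(maps, 0)
  list(
    frames = data.frame(time = t100[keep], stance = stance[keep],
                        stride_id = stride_id[keep], frame_idx = keep,
                        target = ap100[keep]),
    maps = maps, cop = cop100[keep, , drop = FALSE],
    imu = imu100[keep, , drop = FALSE],
    events = ev, offsets_est = c(insole = d_ins, imu = d_imu),
    n_frames_bout = n100
  )
}

#' Assemble the aligned, stance-only dataset for one side of a session
#'
#' Runs [align_streams()] over every bout and concatenates the results
#' into one modelling table. Targets are the 100 Hz bin-averaged,
#' zero-phase filtered force-plate AP GRF in %BW (anterior positive).
#' Normalization is NOT applied here: constants must be fitted on a
#' training split only (see [fit_minmax()]).
#'
#' @param session a [simulate_session()] result.
#' @param side `"left"` or `"right"`.
#' @param config a [preproc_config()].
#' @return object of class `gait_dataset`: `meta` (frame table with
#'   bout_id, bout_center, stride_id, frame_idx, n_frames_bout, target),
#'   `maps`, `cop`, `imu`, `side`, `subject`, `config`, `offsets_est`.
#' @export
build_dataset <- function(session, side = c("left", "right"),
                          config = preproc_config()) {
  side <- match.arg(side)
  parts <- lapply(session$bouts, function(b) {
    al <- align_streams(b, side, config)
    al$frames$bout_id <- b$bout_id
    al$frames$bout_center <- b$center
    al$frames$n_frames_bout <- al$n_frames_bout
    al
  })
  meta <- do.call(rbind, lapply(parts, `[[`, "frames"))
  # stride ids unique across bouts
  offs <- 0L
  row0 <- 1L
  for (p in parts) {
    n <- nrow(p$frames)
    sel <- row0:(row0 + n - 1L)
    meta$stride_id[sel] <- meta$stride_id[sel] + offs
    offs <- offs + length(p$events$hs)
    row0 <- row0 + n
  }
  structure(list(
    meta = meta,
    maps = do.call(rbind, lapply(parts, `[[`, "maps")),
    cop = do.call(rbind, lapply(parts, `[[`, "cop")),
    imu = do.call(rbind, lapply(parts, `[[`, "imu")),
    offsets_est = lapply(parts, `[[`, "offsets_est"),
    side = side, subject = session$subject, config = config,
    session_seed = session$seed
  ), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> side %s: %d frames, %d strides, %d bouts\n",
              x$side, nrow(x$meta),
              length(unique(stats::na.omit(x$meta$stride_id))),
              length(unique(x$meta$bout_id))))
  invisible(x)
}
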