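#' Preprocessing configuration
#'
#' Collects the tunable constants of the preprocessing chain. Defaults are
#' the protocol values: a zero-phase 2nd-order Butterworth low-pass at
#' 10 Hz, a spatial Gaussian of sigma 0.5 grid units on the sensel layout,
#' resampling to 100 Hz, 28 x 28 pressure maps, 5-frame sequences, and a
#' heel-strike threshold at 3 % of the per-stride vertical-load peak with a
#' 0.4 s debounce.
#'
#' @param butter_order Butterworth order (applied forward-backward).
#' @param cutoff_hz low-pass cutoff (must be below half the target rate).
#' @param gaussian_sigma spatial Gaussian std in sensel-grid units.
#' @param target_rate_hz common resampling rate.
#' @param map_size output pressure-map side length.
#' @param sequence_len LSTM sequence length in frames.
#' @param stance_threshold fraction of the per-stride vertical peak that
#'   defines heel-strike/toe-off crossings.
#' @param min_gap_s minimum inter-heel-strike gap (debounce), seconds.
#' @param insole_zero_window length of the foot-off window used to zero the
#'   sensels, seconds.
#' @param stance_only drop swing frames from the assembled dataset.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(butter_order = 2, cutoff_hz = 10,
                           gaussian_sigma = 0.5, target_rate_hz = 100,
                           map_size = 28, sequence_len = 5,
                           stance_threshold = 0.03, min_gap_s = 0.4,
                           insole_zero_window = 0.3, stance_only = TRUE) {
  assert_that(cutoff_hz < target_rate_hz / 2,
              "cutoff (%g Hz) must be below the target Nyquist (%g Hz)",
              cutoff_hz, target_rate_hz / 2)
  assert_that(sequence_len >= 1, "sequence_len must be >= 1")
  structure(list(butter_order = butter_order, cutoff_hz = cutoff_hz,
                 gaussian_sigma = gaussian_sigma,
                 target_rate_hz = target_rate_hz, map_size = map_size,
                 sequence_len = sequence_len,
                 stance_threshold = stance_threshold, min_gap_s = min_gap_s,
                 insole_zero_window = insole_zero_window,
                 stance_only = stance_only),
            class = "preproc_config")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward
#' (`signal::filtfilt`), giving zero phase lag and a squared magnitude
#' response (half-power amplitude ratio 0.5 at the cutoff for a 2nd-order
#' design). DC gain is exactly 1.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param order filter order.
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff_hz = 10, order = 2) {
  assert_that(fs > 2 * cutoff_hz, "fs must exceed twice the cutoff")
  nmin <- 3 * (order * 3 + 1)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  assert_that(n >= nmin, "signal too short to filter (%d < %d)", n, nmin)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding long enough for startup transients to die out,
  # plus mean-centering so the unit DC gain is exact
  pad <- min(n - 1L, ceiling(6 * fs / cutoff_hz))
  ff1 <- function(col) {
    mu <- mean(col)
    xc <- col - mu
    xp <- c(2 * xc[1] - xc[(pad + 1L):2L],
            xc,
            2 * xc[n] - xc[(n - 1L):(n - pad)])
    y <- signal::filter(bf, xp)
    y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
    y[(pad + 1L):(pad + n)] + mu
  }
  if (is.matrix(x)) apply(x, 2, ff1) else ff1(x)
}

# masked, renormalised spatial Gaussian kernel over the sensel layout,
# returned as a 233 x 233 row-stochastic matrix (cached per sigma)
gaussian_sensel_kernel <- function(sigma, layout = sensel_layout()) {
  key <- paste0("gk_", format(sigma, digits = 12))
  if (!is.null(.gf_cache[[key]])) return(.gf_cache[[key]])
  n <- 233L
  if (sigma < 1e-8) {
    G <- diag(n)
  } else {
    R <- ceiling(3 * sigma)
    dr <- outer(layout$rows, layout$rows, "-")
    dc <- outer(layout$cols, layout$cols, "-")
    G <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
    G[abs(dr) > R | abs(dc) > R] <- 0
    G <- G / rowSums(G)
  }
  .gf_cache[[key]] <- G
  G
}

#' Spatial Gaussian smoothing of sensel frames
#'
#' Smooths each pressure frame over the sensel grid with a unit-sum
#' Gaussian kernel, renormalised over in-mask neighbours so the foot-shaped
#' boundary does not leak pressure off the mask. A uniform frame is left
#' unchanged and `sigma -> 0` is the identity.
#'
#' @param frames n x 233 matrix (or length-233 vector) of sensel values.
#' @param sigma Gaussian std in grid units (default 0.5).
#' @param layout a [sensel_layout()].
#' @return smoothed frames, same shape.
#' @export
spatial_gaussian <- function(frames, sigma = 0.5, layout = sensel_layout()) {
  vec <- is.null(dim(frames))
  if (vec) frames <- matrix(frames, nrow = 1L)
  G <- gaussian_sensel_kernel(sigma, layout)
  out <- frames %*% t(G)
  if (vec) out[1, ] else out
}

# 1-D pixel-area (box) interpolation weights: n_dst x n_src, rows sum to 1
area_weights <- function(n_src, n_dst) {
  W <- matrix(0, n_dst, n_src)
  w_cell <- n_src / n_dst  # source units covered by one target cell
  for (i in seq_len(n_dst)) {
    lo <- (i - 1) * w_cell; hi <- i * w_cell
    r0 <- floor(lo) + 1L; r1 <- ceiling(hi)
    for (r in r0:min(r1, n_src)) {
      ov <- min(hi, r) - max(lo, r - 1)
      if (ov > 0) W[i, r] <- ov / w_cell
    }
  }
  W
}

# cached 341 -> 784 resize operator (embedded grid, column-major both sides)
resize_operator <- function(layout = sensel_layout(), map_size = 28L) {
  key <- paste0("rz_", map_size)
  if (!is.null(.gf_cache[[key]])) return(.gf_cache[[key]])
  Wr <- area_weights(layout$nrow, map_size)  # rows: 31 -> 28
  Wc <- area_weights(layout$ncol, map_size)  # cols: 11 -> 28
  R <- kronecker(t(Wc), t(Wr))               # (341 x 784) on column-major vecs
  .gf_cache[[key]] <- R
  R
}

#' Resize sensel frames to square pressure maps
#'
#' Embeds each 233-sensel frame on its 31 x 11 bounding grid (off-mask
#' cells zero) and applies pixel-area (box) interpolation to a
#' `map_size` x `map_size` map. Area interpolation preserves constants and
#' the grid mean, and maps non-negative frames to non-negative maps.
#'
#' @param frames n x 233 matrix (or length-233 vector) of sensel values.
#' @param layout a [sensel_layout()].
#' @param map_size output side length (default 28).
#' @return n x `map_size`^2 matrix; each row is a column-major map.
#' @export
resize_pressure_map <- function(frames, layout = sensel_layout(), map_size = 28L) {
  vec <- is.null(dim(frames))
  emb <- embed_frames(frames, layout)
  out <- emb %*% resize_operator(layout, map_size)
  if (vec) out[1, ] else out
}

#' Detect heel-strike and toe-off events from a vertical-load signal
#'
#' Finds rising crossings of `threshold` times the per-stride peak of the
#' signal (vertical GRF or insole total pressure), debounced by a minimum
#' inter-event gap; the matching falling crossing is the toe-off. An
#' initial pass uses a robust global peak to segment cycles, then each
#' cycle's own peak refines its crossing threshold.
#'
#' @param v non-negative load signal.
#' @param fs sampling rate, Hz.
#' @param threshold fraction of the per-stride peak (default 0.03).
#' @param min_gap_s debounce gap in seconds (default 0.4).
#' @return list(hs, to): 1-based sample indices (equal length; events with
#'   no matching toe-off are dropped). Zero-event signals return empty
#'   vectors with a warning.
#' @export
detect_heel_strikes <- function(v, fs, threshold = 0.03, min_gap_s = 0.4) {
  stopifnot(is.numeric(v))
  peak0 <- stats::quantile(v, 0.995, names = FALSE)
  if (!is.finite(peak0) || peak0 <= 0) {
    warning("no gait events found: signal has no positive load")
    return(list(hs = integer(0), to = integer(0)))
  }
  thr0 <- threshold * peak0
  above <- v > thr0
  d <- diff(above)
  rises <- which(d == 1L) + 1L
  falls <- which(d == -1L) + 1L
  if (!length(rises)) {
    warning("no gait events found above threshold")
    return(list(hs = integer(0), to = integer(0)))
  }
  # debounce rises
  keep <- c(TRUE, diff(rises) >= min_gap_s * fs)
  while (!all(keep)) {
    rises <- rises[keep]
    keep <- c(TRUE, diff(rises) >= min_gap_s * fs)
  }
  hs <- integer(0); to <- integer(0)
  for (i in seq_along(rises)) {
    r <- rises[i]
    f <- falls[falls > r]
    f <- if (length(f)) f[1] else NA_integer_
    nxt <- if (i < length(rises)) rises[i + 1] else length(v) + 1L
    if (is.na(f) || f >= nxt) next  # incomplete stance at the end
    pk <- max(v[r:f])
    thr <- threshold * pk
    # refine: walk outward from the above-threshold region
    h <- r
    while (h > 1L && v[h - 1L] > thr) h <- h - 1L
    while (h < f && v[h] <= thr) h <- h + 1L
    tt <- f
    while (tt < nxt - 1L && tt < length(v) && v[tt] > thr) tt <- tt + 1L
    while (tt > h && v[tt - 1L] <= thr) tt <- tt - 1L
    hs <- c(hs, h); to <- c(to, tt)
  }
  list(hs = hs, to = to)
}

# continuous threshold-crossing times (for sub-sample clock estimation)
crossing_times <- function(v, t, fs, threshold = 0.03, min_gap_s = 0.4) {
  ev <- detect_heel_strikes(v, fs, threshold, min_gap_s)
  if (!length(ev$hs)) return(numeric(0))
  pk <- stats::quantile(v, 0.995, names = FALSE)
  sapply(ev$hs, function(i) {
    thr <- threshold * pk
    if (i <= 1L || v[i] == v[i - 1L]) return(t[i])
    t[i - 1L] + (thr - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
  })
}

#' Fit grouped min-max normalization constants
#'
#' Computes per-group minima and spans from training frames only. All
#' channels of a group (e.g. the three acceleration axes of one IMU, the
#' whole pressure map, or the CoP pair) share one (min, span) so their
#' relative scale is preserved; the training range maps to \[0, 1\] and
#' test data may fall outside. Degenerate (constant) groups get span 1 with
#' a warning and normalise to 0.
#'
#' @param x n x p numeric matrix of training frames.
#' @param groups named list of column-index vectors partitioning `1:p`.
#' @return list of class `minmax_constants` with `min`, `span` per group.
#' @export
fit_minmax <- function(x, groups) {
  cons <- lapply(groups, function(cols) {
    v <- x[, cols, drop = FALSE]
    mn <- min(v); mx <- max(v)
    if (mx - mn < .Machine$double.eps) {
      warning("degenerate (constant) normalization group; using span 1")
      list(min = mn, span = 1)
    } else list(min = mn, span = mx - mn)
  })
  structure(list(groups = groups, constants = cons), class = "minmax_constants")
}

#' Apply min-max normalization constants
#'
#' @param x n x p matrix on the same column layout used in [fit_minmax()].
#' @param cons a `minmax_constants` object.
#' @return normalized matrix (training range mapped to \[0, 1\], no
#'   clipping).
#' @export
apply_minmax <- function(x, cons) {
  out <- x
  for (g in names(cons$groups)) {
    cols <- cons$groups[[g]]
    cc <- cons$constants[[g]]
    out[, cols] <- (x[, cols, drop = FALSE] - cc$min) / cc$span
  }
  out
}

#' Standard normalization groups for the aligned feature layout
#'
#' @return named list of column indices for a feature matrix laid out as
#'   21 IMU channels (see [imu_channels()]) followed by 2 CoP channels.
#' @export
feature_groups <- function() {
  ch <- imu_channels()
  g <- list(
    foot_acc = grep("^foot_acc", ch), shank_acc = grep("^shank_acc", ch),
    foot_gyr = grep("^foot_gyr", ch), shank_gyr = grep("^shank_gyr", ch),
    thigh_gyr = grep("^thigh_gyr", ch),
    foot_ang = grep("^foot_(pitch|roll)", ch),
    shank_ang = grep("^shank_(pitch|roll)", ch),
    thigh_ang = grep("^thigh_(pitch|roll)", ch)
  )
  g$cop <- 22:23
  g
}

#' Build LSTM sequence indices
#'
#' For each retained frame `t`, the sequence is the `L` frames
#' `t-L+1 ... t` within the same contiguous stance segment; at segment
#' starts the first stance frame is repeated (left padding). One sequence
#' is emitted per frame.
#'
#' @param segment_id integer vector: contiguous-segment label per frame
#'   (e.g. stride id of stance frames, in time order).
#' @param L sequence length.
#' @return n x L matrix of row indices; column L is the current frame.
#' @export
make_sequences <- function(segment_id, L = 5L) {
  n <- length(segment_id)
  idx <- matrix(0L, n, L)
  start_of <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    if (i > 1L && segment_id[i] != segment_id[i - 1L]) cur <- i
    start_of[i] <- cur
  }
  for (k in seq_len(L)) {
    idx[, k] <- pmax(seq_len(n) - (L - k), start_of)
  }
  idx
}
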