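# Parametric per-stride gait model.
#
# The simulator is deliberately simple: smooth speed-dependent stride
# kinetics with closed-form lobe shapes so every derived quantity (impulse,
# peak, timing) has an analytic oracle. Two independent per-stride latent
# gains drive the propulsion amplitude: a kinematic latent g_k (expressed in
# the IMU channels) and a loading latent g_l (expressed in the insole
# pressure gain). Neither sensing modality alone observes both, which is what
# makes multi-modal fusion strictly better than either single modality on
# this generator.

# model constants (documented in the methods vignette)
gf_gait_constants <- function() {
  list(
    T_ref = 1.1,      # stride period at 1 m/s (s)
    T_exp = -0.4,     # period ~ speed^T_exp
    T_clamp = c(0.8, 2.0),
    duty = function(v) pmin(pmax(0.68 - 0.05 * v, 0.55), 0.70),
    P0 = function(v) 5 + 10 * v,       # base peak propulsion (%BW)
    B_frac = 0.85,                      # braking amplitude / propulsion base
    Av = function(v) 150 + 15 * v,      # vertical GRF scale (%BW-like)
    v_hump = 0.4,                       # double-hump depth of vertical GRF
    tau_b0 = 0.02, wb = 0.44,           # braking lobe start/width (frac stance)
    tau_p0 = 0.54, wp = 0.44,           # propulsion lobe start/width
    latent_sd = 0.08,                   # std of g_k and g_l
    P_floor = 0.2                       # propulsion amplitude floor (%BW)
  )
}

stride_period <- function(v) {
  k <- gf_gait_constants()
  pmin(pmax(k$T_ref * pmax(v, 0.2)^k$T_exp, k$T_clamp[1]), k$T_clamp[2])
}

# vertical GRF shape on stance fraction tau in [0, 1]; double hump
vgrf_shape <- function(tau) {
  k <- gf_gait_constants()
  pmax(sin(pi * tau) * (1 + k$v_hump * cos(2 * pi * tau)), 0)
}

# signed AP GRF shape for one stride given amplitudes (vectorised over tau)
ap_shape <- function(tau, P, B) {
  k <- gf_gait_constants()
  out <- numeric(length(tau))
  ib <- tau >= k$tau_b0 & tau <= k$tau_b0 + k$wb
  out[ib] <- -B * sin(pi * (tau[ib] - k$tau_b0) / k$wb)
  ip <- tau >= k$tau_p0 & tau <= k$tau_p0 + k$wp
  out[ip] <- out[ip] + P * sin(pi * (tau[ip] - k$tau_p0) / k$wp)
  out
}

# Build the per-stride table for one side of one bout. `perturb` is NULL or
# list(window = c(t0, t1) in bout-local seconds, delta = %BW).
stride_table <- function(profile, subject, side, perturb = NULL) {
  k <- gf_gait_constants()
  nl <- subject$noise_levels
  paretic <- identical(side, subject$paretic_side)
  pf <- if (paretic) 1 - subject$impairment else 1
  t0 <- 0.1 + if (side == "left") stride_period(profile$v2) / 2 else 0
  rows <- list(); t <- t0
  repeat {
    v <- speed_at(profile, t)
    if (v <= 1e-6) break  # zero commanded speed: no gait
    Tk <- stride_period(v) * (1 + nl$stride_cv * stats::rnorm(1))
    ds <- gf_gait_constants()$duty(v) * Tk
    if (t + ds > profile$t4) break
    g_k <- k$latent_sd * stats::rnorm(1)
    g_l <- k$latent_sd * stats::rnorm(1)
    if (!is.null(perturb) && t >= perturb$window[1] && t <= perturb$window[2]) {
      # intervention emulation: route the propulsion shift through the
      # kinematic latent so IMU channels reflect it coherently
      g_k <- g_k + perturb$delta / (k$P0(v) * pf)
    }
    P <- max(k$P0(v) * pf * (1 + g_k + g_l), k$P_floor)
    B <- max(k$B_frac * k$P0(v) * (1 - 0.5 * (if (paretic) subject$impairment else 0)) *
               (1 + 0.5 * (g_k + g_l)), k$P_floor)
    A <- k$Av(v)
    rows[[length(rows) + 1L]] <-
      data.frame(hs = t, T = Tk, ds = ds, to = t + ds, v = v,
                 g_k = g_k, g_l = g_l, P = P, B = B, A = A)
    t <- t + Tk
  }
  if (!length(rows)) {
    return(data.frame(hs = numeric(0), T = numeric(0), ds = numeric(0),
                      to = numeric(0), v = numeric(0), g_k = numeric(0),
                      g_l = numeric(0), P = numeric(0), B = numeric(0),
                      A = numeric(0)))
  }
  do.call(rbind, rows)
}

# stride index (or NA) and within-stride phase for arbitrary times
stride_phase <- function(strides, t) {
  if (!nrow(strides)) {
    return(list(idx = rep(NA_integer_, length(t)), phi = rep(NA_real_, length(t))))
  }
  idx <- findInterval(t, strides$hs)
  phi <- rep(NA_real_, length(t))
  ok <- idx >= 1L
  ok[ok] <- t[ok] < strides$hs[idx[ok]] + strides$T[idx[ok]]
  idx[!ok] <- NA_integer_
  phi[ok] <- (t[ok] - strides$hs[idx[ok]]) / strides$T[idx[ok]]
  list(idx = idx, phi = phi)
}

# analytic AP and vertical GRF (no noise) at arbitrary times
grf_at <- function(strides, t) {
  ap <- numeric(length(t)); vg <- numeric(length(t))
  sp <- stride_phase(strides, t)
  ok <- which(!is.na(sp$idx))
  if (length(ok)) {
    tau <- sp$phi[ok] * strides$T[sp$idx[ok]] / strides$ds[sp$idx[ok]]
    st <- tau <= 1
    i <- ok[st]; taui <- tau[st]; ki <- sp$idx[ok][st]
    vg[i] <- strides$A[ki] * vgrf_shape(taui)
    # lobes (vectorised across strides)
    kc <- gf_gait_constants()
    ib <- taui >= kc$tau_b0 & taui <= kc$tau_b0 + kc$wb
    ap[i[ib]] <- -strides$B[ki[ib]] * sin(pi * (taui[ib] - kc$tau_b0) / kc$wb)
    ip <- taui >= kc$tau_p0 & taui <= kc$tau_p0 + kc$wp
    ap[i[ip]] <- ap[i[ip]] + strides$P[ki[ip]] * sin(pi * (taui[ip] - kc$tau_p0) / kc$wp)
  }
  list(ap = ap, v = vg, stride = sp$idx, tau = {
    tau_all <- rep(NA_real_, length(t))
    tau_all[ok] <- sp$phi[ok] * strides$T[sp$idx[ok]] / strides$ds[sp$idx[ok]]
    tau_all
  })
}

#' Simulate force-plate kinetics and ground-truth events for one side
#'
#' Generates a 2000 Hz force-plate stream (signed anterior-positive AP GRF
#' and non-negative vertical GRF, both in %BW) together with the exact
#' ground-truth gait events and per-stride propulsion metrics. Stance-phase
#' AP GRF is a negative braking half-sine followed by a positive propulsion
#' half-sine; forces are exactly zero during swing. The paretic side of a
#' clinical subject has its propulsion amplitude scaled by
#' `1 - impairment`.
#'
#' @param profile a [make_speed_profile()] object.
#' @param subject a [subject_spec()].
#' @param side `"left"` or `"right"`.
#' @param seed integer seed for stride-to-stride variability.
#' @param perturb optional list(window = c(t0, t1), delta) adding `delta`
#'   %BW of propulsion to strides starting inside the bout-local window.
#' @return list with elements `plate` (class `plate_stream`: `t`, `ap`,
#'   `v`, `side`, `fs`) and `events` (data.frame of per-stride truth:
#'   `hs`, `to`, `v`, `g_k`, `g_l`, `peak`, `impulse`, `timing_pct`).
#' @export
simulate_kinetics <- function(profile, subject, side = c("left", "right"),
                              seed = 1L, perturb = NULL) {
  side <- match.arg(side)
  k <- gf_gait_constants()
  strides <- with_seed(sub_seed(seed, paste0("kinetics_", side)),
                       stride_table(profile, subject, side, perturb))
  fs <- 2000
  t <- seq(0, profile$t4, by = 1 / fs)
  g <- grf_at(strides, t)
  ap <- g$ap; vg <- g$v
  stance <- !is.na(g$tau) & g$tau <= 1
  if (subject$noise_levels$fp > 0 && any(stance)) {
    noise <- with_seed(sub_seed(seed, paste0("fpnoise_", side)),
                       stats::rnorm(2L * sum(stance), sd = subject$noise_levels$fp))
    ap[stance] <- ap[stance] + noise[seq_len(sum(stance))]
    vg[stance] <- pmax(vg[stance] + noise[sum(stance) + seq_len(sum(stance))], 0)
  }
  events <- data.frame(
    hs = strides$hs, to = strides$to, v = strides$v,
    g_k = strides$g_k, g_l = strides$g_l,
    peak = strides$P,
    impulse = 2 * strides$P * (k$wp * strides$ds) / pi,
    timing_pct = (k$tau_p0 + k$wp / 2) * 100
  )
  plate <- structure(list(t = t, ap = ap, v = vg, side = side, fs = fs),
                     class = "plate_stream")
  list(plate = plate, events = events, strides = strides)
}
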