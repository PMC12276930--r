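#' Default bout plan for a cohort
#'
#' Bout centers follow the protocol grids: percentages of CWS (70–130, step
#' 10) for clinical subjects and absolute speeds (0.6–1.4 m/s, step 0.2) for
#' healthy subjects. Plans spread the requested number of bouts over the
#' grid while always including bouts adjacent to the comfortable speed so a
#' by-bout split has natural validation/test bouts.
#'
#' @param cohort `"clinical"` or `"healthy"`.
#' @param n_bouts number of bouts (3–7 clinical, 3–6 healthy).
#' @return data.frame with columns `center` and `a1_sign`.
#' @export
default_bout_plan <- function(cohort = c("clinical", "healthy"), n_bouts = 4L) {
  cohort <- match.arg(cohort)
  centers <- if (cohort == "clinical") {
    switch(as.character(n_bouts),
           "3" = c(70, 100, 130),
           "4" = c(70, 90, 110, 130),
           "5" = c(70, 90, 100, 110, 130),
           "6" = c(70, 80, 90, 110, 120, 130),
           "7" = seq(70, 130, 10),
           stop_gf("no default clinical plan for %d bouts", n_bouts))
  } else {
    switch(as.character(n_bouts),
           "3" = c(0.6, 1.0, 1.4),
           "4" = c(0.6, 0.8, 1.2, 1.4),
           "5" = seq(0.6, 1.4, 0.2),
           "6" = c(seq(0.6, 1.4, 0.2), 1.0),
           stop_gf("no default healthy plan for %d bouts", n_bouts))
  }
  data.frame(center = centers,
             a1_sign = rep(c(1, -1), length.out = length(centers)))
}

#' Simulate a complete multi-rate sensor session
#'
#' Generates one walking session for a virtual subject: for each bout a
#' commanded treadmill speed profile and, per side, a 2000 Hz force-plate
#' stream with exact ground-truth events, a 50 Hz insole stream and a
#' 100 Hz IMU stream. The insole and IMU streams carry known constant clock
#' offsets (so the preprocessing alignment stage has something to recover),
#' and the bout order is randomized and recorded. The whole session is a
#' deterministic function of `(subject, bout_plan, seed)`.
#'
#' @param subject a [subject_spec()].
#' @param bout_plan data.frame(center, a1_sign), a vector of centers, or
#'   `NULL` to use [default_bout_plan()] with `n_bouts`.
#' @param seed integer master seed; all stream sub-seeds derive from it.
#' @param n_bouts used when `bout_plan` is `NULL`.
#' @param clock_offsets list(insole=, imu=) true clock offsets in seconds.
#' @param duration_scale passed to [make_speed_profile()]; < 1 gives
#'   shortened bouts for desk-scale experiments.
#' @param perturb optional list(window = c(t0, t1) in session seconds,
#'   delta = %BW) applied to strides starting inside the window; see
#'   [perturb_propulsion()].
#' @return class `gait_session`.
#' @export
simulate_session <- function(subject, bout_plan = NULL, seed = 1L,
                             n_bouts = 4L,
                             clock_offsets = list(insole = 0.02, imu = 0.01),
                             duration_scale = 1, perturb = NULL) {
  if (is.null(bout_plan)) bout_plan <- default_bout_plan(subject$cohort, n_bouts)
  if (is.numeric(bout_plan)) {
    bout_plan <- data.frame(center = bout_plan,
                            a1_sign = rep(c(1, -1), length.out = length(bout_plan)))
  }
  ord <- with_seed(sub_seed(seed, "bout_order"), sample.int(nrow(bout_plan)))
  plan <- bout_plan[ord, , drop = FALSE]
  bouts <- vector("list", nrow(plan))
  t_offset <- 0
  for (b in seq_len(nrow(plan))) {
    prof <- make_speed_profile(subject$cohort, subject$cws, plan$center[b],
                               a1_sign = plan$a1_sign[b],
                               duration_scale = duration_scale)
    local_pert <- NULL
    if (!is.null(perturb)) {
      lo <- max(perturb$window[1] - t_offset, 0)
      hi <- min(perturb$window[2] - t_offset, prof$t4)
      if (hi > lo) local_pert <- list(window = c(lo, hi), delta = perturb$delta)
    }
    bseed <- sub_seed(seed, paste0("bout", b))
    sides <- list()
    for (sd in c("left", "right")) {
      kin <- simulate_kinetics(prof, subject, sd, seed = bseed, perturb = local_pert)
      ins <- simulate_insole(kin, subject, sd, seed = bseed,
                             clock_offset = clock_offsets$insole %||% 0)
      imu <- simulate_imu(kin, subject, sd, seed = bseed,
                          clock_offset = clock_offsets$imu %||% 0)
      sides[[sd]] <- list(plate = kin$plate, events = kin$events,
                          strides = kin$strides, insole = ins, imu = imu)
    }
    bouts[[b]] <- list(bout_id = b, center = plan$center[b],
                       a1_sign = plan$a1_sign[b], t_offset = t_offset,
                       profile = prof, sides = sides)
    t_offset <- t_offset + prof$t4
  }
  structure(list(subject = subject, seed = seed, clock_offsets = clock_offsets,
                 duration_scale = duration_scale, bout_plan = plan,
                 bout_plan_input = bout_plan, bouts = bouts, span = t_offset,
                 perturb = perturb),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %s, %d bouts, span %.0f s, seed %d\n",
              x$subject$subject_id, length(x$bouts), x$span, x$seed))
  invisible(x)
}

#' Apply a propulsion perturbation to a session
#'
#' Emulates an active gait intervention (e.g. functional electrical
#' stimulation or exosuit assistance/resistance) by shifting the propulsion
#' amplitude of every stride starting inside `window` by `delta` %BW. The
#' shift is routed through the kinematic stride latent, so force-plate
#' kinetics, ground-truth metrics and IMU channels all change coherently
#' while insole loading is unaffected. The session is re-simulated with its
#' original seed, so `delta = 0` reproduces the input exactly and the
#' propulsion amplitude remains floored at a small positive value for
#' strongly negative `delta`.
#'
#' @param session a [simulate_session()] result.
#' @param window c(t0, t1) in session seconds.
#' @param delta propulsion shift in %BW.
#' @return a new `gait_session`.
#' @export
perturb_propulsion <- function(session, window, delta) {
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be c(t0, t1) with t0 < t1")
  assert_that(window[1] >= 0 && window[2] <= session$span,
              "window [%.1f, %.1f] outside session span [0, %.1f]",
              window[1], window[2], session$span)
  simulate_session(session$subject,
                   bout_plan = session$bout_plan_input,
                   seed = session$seed,
                   clock_offsets = session$clock_offsets,
                   duration_scale = session$duration_scale,
                   perturb = list(window = window, delta = delta))
}

#' Session-level ground-truth stride table
#'
#' @param session a `gait_session`.
#' @return data.frame of all strides with session-time `hs`/`to`, side,
#'   bout_id and the true per-stride propulsion metrics.
#' @export
session_truth <- function(session) {
  out <- lapply(session$bouts, function(b) {
    do.call(rbind, lapply(c("left", "right"), function(sd) {
      ev <- b$sides[[sd]]$events
      if (!nrow(ev)) return(NULL)
      cbind(bout_id = b$bout_id, side = sd,
            transform(ev, hs = hs + b$t_offset, to = to + b$t_offset))
    }))
  })
  do.call(rbind, out)
}
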