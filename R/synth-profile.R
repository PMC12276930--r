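#' Commanded treadmill speed profile
#'
#' Builds the commanded treadmill speed schedule for one walking bout. The
#' profile holds an initial speed `v2` for a constant period, then ramps
#' repeatedly between a minimum `v1` and a maximum `v3` until the end of the
#' bout, with plateau holds at each extreme. Protocol constants depend on the
#' cohort:
#'
#' * clinical: `v2` given as a percentage of the subject's comfortable
#'   walking speed (CWS) on the grid 70–130 %CWS in steps of 10;
#'   `v1 = v2 - 20 %CWS`, `v3 = v2 + 20 %CWS`; constant period `t1 = 120` s,
#'   bout length `t4 = 240` s, extremes held 15 s.
#' * healthy: `v2` given in m/s on the grid 0.6–1.4 in steps of 0.2;
#'   `v1 = v2 - 0.2`, `v3 = v2 + 0.2` m/s; `t1 = 180` s, `t4 = 600` s,
#'   extremes held 60 s.
#'
#' Ramps always change speed by `v2 - v1` in 30 s, so a full sweep between
#' extremes takes 60 s regardless of cohort.
#'
#' @param cohort `"clinical"` or `"healthy"`.
#' @param cws comfortable walking speed (m/s); used to convert %CWS centers.
#' @param center bout center: %CWS (clinical) or m/s (healthy).
#' @param a1_sign +1 to ramp up first, -1 to ramp down first.
#' @param seed unused; the commanded profile is deterministic. Accepted so
#'   the simulator can thread one seed through every stage uniformly.
#' @param duration_scale scales `t1`, `t4` and the plateau holds (not the
#'   ramp slope) to produce shorter bouts for desk-scale experiments.
#' @return Object of class `treadmill_profile` with fields `t1`, `t4`,
#'   `v1`, `v2`, `v3`, `a1_sign`, `hold`, `knots` (piecewise-linear
#'   breakpoints) and `samples` (10 Hz (time, speed) series).
#' @examples
#' pr <- make_speed_profile("clinical", cws = 1.0, center = 70)
#' c(pr$v1, pr$v2, pr$v3)  # 0.5 0.7 0.9
#' @export
make_speed_profile <- function(cohort = c("clinical", "healthy"), cws, center,
                               a1_sign = 1, seed = NULL, duration_scale = 1) {
  cohort <- match.arg(cohort)
  assert_that(a1_sign %in% c(-1, 1), "a1_sign must be +1 or -1")
  assert_that(duration_scale > 0, "duration_scale must be > 0")
  if (cohort == "clinical") {
    grid <- seq(70, 130, by = 10)
    assert_that(any(abs(center - grid) < 1e-9),
                "clinical bout center must be one of %s %%CWS",
                paste(grid, collapse = ", "))
    v2 <- center / 100 * cws
    dv <- 0.20 * cws
    t1 <- 120 * duration_scale; t4 <- 240 * duration_scale
    hold <- 15 * duration_scale
  } else {
    grid <- seq(0.6, 1.4, by = 0.2)
    assert_that(any(abs(center - grid) < 1e-9),
                "healthy bout center must be one of %s m/s",
                paste(grid, collapse = ", "))
    v2 <- center
    dv <- 0.2
    t1 <- 180 * duration_scale; t4 <- 600 * duration_scale
    hold <- 60 * duration_scale
  }
  v1 <- v2 - dv; v3 <- v2 + dv
  ramp <- 30  # seconds for a v2 -> v1 (or v2 -> v3) change; slope dv/30
  # build piecewise-linear knots: constant, then sweep between extremes
  tt <- c(0, t1); vv <- c(v2, v2)
  target <- if (a1_sign > 0) v3 else v1
  t <- t1
  repeat {
    cur <- vv[length(vv)]
    ramp_t <- abs(target - cur) / dv * ramp
    if (t + ramp_t >= t4) {  # truncate mid-ramp
      frac <- (t4 - t) / ramp_t
      tt <- c(tt, t4); vv <- c(vv, cur + (target - cur) * frac)
      break
    }
    t <- t + ramp_t
    tt <- c(tt, t); vv <- c(vv, target)
    if (t + hold >= t4) {
      tt <- c(tt, t4); vv <- c(vv, target)
      break
    }
    t <- t + hold
    tt <- c(tt, t); vv <- c(vv, target)
    target <- if (abs(target - v3) < 1e-12) v1 else v3
  }
  samples_t <- seq(0, t4, by = 0.1)
  prof <- structure(list(cohort = cohort, cws = cws, center = center,
                         v1 = v1, v2 = v2, v3 = v3,
                         t1 = t1, t4 = t4, a1_sign = a1_sign, hold = hold,
                         duration_scale = duration_scale,
                         knots = data.frame(t = tt, v = vv)),
                    class = "treadmill_profile")
  prof$samples <- data.frame(t = samples_t, v = speed_at(prof, samples_t))
  prof
}

#' Commanded speed at arbitrary times
#'
#' @param profile a [make_speed_profile()] object.
#' @param t numeric vector of times (s).
#' @return speeds in m/s (flat extrapolation outside the bout).
#' @export
speed_at <- function(profile, t) {
  interp1_flat(profile$knots$t, profile$knots$v, t)
}
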