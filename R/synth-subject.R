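#' Virtual subject specification
#'
#' Describes one virtual walker for the gait-session simulator. Clinical
#' (hemiparetic) subjects have a paretic side and an impairment level that
#' scales down the propulsion generated by the paretic leg; healthy subjects
#' have neither.
#'
#' @param subject_id character label.
#' @param bodyweight body mass in kg (> 0).
#' @param cws comfortable treadmill walking speed in m/s (> 0).
#' @param cohort `"clinical"` or `"healthy"`.
#' @param paretic_side `"left"`, `"right"` or `"none"` (healthy).
#' @param impairment scalar in \[0, 1\]: fraction by which paretic-side
#'   propulsion amplitude is reduced (0 = symmetric gait).
#' @param noise_levels optional list overriding entries of
#'   [default_noise_levels()].
#' @return An object of class `subject_spec`.
#' @examples
#' subject_spec("S1", 85, 0.8, "clinical", "left", 0.35)
#' @export
subject_spec <- function(subject_id, bodyweight, cws,
                         cohort = c("clinical", "healthy"),
                         paretic_side = c("none", "left", "right"),
                         impairment = 0,
                         noise_levels = list()) {
  cohort <- match.arg(cohort)
  paretic_side <- match.arg(paretic_side)
  assert_that(is.numeric(bodyweight) && bodyweight > 0, "bodyweight must be > 0")
  assert_that(is.numeric(cws) && cws > 0, "cws must be > 0")
  assert_that(impairment >= 0 && impairment <= 1, "impairment must lie in [0, 1]")
  if (cohort == "healthy") {
    assert_that(paretic_side == "none" && impairment == 0,
                "healthy subjects must have paretic_side = 'none' and impairment = 0")
  } else {
    assert_that(paretic_side != "none", "clinical subjects need a paretic side")
  }
  nl <- utils::modifyList(default_noise_levels(), noise_levels)
  structure(list(subject_id = subject_id, bodyweight = bodyweight, cws = cws,
                 cohort = cohort, paretic_side = paretic_side,
                 impairment = impairment, noise_levels = nl),
            class = "subject_spec")
}

#' Default simulator noise levels
#'
#' Per-modality noise parameters used by the session simulator. Values are
#' chosen to resemble bench characteristics of commercial hardware: a quiet
#' force plate, insole sensels with a persistent per-cell offset plus white
#' noise, and consumer-grade IMU channels.
#'
#' @return Named list: `fp` force-plate noise std (%BW, stance only);
#'   `insole` sensel white-noise std (arbitrary pressure units);
#'   `insole_offset` range (lo, hi) of the constant per-sensel offset;
#'   `imu_acc` (m/s^2), `imu_gyr` (deg/s), `imu_ang` (deg) channel noise
#'   stds; `stride_cv` coefficient of variation of the stride period.
#' @export
default_noise_levels <- function() {
  list(fp = 0.2, insole = 0.2, insole_offset = c(1, 3),
       imu_acc = 0.3, imu_gyr = 1.5, imu_ang = 0.3,
       stride_cv = 0.02)
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec> %s: %s, %.1f kg, CWS %.2f m/s",
              x$subject_id, x$cohort, x$bodyweight, x$cws))
  if (x$cohort == "clinical") {
    cat(sprintf(", paretic %s (impairment %.2f)", x$paretic_side, x$impairment))
  }
  cat("\n")
  invisible(x)
}
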