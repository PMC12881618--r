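#' Build a stepped laser PRF schedule
#'
#' A schedule is an ordered set of non-overlapping time intervals, each with a
#' constant pulse repetition frequency (PRF); the laser is off in gaps.
#'
#' @param t_start,t_end Interval bounds (s), vectors of equal length.
#' @param prf PRF per interval (Hz).
#' @return A tibble of class `prf_schedule` with columns `t_start`, `t_end`,
#'   `prf`, ordered by `t_start`.
#' @export
prf_schedule <- function(t_start, t_end, prf) {
  if (length(t_start) != length(t_end) || length(t_start) != length(prf)) {
    abort("`t_start`, `t_end`, `prf` must have equal length.",
          class = "spiralpam_invalid_spec")
  }
  if (length(t_start)) {
    if (any(t_end <= t_start) || any(prf <= 0)) {
      abort("Each step needs t_start < t_end and prf > 0.",
            class = "spiralpam_invalid_spec")
    }
    o <- order(t_start)
    t_start <- t_start[o]; t_end <- t_end[o]; prf <- prf[o]
    if (any(t_start[-1] < t_end[-length(t_end)])) {
      abort("Schedule steps must not overlap.",
            class = "spiralpam_invalid_spec")
    }
  }
  out <- tibble::tibble(t_start = t_start, t_end = t_end, prf = prf)
  class(out) <- c("prf_schedule", class(out))
  out
}

#' The stepped PRF schedule used for density-equalized spiral scanning
#'
#' Five steps that ramp the laser rate with the spiral radius: 20 kHz for
#' 0.05-0.1 s, 100 kHz for 0.1-0.2 s, 200 kHz for 0.2-0.3 s, 250 kHz for
#' 0.3-0.4 s and 500 kHz for 0.4-1 s; the laser is off before 0.05 s, while
#' the beam still dwells near the scan center. Generating the full pulse train
#' yields 356,000 triggers.
#'
#' @return A [prf_schedule()] with five steps.
#' @export
stepped_prf_schedule <- function() {
  prf_schedule(
    t_start = c(0.05, 0.1, 0.2, 0.3, 0.4),
    t_end   = c(0.1, 0.2, 0.3, 0.4, 1.0),
    prf     = c(20e3, 100e3, 200e3, 250e3, 500e3)
  )
}

#' Laser fire times of a PRF schedule
#'
#' Within each step, pulses are uniformly spaced at `1 / prf` starting at the
#' step's `t_start`; the pulse count per step is `floor(duration * prf)`
#' (evaluated with a 1e-9 guard against binary floating-point droop so that,
#' e.g., a 0.6 s step at 500 kHz yields exactly 300,000 pulses).
#'
#' @param schedule A [prf_schedule()].
#' @return Strictly increasing numeric vector of fire times (s).
#' @export
fire_times <- function(schedule) {
  if (!nrow(schedule)) return(numeric(0))
  unlist(purrr::pmap(schedule, function(t_start, t_end, prf) {
    n <- floor((t_end - t_start) * prf + 1e-9)
    if (n <= 0) return(numeric(0))
    t_start + (seq_len(n) - 1) / prf
  }))
}

#' Pair laser fire times with beam positions
#'
#' Looks up the beam position at every fire time by linear interpolation of a
#' sampled trajectory.
#'
#' @param trajectory A `pam_trajectory` (see [simulate_trajectory()]).
#' @param schedule A [prf_schedule()].
#' @return A tibble of class `trigger_train` with columns `time`, `x`, `y`.
#' @export
trigger_train <- function(trajectory, schedule) {
  ft <- fire_times(schedule)
  if (length(ft) &&
      (min(ft) < min(trajectory$time) || max(ft) > max(trajectory$time))) {
    abort("Fire times fall outside the trajectory's time span.",
          class = "spiralpam_range_error")
  }
  out <- tibble::tibble(
    time = ft,
    x = approx(trajectory$time, trajectory$x, ft)$y,
    y = approx(trajectory$time, trajectory$y, ft)$y
  )
  class(out) <- c("trigger_train", class(out))
  out
}
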