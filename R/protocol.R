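#' Define a spiral scan protocol
#'
#' One volumetric acquisition cycle consists of an imaging phase in which the
#' drive amplitude ramps up and the fiber tip spirals outward, an active-
#' braking phase in which a phase-opposed drive decelerates the fiber, and a
#' free-decay phase with no drive. The defaults reproduce the 333 Hz, 1 s +
#' 0.2 s + 0.3 s cycle of the handheld probe, i.e. one volume every 1.5 s over
#' a 2.6 mm diameter field of view.
#'
#' @param scan_frequency Spiral (drive) frequency in Hz.
#' @param imaging_duration,braking_duration,decay_duration Phase durations (s).
#' @param max_radius Outer spiral radius (m); the field of view diameter is
#'   `2 * max_radius`.
#' @param ramp_shape Amplitude ramp during imaging; only `"linear"` (0 to full
#'   amplitude across the imaging phase) is implemented, which yields uniform
#'   radial pitch between spiral turns.
#' @param decay_time_constant Exponential envelope time constant of the free
#'   decay (s). Defaults to `decay_duration / 3` so the residual amplitude at
#'   the end of the cycle is below 5 % of where the decay started.
#'
#' @return A one-row tibble of class `scan_protocol`.
#' @export
scan_protocol <- function(scan_frequency = 333,
                          imaging_duration = 1,
                          braking_duration = 0.2,
                          decay_duration = 0.3,
                          max_radius = 1.3e-3,
                          ramp_shape = c("linear"),
                          decay_time_constant = if (decay_duration > 0)
                            decay_duration / 3 else 0.1) {
  ramp_shape <- match.arg(ramp_shape)
  stopifnot_positive(scan_frequency = scan_frequency, max_radius = max_radius,
                     decay_time_constant = decay_time_constant)
  durs <- c(imaging_duration, braking_duration, decay_duration)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    abort("Phase durations must be finite and >= 0.",
          class = "spiralpam_invalid_spec")
  }
  out <- tibble::tibble(
    scan_frequency = scan_frequency,
    imaging_duration = imaging_duration,
    braking_duration = braking_duration,
    decay_duration = decay_duration,
    max_radius = max_radius,
    ramp_shape = ramp_shape,
    decay_time_constant = decay_time_constant
  )
  class(out) <- c("scan_protocol", class(out))
  out
}

#' Total cycle duration of a scan protocol
#'
#' @param protocol A [scan_protocol()].
#' @return Imaging + braking + decay duration in seconds.
#' @export
cycle_duration <- function(protocol) {
  protocol$imaging_duration + protocol$braking_duration +
    protocol$decay_duration
}

phase_of <- function(protocol, times) {
  t_i <- protocol$imaging_duration
  t_b <- t_i + protocol$braking_duration
  phase <- ifelse(times <= t_i, "imaging",
                  ifelse(times <= t_b, "braking", "decay"))
  factor(phase, levels = c("imaging", "braking", "decay"))
}

# analytic two-channel drive as a function of time; x = sin, y = cos so that
# y leads x by a quarter period (counter-clockwise spiral, right-handed frame)
drive_fun <- function(protocol) {
  f <- protocol$scan_frequency
  t_i <- protocol$imaging_duration
  t_b <- t_i + protocol$braking_duration
  force(f); force(t_i); force(t_b)
  function(times) {
    amp <- numeric(length(times))
    sgn <- rep(1, length(times))
    img <- times <= t_i
    amp[img] <- if (t_i > 0) times[img] / t_i else 1
    brk <- times > t_i & times <= t_b
    if (any(brk)) {
      amp[brk] <- 1 - (times[brk] - t_i) / (t_b - t_i)
      sgn[brk] <- -1 # 180 degrees phase-opposed braking drive
    }
    ph <- 2 * pi * f * times
    list(x = sgn * amp * sin(ph), y = sgn * amp * cos(ph))
  }
}

#' Two-channel drive waveform for the piezo tube
#'
#' During imaging the +/-XY electrode channels are sinusoids at the scan
#' frequency with a 90 degree relative phase (y leads x) and a linear 0-to-1
#' amplitude ramp; during braking the same sinusoids are applied 180 degrees
#' phase-opposed with amplitude decaying linearly to zero; during free decay
#' the output is zero and the fiber dampens naturally.
#'
#' @param protocol A [scan_protocol()].
#' @param times Time stamps (s) within one full cycle.
#' @return A tibble with columns `time`, `x`, `y` (normalized volts), `phase`.
#' @export
drive_waveform <- function(protocol, times) {
  total <- cycle_duration(protocol)
  if (any(times < 0 | times > total)) {
    abort("`times` must lie within one full scan cycle.",
          class = "spiralpam_range_error")
  }
  d <- drive_fun(protocol)(times)
  tibble::tibble(time = times, x = d$x, y = d$y,
                 phase = phase_of(protocol, times))
}

#' Simulate the fiber-tip trajectory over one scan cycle
#'
#' The kinematic model is the ideal spiral: radius `max_radius * ramp(t)` at
#' angle `2 pi f t` during imaging, a linear inward spiral during braking, and
#' an exponentially damped oscillation during free decay. The dynamic model
#' integrates a driven damped harmonic oscillator per axis (natural frequency
#' from [resonant_frequency()], quality factor `Q = pi * f * tau` tied to the
#' free-decay envelope time constant `tau`) and rescales displacement so the
#' radius at the end of the imaging phase equals `max_radius` exactly.
#'
#' @param protocol A [scan_protocol()].
#' @param spec A [cantilever_spec()]; required for the dynamic model.
#' @param sample_rate Output sampling rate (Hz); must be at least ten times
#'   the scan frequency. The default 500 kHz matches the maximum laser pulse
#'   repetition frequency so trigger positions never need extrapolation.
#' @param model `"kinematic"` or `"dynamic"`.
#' @return A tibble of class `pam_trajectory` with columns `time`, `x`, `y`
#'   (m, probe frame, origin at scan center), `phase`.
#' @export
simulate_trajectory <- function(protocol, spec = NULL, sample_rate = 5e5,
                                model = c("kinematic", "dynamic")) {
  model <- match.arg(model)
  f <- protocol$scan_frequency
  if (sample_rate < 10 * f) {
    abort("`sample_rate` must be at least 10x the scan frequency.",
          class = "spiralpam_sampling_error")
  }
  total <- cycle_duration(protocol)
  times <- seq(0, total, by = 1 / sample_rate)
  if (model == "kinematic") {
    pos <- kinematic_positions(protocol, times)
  } else {
    if (is.null(spec)) {
      abort("The dynamic model needs a `cantilever_spec`.",
            class = "spiralpam_invalid_spec")
    }
    pos <- dynamic_positions(protocol, spec, times)
  }
  out <- tibble::tibble(time = times, x = pos$x, y = pos$y,
                        phase = phase_of(protocol, times))
  attr(out, "protocol") <- protocol
  if (!is.null(pos$scale)) attr(out, "dynamic_scale") <- pos$scale
  attr(out, "model") <- model
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("pam_trajectory", class(out))
  out
}

kinematic_positions <- function(protocol, times) {
  f <- protocol$scan_frequency
  r_max <- protocol$max_radius
  t_i <- protocol$imaging_duration
  t_b <- protocol$braking_duration
  tau <- protocol$decay_time_constant
  amp <- numeric(length(times))
  img <- times <= t_i
  amp[img] <- if (t_i > 0) r_max * times[img] / t_i else r_max
  brk <- times > t_i & times <= t_i + t_b
  amp[brk] <- r_max * (1 - (times[brk] - t_i) / t_b)
  r_decay0 <- if (t_b > 0) 0 else r_max
  dec <- times > t_i + t_b
  amp[dec] <- r_decay0 * exp(-(times[dec] - t_i - t_b) / tau)
  ph <- 2 * pi * f * times
  list(x = amp * sin(ph), y = amp * cos(ph))
}

dynamic_positions <- function(protocol, spec, times) {
  f <- protocol$scan_frequency
  w0 <- 2 * pi * resonant_frequency(spec)
  q <- pi * f * protocol$decay_time_constant
  drv <- drive_fun(protocol)
  # steady-state amplitude of x'' + (w0/Q) x' + w0^2 x = g sin(wt)
  w <- 2 * pi * f
  gain <- protocol$max_radius *
    sqrt((w0^2 - w^2)^2 + (w0 * w / q)^2)
  rhs <- function(t, state, parms) {
    d <- drv(t)
    list(c(state[2], gain * d$x - (w0 / q) * state[2] - w0^2 * state[1],
           state[4], gain * d$y - (w0 / q) * state[4] - w0^2 * state[3]))
  }
  sol <- deSolve::ode(y = c(x = 0, vx = 0, y = 0, vy = 0), times = times,
                      func = rhs, parms = NULL, rtol = 1e-8, atol = 1e-12)
  x <- sol[, "x"]; y <- sol[, "y"]
  # normalize so the imaging phase ends exactly at max_radius
  t_i <- protocol$imaging_duration
  last <- times >= t_i - 1 / f & times <= t_i
  r_end <- max(sqrt(x[last]^2 + y[last]^2))
  s <- protocol$max_radius / r_end
  list(x = s * x, y = s * y, scale = s)
}

#' @export
autoplot.pam_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$x * 1e3, y = .data$y * 1e3,
                     colour = .data$phase)) +
    geom_path(linewidth = 0.2) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", colour = "phase") +
    theme_minimal()
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `pam_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
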