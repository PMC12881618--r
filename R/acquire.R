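#' Acquisition settings
#'
#' @param sampling_rate Digitizer sampling rate (Hz); the system digitizes at
#'   250 MHz.
#' @param speed_of_sound Acoustic speed (m/s) used for the one-way
#'   depth-to-time mapping `t = z / c` (photoacoustic reception).
#' @param record_length Samples per A-scan.
#' @param focal_spot_sigma Lateral Gaussian beam radius (m, standard
#'   deviation); depth-independent.
#' @param noise_sigma Additive white Gaussian noise standard deviation
#'   (relative units).
#' @param seed Integer seed for the noise stream.
#' @return A one-row tibble of class `acquisition_settings`.
#' @export
acquisition_settings <- function(sampling_rate = 250e6,
                                 speed_of_sound = 1500,
                                 record_length = 512L,
                                 focal_spot_sigma = 3e-6,
                                 noise_sigma = 0,
                                 seed = 1L) {
  stopifnot_positive(sampling_rate = sampling_rate,
                     speed_of_sound = speed_of_sound,
                     record_length = record_length,
                     focal_spot_sigma = focal_spot_sigma)
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "spiralpam_invalid_spec")
  }
  out <- tibble::tibble(
    sampling_rate = sampling_rate, speed_of_sound = speed_of_sound,
    record_length = as.integer(record_length),
    focal_spot_sigma = focal_spot_sigma, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  )
  class(out) <- c("acquisition_settings", class(out))
  out
}

# noiseless initial-pressure record for one beam position; noise is added by
# the caller so that acquire() owns a single seeded stream
ascan_core <- function(phantom, beam_xy, impulse, settings) {
  d <- dim(phantom)
  vs <- attr(phantom, "voxel_size")
  org <- attr(phantom, "origin")
  xs <- org[1] + (0:(d[1] - 1)) * vs[1]
  ys <- org[2] + (0:(d[2] - 1)) * vs[2]
  if (beam_xy[1] < xs[1] || beam_xy[1] > xs[d[1]] ||
      beam_xy[2] < ys[1] || beam_xy[2] > ys[d[2]]) {
    abort("`beam_xy` lies outside the phantom's lateral extent.",
          class = "spiralpam_range_error")
  }
  s2 <- 2 * settings$focal_spot_sigma^2
  wx <- exp(-(xs - beam_xy[1])^2 / s2)
  wy <- exp(-(ys - beam_xy[2])^2 / s2)
  # separable lateral Gaussian: p(z) = wx' P(,,z) wy
  m <- matrix(unclass(phantom), d[1], d[2] * d[3])
  pz <- matrix(crossprod(wx, m), d[2], d[3]) # (ny x nz)
  pz <- as.vector(crossprod(wy, pz))
  # one-way flight: depth sample k arrives at t = z_k / c
  fs <- settings$sampling_rate
  zc <- org[3] + (0:(d[3] - 1)) * vs[3]
  idx <- round_half_away(zc / settings$speed_of_sound * fs) + 1
  n <- settings$record_length
  if (any(idx > n & pz > 0)) {
    warn("Record too short to hold the deepest absorber; truncating.",
         class = "spiralpam_truncation_warning")
  }
  keep <- idx >= 1 & idx <= n
  p_t <- numeric(n)
  if (any(keep)) {
    acc <- tapply(pz[keep], idx[keep], sum)
    p_t[as.integer(names(acc))] <- acc
  }
  if (!is.null(impulse) && length(impulse) > 1) {
    conv <- stats::convolve(p_t, rev(impulse), type = "open")
    p_t <- conv[seq_len(n)]
  } else if (!is.null(impulse)) {
    p_t <- p_t * impulse[1]
  }
  p_t
}

#' Synthesize one A-scan
#'
#' Forward model: the initial-pressure depth line is the absorption volume
#' weighted by a lateral Gaussian centered on the beam axis; depth maps to
#' time by one-way flight `t = z / c`; the line is convolved with the
#' transducer's time-domain two-way impulse response, sampled at the
#' digitizer rate, and white Gaussian noise is added.
#'
#' @param phantom A [pam_phantom()].
#' @param beam_xy Planar beam position `(x, y)` (m), within the phantom.
#' @param impulse Time-domain transducer waveform sampled at
#'   `settings$sampling_rate`; `NULL` or length-1 means delta acoustics.
#' @param settings [acquisition_settings()].
#' @return A tibble of class `pam_ascan` with columns `time` and `amplitude`.
#' @export
simulate_ascan <- function(phantom, beam_xy, impulse = NULL,
                           settings = acquisition_settings()) {
  p_t <- ascan_core(phantom, beam_xy, impulse, settings)
  if (settings$noise_sigma > 0) {
    p_t <- with_fixed_seed(settings$seed,
                           p_t + rnorm(length(p_t), 0, settings$noise_sigma))
  }
  out <- tibble::tibble(
    time = (seq_along(p_t) - 1) / settings$sampling_rate,
    amplitude = p_t
  )
  class(out) <- c("pam_ascan", class(out))
  out
}

#' Acquire a sample set along a trajectory
#'
#' Evaluates the A-scan forward model at every laser fire position of the
#' trigger train. Deterministic for a fixed `settings$seed`.
#'
#' @param trajectory A `pam_trajectory`.
#' @param schedule A [prf_schedule()].
#' @param phantom A [pam_phantom()].
#' @param impulse Transducer impulse waveform (see [simulate_ascan()]).
#' @param settings [acquisition_settings()].
#' @return A `pam_sample_set`: list with `positions` (tibble `time`, `x`,
#'   `y`), `ascans` (matrix, shots x record_length) and `settings`.
#' @export
acquire <- function(trajectory, schedule, phantom, impulse = NULL,
                    settings = acquisition_settings()) {
  train <- trigger_train(trajectory, schedule)
  acquire_at(train, phantom, impulse, settings)
}

#' @rdname acquire
#' @param positions A tibble with columns `x`, `y` (m) — e.g. a
#'   `trigger_train`, or an explicit raster of beam positions.
#' @export
acquire_at <- function(positions, phantom, impulse = NULL,
                       settings = acquisition_settings()) {
  positions <- tibble::as_tibble(positions)
  if (!"time" %in% names(positions)) {
    positions$time <- seq_len(nrow(positions)) - 1
  }
  n <- nrow(positions)
  ascans <- matrix(0, n, settings$record_length)
  for (i in seq_len(n)) {
    ascans[i, ] <- ascan_core(phantom,
                              c(positions$x[i], positions$y[i]),
                              impulse, settings)
  }
  if (settings$noise_sigma > 0 && n > 0) {
    ascans <- with_fixed_seed(
      settings$seed,
      ascans + matrix(rnorm(length(ascans), 0, settings$noise_sigma),
                      nrow(ascans)))
  }
  structure(
    list(positions = positions[, c("time", "x", "y")], ascans = ascans,
         settings = settings),
    class = "pam_sample_set"
  )
}

#' @export
print.pam_sample_set <- function(x, ...) {
  cat(sprintf("<pam_sample_set> %d A-scans x %d samples at %.0f MHz\n",
              nrow(x$ascans), ncol(x$ascans),
              x$settings$sampling_rate / 1e6))
  invisible(x)
}

#' Persist / load a sample set
#'
#' Writes the A-scans as a flat binary array of doubles alongside a CSV of
#' positions and a JSON of settings.
#'
#' @param samples A `pam_sample_set`.
#' @param stem Output path stem; writes `<stem>.bin`, `<stem>.csv`,
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_sample_set <- function(samples, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.vector(t(samples$ascans)), con)
  close(con)
  write.csv(as.data.frame(samples$positions), paste0(stem, ".csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(samples$settings), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(stem) {
  settings <- tibble::as_tibble(
    jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE))
  class(settings) <- c("acquisition_settings", class(settings))
  positions <- tibble::as_tibble(
    utils::read.csv(paste0(stem, ".csv")))
  con <- file(paste0(stem, ".bin"), "rb")
  raw <- readBin(con, "double", n = nrow(positions) * settings$record_length)
  close(con)
  structure(
    list(positions = positions,
         ascans = matrix(raw, nrow(positions), settings$record_length,
                         byrow = TRUE),
         settings = settings),
    class = "pam_sample_set"
  )
}
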