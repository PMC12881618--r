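#' Per-pixel laser-shot density map
#'
#' Interpolates the beam position at every laser fire time, bins the shot
#' positions onto the image grid with the shared [position_to_pixel()] rule,
#' and accumulates counts. The returned object also records which pixels the
#' beam traversed while the laser was on (the trajectory itself, binned over
#' the union of schedule intervals), which is the region over which shot
#' uniformity is judged: pixels inside the unscanned central disc receive no
#' pulses by construction and are excluded.
#'
#' @param trajectory A `pam_trajectory` covering the schedule's time span.
#' @param schedule A [prf_schedule()].
#' @param grid_size Image width/height in pixels (default 512).
#' @param fov_diameter Field-of-view diameter (m); defaults to twice the
#'   trajectory protocol's `max_radius`.
#' @return An object of class `pam_density_map`: a list with integer matrix
#'   `counts` (`grid_size` x `grid_size`, x indexing rows), logical matrix
#'   `visited`, `grid_size`, `fov_diameter` and `n_triggers`.
#' @export
density_map <- function(trajectory, schedule, grid_size = 512,
                        fov_diameter = NULL) {
  if (is.null(fov_diameter)) {
    proto <- attr(trajectory, "protocol")
    if (is.null(proto)) {
      abort("Supply `fov_diameter` when the trajectory has no protocol.",
            class = "spiralpam_invalid_spec")
    }
    fov_diameter <- 2 * proto$max_radius
  }
  train <- trigger_train(trajectory, schedule)
  counts <- matrix(0L, grid_size, grid_size)
  if (nrow(train)) {
    px <- position_to_pixel(train$x, train$y, grid_size, fov_diameter)
    px <- px[px$inside, ]
    idx <- px$ix + grid_size * px$iy + 1L
    tab <- tabulate(idx, nbins = grid_size * grid_size)
    counts <- matrix(as.integer(tab), grid_size, grid_size)
  }
  on <- rep(FALSE, nrow(trajectory))
  for (k in seq_len(nrow(schedule))) {
    on <- on | (trajectory$time >= schedule$t_start[k] &
                  trajectory$time <= schedule$t_end[k])
  }
  visited <- matrix(FALSE, grid_size, grid_size)
  if (any(on)) {
    vp <- position_to_pixel(trajectory$x[on], trajectory$y[on],
                            grid_size, fov_diameter)
    vp <- vp[vp$inside, ]
    visited[unique(vp$ix + grid_size * vp$iy + 1L)] <- TRUE
  }
  structure(
    list(counts = counts, visited = visited, grid_size = grid_size,
         fov_diameter = fov_diameter, n_triggers = nrow(train)),
    class = "pam_density_map"
  )
}

#' @export
print.pam_density_map <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<pam_density_map> %d x %d px over %.2f mm FOV: %d shots, %d-%d shots/visited px, fill %.3f\n",
    x$grid_size, x$grid_size, x$fov_diameter * 1e3, s$n_triggers,
    s$min_visited, s$max_visited, s$fill_factor))
  invisible(x)
}

#' @export
glance.pam_density_map <- function(x, ...) {
  vc <- x$counts[x$visited]
  tibble::tibble(
    n_triggers = x$n_triggers,
    n_visited = sum(x$visited),
    min_visited = if (length(vc)) min(vc) else NA_integer_,
    max_visited = if (length(vc)) max(vc) else NA_integer_,
    mean_visited = if (length(vc)) mean(vc) else NA_real_,
    fill_factor = fill_factor(x)
  )
}

#' @export
tidy.pam_density_map <- function(x, ...) {
  g <- x$grid_size
  tibble::tibble(
    ix = rep(0:(g - 1), times = g),
    iy = rep(0:(g - 1), each = g),
    count = as.vector(x$counts),
    visited = as.vector(x$visited)
  )
}

#' Fill factor of a density map
#'
#' Fraction of pixels in a reference region receiving at least one laser shot.
#'
#' @param map A [density_map()].
#' @param region `"fov"` (default): all pixels whose centers lie inside the
#'   field-of-view disc; `"visited"`: only pixels the beam traversed during
#'   laser-on time.
#' @return A fraction in \[0, 1\].
#' @export
fill_factor <- function(map, region = c("fov", "visited")) {
  region <- match.arg(region)
  sel <- switch(region,
                fov = fov_disc_mask(map$grid_size, map$fov_diameter),
                visited = map$visited)
  if (!any(sel)) return(0)
  mean(map$counts[sel] >= 1)
}

#' Fill factor versus scan frequency at fixed PRF
#'
#' Re-simulates the spiral at each candidate scan frequency with all other
#' protocol settings held fixed and a single constant-PRF laser-on interval
#' spanning the imaging phase, and reports the field-of-view fill factor.
#' Reproduces the aliasing analysis: the fill factor rises with frequency
#' until trigger/trajectory phase locking starts leaving systematic gaps.
#'
#' @param fixed_prf Constant laser PRF (Hz).
#' @param frequencies Scan frequencies to test (Hz).
#' @param protocol Template [scan_protocol()]; its `scan_frequency` is
#'   replaced per candidate.
#' @param grid_size Image grid (default 256 to keep sweeps fast).
#' @param sample_rate Trajectory sampling rate (Hz).
#' @return A tibble with columns `frequency` and `fill_factor`.
#' @export
frequency_sweep <- function(fixed_prf, frequencies,
                            protocol = scan_protocol(),
                            grid_size = 256, sample_rate = 5e5) {
  purrr::map_dfr(frequencies, function(f) {
    p <- protocol
    p$scan_frequency <- f
    traj <- simulate_trajectory(p, sample_rate = sample_rate)
    sched <- prf_schedule(0, p$imaging_duration, fixed_prf)
    m <- density_map(traj, sched, grid_size = grid_size)
    tibble::tibble(frequency = f, fill_factor = fill_factor(m))
  })
}

#' @export
autoplot.pam_density_map <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$ix, y = .data$iy, fill = .data$count)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", fill = "shots") +
    theme_minimal()
}

#' Write a density map as 16-bit TIFF plus CSV summary
#'
#' @param map A [density_map()].
#' @param tiff_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_density_map <- function(map, tiff_path = NULL, csv_path = NULL) {
  if (!is.null(tiff_path)) {
    EBImage::writeImage(map$counts / 65535, tiff_path, type = "tiff",
                        bits.per.sample = 16L)
  }
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(glance(map)), csv_path, row.names = FALSE)
  }
  invisible(list(tiff = tiff_path, csv = csv_path))
}
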