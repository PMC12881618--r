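#' Hilbert envelope of a signal
#'
#' Magnitude of the analytic signal, computed by zeroing the negative
#' frequencies of the FFT.
#'
#' @param ascan A numeric vector, or a `pam_ascan` tibble (its `amplitude`
#'   column is used).
#' @return Non-negative numeric vector of the same length.
#' @export
envelope <- function(ascan) {
  x <- if (is.data.frame(ascan)) ascan$amplitude else as.numeric(ascan)
  as.vector(envelope_mat(matrix(x, ncol = 1)))
}

# column-wise analytic-signal envelope
envelope_mat <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- mvfft(mvfft(m) * h, inverse = TRUE) / n
  Mod(a)
}

#' Reconstruct a volume from scattered samples (three-case rule)
#'
#' Shot positions are snapped to pixels with the shared
#' [position_to_pixel()] rule, then: a pixel holding exactly one sample takes
#' that A-scan directly; a pixel holding several takes their element-wise
#' average; an empty pixel inside the field-of-view disc takes an inverse-
#' distance-weighted combination of the traces of its `k_neighbors` nearest
#' directly-hit pixels (whole traces, identical weights at every depth
#' sample). Pixels outside the disc stay zero.
#'
#' @param samples A `pam_sample_set`.
#' @param grid_size Output grid width/height (pixels).
#' @param fov_diameter Field-of-view diameter (m).
#' @param k_neighbors Neighbors used for the empty-pixel interpolation.
#' @param idw_power Inverse-distance weight exponent (weights `d^-power`).
#' @return A `pam_volume`: list with `data` (grid_size x grid_size x
#'   record_length array), `pixel_size`, `depth_sample_size` (`c / fs`,
#'   one-way), `fov_diameter`, `fill_mask` (directly-hit pixels) and the
#'   acquisition `settings`.
#' @export
grid_assign <- function(samples, grid_size, fov_diameter,
                        k_neighbors = 4, idw_power = 1) {
  if (!nrow(samples$positions)) {
    abort("Empty sample set.", class = "spiralpam_reconstruction_error")
  }
  px <- position_to_pixel(samples$positions$x, samples$positions$y,
                          grid_size, fov_diameter)
  keep <- px$inside
  if (!any(keep)) {
    abort("No sample falls on the grid.",
          class = "spiralpam_reconstruction_error")
  }
  idx <- px$ix[keep] + grid_size * px$iy[keep] + 1L
  traces <- samples$ascans[keep, , drop = FALSE]
  lev <- sort(unique(idx))
  fac <- factor(idx, levels = lev)
  sums <- rowsum(traces, fac)
  counts <- tabulate(fac, nbins = length(lev))
  filled_idx <- lev
  means <- sums / counts

  npix <- grid_size * grid_size
  record <- ncol(traces)
  flat <- matrix(0, npix, record)
  flat[filled_idx, ] <- means
  fill_mask <- matrix(FALSE, grid_size, grid_size)
  fill_mask[filled_idx] <- TRUE

  disc <- fov_disc_mask(grid_size, fov_diameter)
  empty_idx <- which(disc & !fill_mask)
  k_neighbors <- min(k_neighbors, length(filled_idx))
  if (length(empty_idx) && k_neighbors > 0) {
    nb <- grid_knn(fill_mask, empty_idx, k_neighbors)
    w <- 1 / nb$dist^idw_power
    w <- w / rowSums(w)
    for (j in seq_len(k_neighbors)) {
      flat[empty_idx, ] <- flat[empty_idx, ] +
        w[, j] * flat[nb$idx[, j], , drop = FALSE]
    }
  }
  structure(
    list(data = array(flat, c(grid_size, grid_size, record)),
         pixel_size = fov_diameter / (grid_size - 1),
         depth_sample_size = samples$settings$speed_of_sound /
           samples$settings$sampling_rate,
         fov_diameter = fov_diameter,
         fill_mask = fill_mask,
         settings = samples$settings),
    class = "pam_volume"
  )
}

# exact k nearest TRUE pixels of `mask` for each linear index in `query`:
# offsets are visited in non-decreasing Euclidean distance, so the first k
# hits per query are the k nearest
grid_knn <- function(mask, query, k) {
  g <- nrow(mask)
  nc <- ncol(mask)
  qx <- (query - 1L) %% g
  qy <- (query - 1L) %/% g
  n <- length(query)
  nb_idx <- matrix(NA_integer_, n, k)
  nb_dist <- matrix(NA_real_, n, k)
  found <- integer(n)
  r <- 4L
  repeat {
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off$d2 <- off$dx^2 + off$dy^2
    off <- off[off$d2 > 0 & off$d2 <= r^2, ]
    off <- off[order(off$d2), ]
    nb_idx[] <- NA_integer_; nb_dist[] <- NA_real_; found[] <- 0L
    open <- seq_len(n)
    for (j in seq_len(nrow(off))) {
      if (!length(open)) break
      nx <- qx[open] + off$dx[j]
      ny <- qy[open] + off$dy[j]
      ok <- nx >= 0 & nx < g & ny >= 0 & ny < nc
      lin <- rep(1L, length(nx))
      lin[ok] <- nx[ok] + g * ny[ok] + 1L
      hit <- ok & mask[lin]
      if (any(hit)) {
        rows <- open[hit]
        slot <- found[rows] + 1L
        nb_idx[cbind(rows, slot)] <- lin[hit]
        nb_dist[cbind(rows, slot)] <- sqrt(off$d2[j])
        found[rows] <- slot
        open <- open[found[open] < k]
      }
    }
    if (!length(open)) break
    if (r > 2L * (g + nc)) {
      abort("No directly-hit pixels within search range.",
            class = "spiralpam_reconstruction_error")
    }
    r <- r * 2L
  }
  list(idx = nb_idx, dist = nb_dist)
}

#' @export
print.pam_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pam_volume> %d x %d px x %d depth samples, %.0f %% directly hit\n",
              d[1], d[2], d[3], 100 * mean(x$fill_mask)))
  invisible(x)
}

new_map_image <- function(data, provenance, pixel_size, fov_diameter) {
  structure(list(data = data, provenance = provenance,
                 pixel_size = pixel_size, fov_diameter = fov_diameter),
            class = "pam_map_image")
}

#' Maximum amplitude projection (MAP)
#'
#' Per-pixel maximum of the Hilbert envelope along depth.
#'
#' @param volume A `pam_volume` from [grid_assign()], or a 3D array (then
#'   `pixel_size` may be given).
#' @param pixel_size Pixel pitch (m), for plain arrays.
#' @return A `pam_map_image` with `provenance = "map"`.
#' @export
map_projection <- function(volume, pixel_size = NULL) {
  arr <- if (inherits(volume, "pam_volume")) volume$data else volume
  if (is.null(pixel_size) && inherits(volume, "pam_volume")) {
    pixel_size <- volume$pixel_size
  }
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3])
  vals <- numeric(d[1] * d[2])
  chunk <- 4096L
  for (s in seq(1L, nrow(flat), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(flat))
    env <- envelope_mat(t(flat[s:e, , drop = FALSE]))
    vals[s:e] <- apply(env, 2, max)
  }
  new_map_image(matrix(vals, d[1], d[2]), "map", pixel_size,
                if (inherits(volume, "pam_volume")) volume$fov_diameter
                else NULL)
}

#' Depth-encoded projection
#'
#' Per-pixel depth index (0-based) of the envelope maximum; pixels whose
#' envelope maximum falls below `floor_frac` of the image-wide maximum are
#' background (`NA`).
#'
#' @param volume A `pam_volume` or 3D array.
#' @param floor_frac Amplitude floor as a fraction of the global maximum.
#' @param pixel_size Pixel pitch (m), for plain arrays.
#' @return A `pam_map_image` with `provenance = "depth"`.
#' @export
depth_encode <- function(volume, floor_frac = 0.05, pixel_size = NULL) {
  arr <- if (inherits(volume, "pam_volume")) volume$data else volume
  if (is.null(pixel_size) && inherits(volume, "pam_volume")) {
    pixel_size <- volume$pixel_size
  }
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3])
  amax <- numeric(d[1] * d[2])
  aidx <- integer(d[1] * d[2])
  chunk <- 4096L
  for (s in seq(1L, nrow(flat), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(flat))
    env <- envelope_mat(t(flat[s:e, , drop = FALSE]))
    amax[s:e] <- apply(env, 2, max)
    aidx[s:e] <- apply(env, 2, which.max) - 1L
  }
  floor_amp <- floor_frac * max(amax)
  depth <- ifelse(amax >= floor_amp & amax > 0, aidx, NA_integer_)
  new_map_image(matrix(depth, d[1], d[2]), "depth", pixel_size,
                if (inherits(volume, "pam_volume")) volume$fov_diameter
                else NULL)
}

#' @export
print.pam_map_image <- function(x, ...) {
  cat(sprintf("<pam_map_image> %s, %d x %d px\n", x$provenance,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
tidy.pam_map_image <- function(x, ...) {
  g <- dim(x$data)
  tibble::tibble(
    ix = rep(0:(g[1] - 1), times = g[2]),
    iy = rep(0:(g[2] - 1), each = g[1]),
    value = as.vector(x$data)
  )
}

#' @export
autoplot.pam_map_image <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$ix, y = .data$iy, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "black") +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)",
         fill = if (object$provenance == "map") "amplitude" else "depth") +
    theme_minimal()
}

#' Write volumes and projection images
#'
#' Volumes go to multi-page TIFF (depth pages) with a JSON sidecar; images to
#' single-page TIFF.
#'
#' @param volume A `pam_volume`.
#' @param tiff_path,json_path Output paths.
#' @return The primary path, invisibly.
#' @export
write_volume <- function(volume, tiff_path,
                         json_path = paste0(tiff_path, ".json")) {
  arr <- volume$data
  rng <- range(arr)
  scaled <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  EBImage::writeImage(scaled, tiff_path, type = "tiff",
                      bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size = volume$pixel_size,
         depth_sample_size = volume$depth_sample_size,
         fov_diameter = volume$fov_diameter,
         data_min = rng[1], data_max = rng[2]),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_volume
#' @param image A `pam_map_image`.
#' @export
write_map_image <- function(image, tiff_path) {
  m <- image$data
  m[is.na(m)] <- 0
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  EBImage::writeImage(scaled, tiff_path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(tiff_path)
}
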