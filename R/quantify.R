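as_image_matrix <- function(image) {
  if (inherits(image, "pam_map_image")) image$data else as.matrix(image)
}

#' Lateral resolution from an edge target
#'
#' Averages the image profile perpendicular to a straight edge, fits a
#' scaled-and-offset error-function edge spread function (ESF)
#' `a + b * Phi((x - x0) / sigma)`, and reports the full width at half
#' maximum of the corresponding line spread function (the ESF's Gaussian
#' derivative): `FWHM = 2 sqrt(2 ln 2) * sigma`.
#'
#' @param image A `pam_map_image` or matrix containing one straight edge.
#' @param pixel_size Pixel pitch (m).
#' @param edge_roi Optional list `list(rows =, cols =)` of index ranges
#'   selecting a region crossing the edge once.
#' @param edge_axis `"x"` if the intensity step runs along the first index,
#'   `"y"` otherwise.
#' @param rmse_threshold Relative root-mean-square fit residual above which
#'   the fit is rejected.
#' @return A one-row tibble of class `pam_resolution`: `fwhm` (m),
#'   `fit_sigma` (m), `fit_rmse` (relative), `kind = "lateral"`.
#' @export
lateral_resolution <- function(image, pixel_size, edge_roi = NULL,
                               edge_axis = c("x", "y"),
                               rmse_threshold = 0.1) {
  edge_axis <- match.arg(edge_axis)
  m <- as_image_matrix(image)
  if (!is.null(edge_roi)) m <- m[edge_roi$rows, edge_roi$cols, drop = FALSE]
  profile <- if (edge_axis == "x") rowMeans(m) else colMeans(m)
  xi <- seq_along(profile)
  lo <- min(profile); hi <- max(profile)
  if (hi - lo <= 0) {
    abort("Flat region of interest: no edge found.",
          class = "spiralpam_degenerate_input")
  }
  x0_start <- xi[which.min(abs(profile - (lo + hi) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      profile ~ a + b * pnorm((xi - x0) / sigma),
      start = list(a = lo, b = hi - lo, x0 = x0_start, sigma = 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort("Edge-spread-function fit failed to converge.",
                              class = "spiralpam_fit_error"))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2)) / abs(cf["b"])
  if (rmse > rmse_threshold) {
    abort("Edge-spread-function fit is unreliable.",
          class = "spiralpam_fit_error")
  }
  sigma_m <- abs(cf[["sigma"]]) * pixel_size
  out <- tibble::tibble(
    fwhm = 2 * sqrt(2 * log(2)) * sigma_m,
    fit_sigma = sigma_m,
    fit_rmse = unname(rmse),
    kind = "lateral"
  )
  class(out) <- c("pam_resolution", class(out))
  out
}

#' Axial resolution from a point-target A-scan
#'
#' Extracts the Hilbert envelope of the A-line, fits a Gaussian
#' `a exp(-(t - t0)^2 / (2 sigma^2))` around its peak, and converts the
#' temporal FWHM to meters through the one-way speed of sound.
#'
#' @param ascan A `pam_ascan` tibble or numeric vector.
#' @param settings [acquisition_settings()] (provides `sampling_rate` and
#'   `speed_of_sound`).
#' @param rmse_threshold Relative RMS residual limit.
#' @return A one-row tibble of class `pam_resolution`: `fwhm` (m),
#'   `fit_sigma` (s), `fit_rmse`, `kind = "axial"`.
#' @export
axial_resolution <- function(ascan, settings = acquisition_settings(),
                             rmse_threshold = 0.1) {
  env <- envelope(ascan)
  tt <- (seq_along(env) - 1) / settings$sampling_rate
  pk <- which.max(env)
  # fit only the coherent peak region; far-field samples carry no pulse shape
  win <- env >= 0.05 * env[pk]
  reg <- range(which(win & cumsum(win) > 0))
  sel <- seq(max(1, pk - (pk - reg[1])), min(length(env), pk + (reg[2] - pk)))
  e <- env[sel]; t <- tt[sel]
  sig0 <- max(diff(range(t)) / 6, 1 / settings$sampling_rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      e ~ a * exp(-(t - t0)^2 / (2 * sigma^2)),
      start = list(a = env[pk], t0 = tt[pk], sigma = sig0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort("Envelope Gaussian fit failed to converge.",
                              class = "spiralpam_fit_error"))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2)) / abs(cf["a"])
  if (rmse > rmse_threshold) {
    abort("Envelope Gaussian fit is unreliable.",
          class = "spiralpam_fit_error")
  }
  out <- tibble::tibble(
    fwhm = 2 * sqrt(2 * log(2)) * abs(cf[["sigma"]]) * settings$speed_of_sound,
    fit_sigma = abs(cf[["sigma"]]),
    fit_rmse = unname(rmse),
    kind = "axial"
  )
  class(out) <- c("pam_resolution", class(out))
  out
}

#' @export
glance.pam_resolution <- function(x, ...) tibble::as_tibble(x)

#' Signal-to-noise ratio in dB
#'
#' `20 log10(peak signal amplitude / noise standard deviation)`.
#'
#' @param image A `pam_map_image` or matrix.
#' @param signal_roi,noise_roi Logical masks of the image size, or lists
#'   `list(rows =, cols =)` of index ranges.
#' @return SNR in dB.
#' @export
snr_db <- function(image, signal_roi, noise_roi) {
  m <- as_image_matrix(image)
  pick <- function(roi) {
    if (is.list(roi)) m[roi$rows, roi$cols] else m[roi]
  }
  peak <- max(pick(signal_roi))
  nsd <- sd(as.vector(pick(noise_roi)))
  if (!is.finite(nsd) || nsd == 0) {
    abort("Noise standard deviation is zero; SNR undefined.",
          class = "spiralpam_degenerate_input")
  }
  20 * log10(peak / nsd)
}

#' Threshold an amplitude image into a vascular mask
#'
#' @param image A `pam_map_image` or matrix.
#' @param method `"otsu"` (threshold chosen by Otsu's criterion on the
#'   normalized image) or `"fixed"`.
#' @param threshold Threshold on the original amplitude scale for
#'   `method = "fixed"`.
#' @return Logical matrix with attributes `method` and `threshold` (on the
#'   original scale).
#' @export
vessel_mask <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  m <- as_image_matrix(image)
  if (method == "otsu") {
    rng <- range(m)
    if (diff(rng) == 0) {
      abort("Constant image: Otsu threshold undefined.",
            class = "spiralpam_degenerate_input")
    }
    norm <- (m - rng[1]) / diff(rng)
    th_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1] + th_norm * diff(rng)
  } else if (is.null(threshold)) {
    abort("`threshold` is required for method = 'fixed'.",
          class = "spiralpam_invalid_spec")
  }
  mask <- m > threshold
  attr(mask, "method") <- method
  attr(mask, "threshold") <- threshold
  mask
}

#' Vessel morphometry of a binary mask
#'
#' Computes the four morphometric indices: vessel area density
#' `VAD = vessel area / imaging area`; vessel skeleton density
#' `VSD = skeleton length / imaging area`; vessel diameter index
#' `VDI = vessel area / skeleton length` (a mean diameter); and vessel
#' complexity index `VCI = perimeter^2 / (4 pi area)` (1 for a circle). The
#' skeleton comes from topological thinning with diagonal steps counted as
#' `sqrt(2)`; the perimeter from corner-corrected Freeman chain codes. All
#' quantities are converted to physical units via `pixel_size`.
#'
#' @param mask Logical matrix (e.g. from [vessel_mask()]).
#' @param pixel_size Pixel pitch (m).
#' @return A one-row tibble of class `pam_vessel_metrics`: `vad`
#'   (dimensionless), `vsd` (1/m), `vdi` (m), `vci` (dimensionless), plus
#'   `vessel_area` (m^2), `skeleton_length` (m) and `perimeter` (m). An
#'   empty mask yields `vad = 0` and `NA` for the undefined indices.
#' @export
vessel_metrics <- function(mask, pixel_size) {
  total_area <- length(mask) * pixel_size^2
  npx <- sum(mask)
  if (npx == 0) {
    out <- tibble::tibble(vad = 0, vsd = NA_real_, vdi = NA_real_,
                          vci = NA_real_, vessel_area = 0,
                          skeleton_length = NA_real_, perimeter = NA_real_)
    class(out) <- c("pam_vessel_metrics", class(out))
    return(out)
  }
  area <- npx * pixel_size^2
  sk <- skeletonize(mask)
  skel_len <- skeleton_length_px(sk) * pixel_size
  perim <- perimeter_px(mask) * pixel_size
  out <- tibble::tibble(
    vad = npx / length(mask),
    vsd = skel_len / total_area,
    vdi = area / skel_len,
    vci = perim^2 / (4 * pi * area),
    vessel_area = area,
    skeleton_length = skel_len,
    perimeter = perim
  )
  class(out) <- c("pam_vessel_metrics", class(out))
  out
}

#' Split a vessel mask into macro and micro vessels
#'
#' The local vessel diameter at each skeleton pixel is estimated as twice
#' the Euclidean distance to the background minus one pixel (the distance
#' transform runs from pixel center to pixel center, half a pixel beyond the
#' boundary on each side); every vessel pixel inherits the diameter of its
#' nearest skeleton pixel and the mask is partitioned at
#' `threshold_diameter`.
#'
#' @param mask Logical vessel mask.
#' @param pixel_size Pixel pitch (m).
#' @param threshold_diameter Macro/micro split (m); vessels 100 um and wider
#'   count as macro by default.
#' @return List with logical matrices `macro` and `micro`.
#' @export
diameter_split <- function(mask, pixel_size, threshold_diameter = 100e-6) {
  if (!any(mask)) {
    return(list(macro = mask, micro = mask))
  }
  sk <- skeletonize(mask)
  if (!any(sk)) sk <- mask # single-pixel specks survive
  dist <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  diam_at_sk <- (2 * dist - 1) * pixel_size
  vessel_idx <- which(mask)
  nb <- grid_knn(sk, vessel_idx, 1)
  diam <- matrix(NA_real_, nrow(mask), ncol(mask))
  diam[vessel_idx] <- diam_at_sk[nb$idx[, 1]]
  macro <- mask & !is.na(diam) & diam >= threshold_diameter
  micro <- mask & !macro
  list(macro = macro, micro = micro)
}

#' Frame-series vessel density and amplitude analysis
#'
#' For a sequence of co-registered amplitude images, computes the per-frame
#' vessel density (mask area fraction, optionally split into macro and micro
#' vessels) and the mean in-mask amplitude expressed in dB relative to a
#' baseline frame (`20 log10(A / A_baseline)`).
#'
#' @param frames List of `pam_map_image`s or matrices.
#' @param times Optional frame times (s); defaults to the frame index.
#' @param mask_method `"otsu"` or `"fixed"` (see [vessel_mask()]).
#' @param threshold Fixed threshold, if used.
#' @param baseline_index Frame defining 0 dB.
#' @param pixel_size Pixel pitch (m); required with `split = TRUE`.
#' @param split Also report macro/micro vessel densities.
#' @param threshold_diameter Macro/micro diameter split (m).
#' @return A tibble of class `pam_frame_series` with columns `time`,
#'   `vessel_density`, `mean_amplitude_db` (and `macro_density`,
#'   `micro_density` when split).
#' @export
timeseries_quantify <- function(frames, times = NULL,
                                mask_method = c("otsu", "fixed"),
                                threshold = NULL, baseline_index = 1,
                                pixel_size = NULL, split = FALSE,
                                threshold_diameter = 100e-6) {
  mask_method <- match.arg(mask_method)
  if (is.null(times)) times <- seq_along(frames) - 1
  rows <- purrr::map(seq_along(frames), function(i) {
    m <- as_image_matrix(frames[[i]])
    mask <- vessel_mask(m, method = mask_method, threshold = threshold)
    dens <- mean(mask)
    amp <- if (any(mask)) mean(m[mask]) else NA_real_
    row <- tibble::tibble(time = times[i], vessel_density = dens,
                          mean_amplitude = amp)
    if (split) {
      if (is.null(pixel_size)) {
        abort("`pixel_size` is required for the macro/micro split.",
              class = "spiralpam_invalid_spec")
      }
      sp <- diameter_split(mask, pixel_size, threshold_diameter)
      row$macro_density <- mean(sp$macro)
      row$micro_density <- mean(sp$micro)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  base_amp <- out$mean_amplitude[baseline_index]
  out$mean_amplitude_db <- 20 * log10(out$mean_amplitude / base_amp)
  out$mean_amplitude <- NULL
  class(out) <- c("pam_frame_series", class(out))
  out
}

#' @export
autoplot.pam_frame_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "metric")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Write quantification outputs
#'
#' @param metrics Any tibble-like metrics object.
#' @param csv_path,json_path Output paths (`NULL` skips).
#' @return Invisibly, the written paths.
#' @export
write_metrics <- function(metrics, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(metrics), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(tibble::as_tibble(metrics)), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
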