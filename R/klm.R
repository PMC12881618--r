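#' Assemble a layered transducer stack
#'
#' @param piezo A piezoelectric [material()] (needs `kt` and
#'   `rel_permittivity`).
#' @param piezo_thickness Piezo layer thickness (m).
#' @param area Active element area (m^2).
#' @param front_layers Tibble/data frame with one row per matching layer,
#'   ordered from the piezo outward, columns `name`,
#'   `longitudinal_velocity`, `density`, `thickness`.
#' @param backing Backing [material()].
#' @param backing_thickness Backing thickness (m), or `NULL` (default) for a
#'   semi-infinite (fully absorbing) backing.
#' @param front_load Semi-infinite front load medium (default water).
#' @param back_load Semi-infinite medium behind a finite backing layer
#'   (default air); ignored for a semi-infinite backing.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(piezo, piezo_thickness, area,
                        front_layers,
                        backing, backing_thickness = NULL,
                        front_load = pam_materials("water"),
                        back_load = pam_materials("air")) {
  stopifnot_positive(piezo_thickness = piezo_thickness, area = area)
  if (is.na(piezo$kt) || is.na(piezo$rel_permittivity)) {
    abort("The piezo material needs `kt` and `rel_permittivity`.",
          class = "spiralpam_invalid_spec")
  }
  front_layers <- tibble::as_tibble(front_layers)
  if (nrow(front_layers) && any(front_layers$thickness <= 0)) {
    abort("Layer thicknesses must be > 0.", class = "spiralpam_invalid_spec")
  }
  if (!is.null(backing_thickness)) {
    stopifnot_positive(backing_thickness = backing_thickness)
  }
  structure(
    list(piezo = piezo, piezo_thickness = piezo_thickness, area = area,
         front_layers = front_layers, backing = backing,
         backing_thickness = backing_thickness,
         front_load = front_load, back_load = back_load),
    class = "layer_stack"
  )
}

#' The transparent-transducer design stack
#'
#' The four-layer design: 94 um lithium niobate, 30 um ceramic-epoxy
#' composite first matching, 19 um epoxy second matching and a 1 mm epoxy
#' backing, on a 6 mm x 6 mm element radiating into water. The backing is
#' modelled as a semi-infinite epoxy load: a lossless 1 mm layer terminated in
#' air would ring with a fine spectral comb that the real (lossy) backing
#' epoxy suppresses, and per-layer loss is off by default.
#'
#' @param materials A materials table as from [pam_materials()], allowing any
#'   constant to be overridden.
#' @return A [layer_stack()].
#' @export
tut_layer_stack <- function(materials = pam_materials()) {
  get_mat <- function(nm) {
    row <- materials[materials$name == nm, ]
    class(row) <- c("pam_material", class(row))
    row
  }
  comp <- get_mat("composite"); epox <- get_mat("epoxy")
  layer_stack(
    piezo = get_mat("lno"), piezo_thickness = 94e-6, area = 6e-3 * 6e-3,
    front_layers = tibble::tibble(
      name = c("composite", "epoxy"),
      longitudinal_velocity = c(comp$longitudinal_velocity,
                                epox$longitudinal_velocity),
      density = c(comp$density, epox$density),
      thickness = c(30e-6, 19e-6)
    ),
    backing = epox, backing_thickness = NULL,
    front_load = get_mat("water"), back_load = get_mat("air")
  )
}

## acoustic transmission-line algebra, vectorized over frequency ----------

# ABCD of a lossless acoustic line: list(A, B, C, D) of complex vectors
line_abcd <- function(z0, gamma) {
  list(A = cos(gamma) + 0i, B = 1i * z0 * sin(gamma),
       C = 1i * sin(gamma) / z0, D = cos(gamma) + 0i)
}

abcd_mul <- function(m1, m2) {
  list(A = m1$A * m2$A + m1$B * m2$C, B = m1$A * m2$B + m1$B * m2$D,
       C = m1$C * m2$A + m1$D * m2$C, D = m1$C * m2$B + m1$D * m2$D)
}

abcd_identity <- function(n) {
  list(A = rep(1 + 0i, n), B = rep(0i, n), C = rep(0i, n), D = rep(1 + 0i, n))
}

abcd_zin <- function(m, z_load) {
  (m$A * z_load + m$B) / (m$C * z_load + m$D)
}

#' Two-way pulse-echo response of a layered stack (KLM model)
#'
#' Implements the KLM equivalent circuit: the piezo layer is an acoustic
#' transmission line tapped at its midpoint by the electrical branch through
#' the frequency-dependent transformer `phi(w) = w Zc / (2 h sin(g/2))` in
#' series with the static capacitance `C0` and the reactance
#' `X1 = h^2 sin(g) / (w^2 Zc)` (`g` the acoustic phase across the piezo,
#' `h` the piezoelectric pressure constant `kt sqrt(rho v^2 / epsS)`);
#' matching and backing layers are acoustic transmission-line two-ports
#' terminated by the semi-infinite loads. The transmit transfer function is
#' the force delivered to the front load per source volt; the receive
#' transfer function is the voltage across the receive termination per unit
#' incident force; the pulse-echo (two-way) spectrum is their product, and
#' the time-domain waveform its inverse Fourier transform with Hermitian
#' symmetry (zero-phase reference at the grid origin).
#'
#' @param stack A [layer_stack()].
#' @param freq_grid Positive, uniformly spaced frequencies (Hz). Default
#'   4096 points up to 150 MHz.
#' @param source_impedance Electrical source and receive termination (ohm);
#'   the design value is 50.
#' @return An object of class `klm_response`: list with `frequency`,
#'   complex `transmit`, `receive`, `two_way`, and a `waveform` tibble
#'   (`time`, `amplitude`).
#' @export
klm_two_way_response <- function(stack,
                                 freq_grid = seq(150e6 / 4096, 150e6,
                                                 length.out = 4096),
                                 source_impedance = 50) {
  f <- freq_grid
  if (any(f <= 0)) {
    abort("`freq_grid` must be strictly positive.",
          class = "spiralpam_invalid_spec")
  }
  df <- diff(f)
  if (length(df) < 2 || max(abs(df - df[1])) > 1e-6 * df[1]) {
    abort("`freq_grid` must be uniform.", class = "spiralpam_invalid_spec")
  }
  if (stack$piezo_thickness <= 0 ||
      (nrow(stack$front_layers) && any(stack$front_layers$thickness <= 0))) {
    abort("Layer thicknesses must be > 0.", class = "spiralpam_invalid_spec")
  }
  w <- 2 * pi * f
  a <- stack$area
  zc_of <- function(v, rho) rho * v * a

  pz <- stack$piezo
  vp <- pz$longitudinal_velocity
  zp <- zc_of(vp, pz$density)
  dp <- stack$piezo_thickness
  c0 <- pz$rel_permittivity * 8.8541878128e-12 * a / dp
  h <- pz$kt * sqrt(pz$density * vp^2 / (pz$rel_permittivity * 8.8541878128e-12))
  g <- w * dp / vp

  # front chain, piezo face -> outermost layer, terminated by the front load
  t_front <- abcd_identity(length(w))
  if (nrow(stack$front_layers)) {
    for (k in seq_len(nrow(stack$front_layers))) {
      lay <- stack$front_layers[k, ]
      t_front <- abcd_mul(
        t_front,
        line_abcd(zc_of(lay$longitudinal_velocity, lay$density),
                  w * lay$thickness / lay$longitudinal_velocity))
    }
  }
  z_front_load <- zc_of(stack$front_load$longitudinal_velocity,
                        stack$front_load$density)
  # backing seen from the piezo back face
  z_back <- zc_of(stack$backing$longitudinal_velocity, stack$backing$density)
  if (!is.null(stack$backing_thickness)) {
    t_back <- line_abcd(z_back, w * stack$backing_thickness /
                          stack$backing$longitudinal_velocity)
    z_back <- abcd_zin(t_back, zc_of(stack$back_load$longitudinal_velocity,
                                     stack$back_load$density))
  }

  t_half <- line_abcd(zp, g / 2)
  z_b_tap <- abcd_zin(t_half, z_back)
  t_front_tap <- abcd_mul(t_half, t_front)
  z_f_tap <- abcd_zin(t_front_tap, z_front_load)

  phi <- w * zp / (2 * h * sin(g / 2))
  x1 <- h^2 * sin(g) / (w^2 * zp)
  z_ac <- z_b_tap * z_f_tap / (z_b_tap + z_f_tap)
  z_el <- 1 / (1i * w * c0) + 1i * x1 + z_ac / phi^2

  # transmit: unit source volt behind the source impedance
  cur <- 1 / (source_impedance + z_el)
  u_w <- cur / phi
  f_tap <- u_w * z_ac
  u_front <- f_tap / z_f_tap
  # propagate (F, u) at the tap through the front chain to the load
  det_t <- t_front_tap$A * t_front_tap$D - t_front_tap$B * t_front_tap$C
  f_load <- (t_front_tap$D * f_tap - t_front_tap$B * u_front) / det_t
  transmit <- f_load

  # receive: Thevenin reduction of a unit incident force behind the water
  # load impedance. First at the piezo front face through the matching
  # layers, then through the front half-line to the tap.
  f_w <- t_front$D / (t_front$D + z_front_load * t_front$C)
  u_w2 <- -(t_front$C / t_front$D) * f_w
  f_th <- t_front$A * f_w + t_front$B * u_w2
  z_th <- abcd_zin(t_front, z_front_load) # source replaced by its impedance
  f_th_tap <- f_th / (t_half$A + z_th * t_half$C)
  z_f_tap_rx <- abcd_zin(t_half, z_th)
  # at the tap the back half-line and the reflected electrical branch
  # (series C0, X1 and the receive termination) load the node in parallel
  z_el_rx <- 1 / (1i * w * c0) + 1i * x1 + source_impedance
  z_refl <- phi^2 * z_el_rx
  z_node <- z_b_tap * z_refl / (z_b_tap + z_refl)
  u_in <- f_th_tap / (z_f_tap_rx + z_node)
  f_node <- u_in * z_node
  i_el <- phi * f_node / z_refl # winding velocity f_node / z_refl, times phi
  receive <- source_impedance * i_el # volts across the receiver per unit force

  two_way <- transmit * receive
  if (any(!is.finite(two_way))) {
    abort("Non-finite response; check the stack.",
          class = "spiralpam_invalid_spec")
  }

  waveform <- pulse_waveform(f, two_way)
  structure(
    list(frequency = f, transmit = transmit, receive = receive,
         two_way = two_way, waveform = waveform, stack = stack,
         source_impedance = source_impedance),
    class = "klm_response"
  )
}

# Hermitian-symmetric inverse FFT of a one-sided spectrum on bins round(f/df)
pulse_waveform <- function(f, spectrum) {
  df <- f[2] - f[1]
  kidx <- as.integer(round(f / df))
  n <- 2L * (max(kidx) + 1L)
  full <- complex(n)
  full[kidx + 1L] <- spectrum
  full[n - kidx + 1L] <- Conj(spectrum)
  amp <- Re(fft(full, inverse = TRUE)) / n
  tibble::tibble(time = (0:(n - 1)) / (n * df), amplitude = amp)
}

#' @export
print.klm_response <- function(x, ...) {
  bm <- extract_band_metrics(x)
  cat(sprintf(
    "<klm_response> %d freqs to %.0f MHz; Fc %.1f MHz, -6 dB FBW %.1f %%\n",
    length(x$frequency), max(x$frequency) / 1e6,
    bm$center_frequency / 1e6, 100 * bm$fractional_bandwidth))
  invisible(x)
}

#' @export
tidy.klm_response <- function(x, ...) {
  mag <- Mod(x$two_way)
  tibble::tibble(
    frequency = x$frequency,
    transmit = Mod(x$transmit),
    receive = Mod(x$receive),
    magnitude = mag,
    db = 20 * log10(mag / max(mag))
  )
}

#' @export
glance.klm_response <- function(x, ...) {
  extract_band_metrics(x)
}

#' @export
autoplot.klm_response <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$frequency / 1e6, y = .data$db)) +
    geom_line() +
    labs(x = "frequency (MHz)", y = "two-way magnitude (dB)") +
    theme_minimal()
}

#' Extract -6 dB band metrics from a magnitude spectrum
#'
#' Locates the outermost -6 dB crossings around the global magnitude peak by
#' linear interpolation between grid points; the center frequency is the
#' midpoint of the crossings and the fractional bandwidth their span divided
#' by the center.
#'
#' @param spectrum A [klm_two_way_response()] result, or a numeric magnitude
#'   vector (then `frequency` is required).
#' @param frequency Frequencies (Hz) matching a numeric `spectrum`.
#' @param level_db Band edge level below the peak; -6 dB by default.
#' @return A one-row tibble of class `pam_band_metrics`: `center_frequency`,
#'   `fractional_bandwidth`, `f_low`, `f_high` (Hz).
#' @export
extract_band_metrics <- function(spectrum, frequency = NULL, level_db = -6) {
  if (inherits(spectrum, "klm_response")) {
    frequency <- spectrum$frequency
    spectrum <- Mod(spectrum$two_way)
  }
  if (is.null(frequency) || length(frequency) != length(spectrum)) {
    abort("Supply `frequency` matching the magnitude spectrum.",
          class = "spiralpam_invalid_spec")
  }
  db <- 20 * log10(spectrum / max(spectrum))
  pk <- which.max(spectrum)
  n <- length(db)
  cross_f <- function(i) { # linear interpolation between i and i+1
    approx(db[c(i, i + 1)], frequency[c(i, i + 1)], level_db)$y
  }
  lo_idx <- which(db[-n] <= level_db & db[-1] > level_db) # upward crossings
  lo_idx <- lo_idx[lo_idx < pk]
  hi_idx <- which(db[-n] > level_db & db[-1] <= level_db) # downward crossings
  hi_idx <- hi_idx[hi_idx >= pk]
  if (!length(lo_idx) || !length(hi_idx)) {
    abort("The spectrum never crosses the band-edge level on both sides.",
          class = "spiralpam_bandwidth_undefined")
  }
  f_low <- cross_f(min(lo_idx))   # outermost crossing below the peak
  f_high <- cross_f(max(hi_idx))  # outermost crossing above the peak
  fc <- (f_low + f_high) / 2
  out <- tibble::tibble(
    center_frequency = fc,
    fractional_bandwidth = (f_high - f_low) / fc,
    f_low = f_low, f_high = f_high
  )
  class(out) <- c("pam_band_metrics", class(out))
  out
}

#' Write KLM outputs (CSV spectrum/waveform, JSON band metrics)
#'
#' @param response A [klm_two_way_response()] result.
#' @param spectrum_csv,waveform_csv,metrics_json Output paths (`NULL` skips).
#' @return Invisibly, the list of written paths.
#' @export
write_klm_outputs <- function(response, spectrum_csv = NULL,
                              waveform_csv = NULL, metrics_json = NULL) {
  if (!is.null(spectrum_csv)) {
    write.csv(as.data.frame(tidy(response)), spectrum_csv, row.names = FALSE)
  }
  if (!is.null(waveform_csv)) {
    write.csv(as.data.frame(response$waveform), waveform_csv,
              row.names = FALSE)
  }
  if (!is.null(metrics_json)) {
    jsonlite::write_json(as.list(extract_band_metrics(response)),
                         metrics_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(spectrum = spectrum_csv, waveform = waveform_csv,
                 metrics = metrics_json))
}
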