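#' Describe a fiber cantilever
#'
#' A single-mode fiber glued to the tip of a piezo tube behaves as a clamped-
#' free flexural beam; its first resonance sets the spiral scan frequency.
#'
#' @param youngs_modulus Young's modulus of the fiber material (Pa).
#' @param density Mass density (kg/m^3).
#' @param radius Fiber radius (m).
#' @param length Free cantilever length (m).
#' @param mode_constant Dimensionless mode constant beta. The default,
#'   `lambda1^2 / 2` with `lambda1 = 1.87510407` the first root of
#'   `cos(x) cosh(x) = -1`, is the first flexural mode of a circular-section
#'   clamped-free beam, for which the radius of gyration is `radius / 2`.
#'
#' @return A one-row tibble of class `cantilever_spec`.
#' @examples
#' fiber_spec <- cantilever_spec(73e9, 2200, 62.5e-6, 18e-3)
#' resonant_frequency(fiber_spec) # about 311 Hz
#' @export
cantilever_spec <- function(youngs_modulus, density, radius, length,
                            mode_constant = 1.87510407^2 / 2) {
  stopifnot_positive(youngs_modulus = youngs_modulus, density = density,
                     radius = radius, length = length,
                     mode_constant = mode_constant)
  out <- tibble::tibble(
    youngs_modulus = youngs_modulus, density = density,
    radius = radius, length = length, mode_constant = mode_constant
  )
  class(out) <- c("cantilever_spec", class(out))
  out
}

#' First flexural resonance of a fiber cantilever
#'
#' Evaluates `omega = beta * sqrt(E / rho) * R / L^2` and converts the angular
#' frequency to Hz. With the default `mode_constant` this is the classical
#' Euler-Bernoulli first eigenfrequency of a clamped-free circular beam.
#'
#' @param spec A [cantilever_spec()].
#' @return Resonant frequency in Hz (scalar).
#' @export
resonant_frequency <- function(spec) {
  if (!inherits(spec, "cantilever_spec")) {
    abort("`spec` must be a cantilever_spec.", class = "spiralpam_invalid_spec")
  }
  omega <- spec$mode_constant * sqrt(spec$youngs_modulus / spec$density) *
    spec$radius / spec$length^2
  omega / (2 * pi)
}
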