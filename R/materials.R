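#' Define an acoustic material
#'
#' @param name Label.
#' @param longitudinal_velocity Longitudinal sound speed (m/s).
#' @param density Mass density (kg/m^3).
#' @param kt Thickness-mode electromechanical coupling (piezo layers only).
#' @param rel_permittivity Clamped relative permittivity (piezo layers only).
#' @return A one-row tibble of class `pam_material` with a derived
#'   `impedance_mrayl` column (`velocity * density`, in MRayl).
#' @export
material <- function(name, longitudinal_velocity, density,
                     kt = NA_real_, rel_permittivity = NA_real_) {
  stopifnot_positive(longitudinal_velocity = longitudinal_velocity,
                     density = density)
  if (!is.na(kt) && (kt <= 0 || kt >= 1)) {
    abort("`kt` must lie in (0, 1).", class = "spiralpam_invalid_spec")
  }
  out <- tibble::tibble(
    name = name,
    longitudinal_velocity = longitudinal_velocity,
    density = density,
    impedance_mrayl = longitudinal_velocity * density / 1e6,
    kt = kt,
    rel_permittivity = rel_permittivity
  )
  class(out) <- c("pam_material", class(out))
  out
}

#' Literature material constants for the transparent-transducer stack
#'
#' The stack layers' acoustic constants are not part of the printed design, so
#' the package ships an editable literature-sourced table:
#' * `lno` - 36 degree rotated Y-cut lithium niobate, thickness mode:
#'   v = 7340 m/s, rho = 4640 kg/m^3, kt = 0.49, clamped relative
#'   permittivity 39.
#' * `composite` - heavily loaded 0-3 ceramic/epoxy first matching layer:
#'   v = 4000 m/s (the quarter-wave velocity implied by a 30 um layer at
#'   33.5 MHz), rho = 2400 kg/m^3, giving Z = 9.6 MRayl, near the two-layer
#'   matching optimum `Zp^(4/7) Zw^(3/7)` of about 8.9 MRayl for lithium
#'   niobate into water.
#' * `epoxy` - EPO-TEK-301-class epoxy (second matching and backing):
#'   v = 2650 m/s, rho = 1150 kg/m^3.
#' * `water` - front load: v = 1500 m/s, rho = 1000 kg/m^3.
#' * `air` - v = 343 m/s, rho = 1.2 kg/m^3.
#'
#' @param name Optional material name; if given, the single matching
#'   `pam_material` row is returned.
#' @return A tibble of materials, or one `pam_material`.
#' @export
pam_materials <- function(name = NULL) {
  tab <- dplyr::bind_rows(
    material("lno", 7340, 4640, kt = 0.49, rel_permittivity = 39),
    material("composite", 4000, 2400),
    material("epoxy", 2650, 1150),
    material("water", 1500, 1000),
    material("air", 343, 1.2)
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (!nrow(row)) {
    abort(sprintf("Unknown material '%s'.", name),
          class = "spiralpam_invalid_spec")
  }
  class(row) <- c("pam_material", class(row))
  row
}

#' Half- or quarter-wave layer thickness
#'
#' The piezo layer of a thickness-mode stack is designed at half the
#' wavelength of the target center frequency; matching layers at a quarter
#' wavelength.
#'
#' @param material A [material()].
#' @param role `"half_wave"` or `"quarter_wave"`.
#' @param frequency Design frequency (Hz).
#' @return Thickness in meters.
#' @export
design_thickness <- function(material, role = c("half_wave", "quarter_wave"),
                             frequency) {
  role <- match.arg(role)
  stopifnot_positive(frequency = frequency)
  v <- material$longitudinal_velocity
  switch(role, half_wave = v / (2 * frequency),
         quarter_wave = v / (4 * frequency))
}
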