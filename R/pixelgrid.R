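#' Map physical positions to image pixels
#'
#' The affine grid convention places the pixel-center of index 0 at
#' `-fov_diameter / 2` and of index `grid_size - 1` at `+fov_diameter / 2`;
#' continuous indices are rounded to the nearest pixel with ties going away
#' from zero, so position (0, 0) on a 512 grid lands on pixel (256, 256).
#' This single routine is shared by the trigger-density and reconstruction
#' stages so that shot binning and pixel assignment can never disagree.
#'
#' @param x,y Positions (m) in the probe frame, origin at the scan center.
#' @param grid_size Image width/height in pixels.
#' @param fov_diameter Field-of-view diameter (m).
#' @return A tibble with 0-based integer columns `ix`, `iy` and logical
#'   `inside` flagging positions that fall on the grid (out-of-grid positions
#'   are flagged, not dropped).
#' @export
position_to_pixel <- function(x, y, grid_size, fov_diameter) {
  half <- fov_diameter / 2
  scale <- (grid_size - 1) / fov_diameter
  ix <- round_half_away((x + half) * scale)
  iy <- round_half_away((y + half) * scale)
  inside <- ix >= 0 & ix <= grid_size - 1 & iy >= 0 & iy <= grid_size - 1
  tibble::tibble(ix = as.integer(ix), iy = as.integer(iy), inside = inside)
}

# physical coordinate of pixel centers for 0-based indices
pixel_center <- function(i, grid_size, fov_diameter) {
  i / (grid_size - 1) * fov_diameter - fov_diameter / 2
}

# logical grid_size x grid_size matrix of pixels whose centers lie inside the
# field-of-view disc
fov_disc_mask <- function(grid_size, fov_diameter) {
  cc <- pixel_center(0:(grid_size - 1), grid_size, fov_diameter)
  outer(cc^2, cc^2, "+") <= (fov_diameter / 2)^2
}
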