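#' Construct a phantom volume
#'
#' A phantom is a 3D grid of relative optical absorption in \[0, 1\]. The z
#' axis is the acoustic axis, increasing away from the probe; (x, y) span the
#' scan plane. Voxel indices are 0-based with physical positions at voxel
#' centers.
#'
#' @param absorption 3D numeric array (x, y, z), values in \[0, 1\].
#' @param voxel_size Length-3 vector `(dx, dy, dz)` in meters.
#' @param origin Physical position of voxel (0, 0, 0)'s center; defaults to
#'   laterally centered with the first depth sample one voxel below z = 0.
#' @param meta List of generator parameters (including any seed).
#' @return An array of class `pam_phantom` with attributes.
#' @export
pam_phantom <- function(absorption, voxel_size, origin = NULL, meta = list()) {
  if (length(dim(absorption)) != 3) {
    abort("`absorption` must be a 3D array.", class = "spiralpam_invalid_spec")
  }
  if (any(absorption < 0) || any(absorption > 1)) {
    abort("Absorption values must lie in [0, 1].",
          class = "spiralpam_invalid_spec")
  }
  stopifnot_positive(voxel_size = voxel_size)
  d <- dim(absorption)
  if (is.null(origin)) {
    origin <- c(-(d[1] - 1) / 2 * voxel_size[1],
                -(d[2] - 1) / 2 * voxel_size[2],
                voxel_size[3])
  }
  structure(absorption, voxel_size = voxel_size, origin = origin, meta = meta,
            class = "pam_phantom")
}

#' @export
print.pam_phantom <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pam_phantom> %d x %d x %d voxels, %.1f x %.1f x %.1f um, %.1f %% filled\n",
              d[1], d[2], d[3], attr(x, "voxel_size")[1] * 1e6,
              attr(x, "voxel_size")[2] * 1e6, attr(x, "voxel_size")[3] * 1e6,
              100 * mean(x > 0)))
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameters of the random vessel-tree generator
#'
#' @param n_roots Number of root vessels.
#' @param diameter_range `(min, max)` root diameters (m).
#' @param tortuosity Standard deviation of the per-step in-plane direction
#'   perturbation (radians); larger values give more tortuous vessels.
#' @param branching_prob Per-step probability of spawning a branch.
#' @param depth_band `(z_min, z_max)` band (m) containing the tree, or `NULL`
#'   for the middle half of the volume.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(n_roots = 3,
                               diameter_range = c(30e-6, 120e-6),
                               tortuosity = 0.15,
                               branching_prob = 0.02,
                               depth_band = NULL,
                               seed = 1L) {
  if (diameter_range[1] <= 0 || diameter_range[2] < diameter_range[1]) {
    abort("`diameter_range` must be positive and ordered.",
          class = "spiralpam_invalid_spec")
  }
  if (branching_prob < 0 || branching_prob > 1) {
    abort("`branching_prob` must be in [0, 1].",
          class = "spiralpam_invalid_spec")
  }
  structure(list(n_roots = n_roots, diameter_range = diameter_range,
                 tortuosity = tortuosity, branching_prob = branching_prob,
                 depth_band = depth_band, seed = seed),
            class = "vessel_tree_params")
}

#' Generate a random vessel-tree phantom
#'
#' Vessels are biased random-walk tubes: each root starts at a random lateral
#' position inside the volume and walks in the scan plane with smoothly
#' perturbed direction (Gaussian step-angle increments) and a weak confined
#' depth drift; branches spawn with `branching_prob` per step at 70 % of the
#' parent diameter. Centerlines are rasterized as filled spheres per step, so
#' tubes of the per-segment diameter result. Ground-truth centerlines and
#' diameters are stored in the `meta` attribute for scoring reconstruction
#' and morphometry.
#'
#' @param params A [vessel_tree_params()].
#' @param shape Volume shape in voxels, at least (64, 64, 32).
#' @param voxel_size `(dx, dy, dz)` in meters.
#' @return A [pam_phantom()]; `meta` holds `centerlines` (tibble with voxel
#'   coordinates and diameters), the parameters, and a `warnings` field that
#'   records segments thinner than two voxels.
#' @export
make_vessel_phantom <- function(params = vessel_tree_params(),
                                shape = c(128, 128, 48),
                                voxel_size = c(5e-6, 5e-6, 5e-6)) {
  if (any(shape < c(64, 64, 32))) {
    abort("`shape` must be at least (64, 64, 32) voxels.",
          class = "spiralpam_invalid_spec")
  }
  vol <- array(0, dim = shape)
  dx <- voxel_size[1]
  zb <- params$depth_band
  if (is.null(zb)) zb <- c(0.25, 0.75) * shape[3] # voxel units
  else zb <- zb / voxel_size[3]
  cl <- list()
  if (params$n_roots > 0) {
    cl <- with_fixed_seed(params$seed, {
      segs <- list()
      queue <- lapply(seq_len(params$n_roots), function(i) {
        list(x = runif(1, 0.15, 0.85) * shape[1],
             y = runif(1, 0.15, 0.85) * shape[2],
             z = runif(1, zb[1], zb[2]),
             theta = runif(1, 0, 2 * pi),
             diam = runif(1, params$diameter_range[1],
                          params$diameter_range[2]) / dx,
             gen = 1L)
      })
      n_steps <- 2L * shape[1]
      seg_id <- 0L
      while (length(queue)) {
        st <- queue[[1]]; queue <- queue[-1]
        seg_id <- seg_id + 1L
        pts <- matrix(NA_real_, n_steps, 3)
        th <- st$theta
        p <- c(st$x, st$y, st$z)
        k <- 0L
        for (s in seq_len(n_steps)) {
          th <- th + rnorm(1, 0, params$tortuosity)
          p <- p + c(cos(th), sin(th), rnorm(1, 0, params$tortuosity / 2))
          p[3] <- min(max(p[3], zb[1]), zb[2])
          if (p[1] < 1 || p[1] > shape[1] - 2 ||
              p[2] < 1 || p[2] > shape[2] - 2) break
          k <- k + 1L
          pts[k, ] <- p
          if (st$gen < 3L && runif(1) < params$branching_prob) {
            queue <- c(queue, list(list(
              x = p[1], y = p[2], z = p[3],
              theta = th + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
              diam = st$diam * 0.7, gen = st$gen + 1L)))
          }
        }
        if (k > 0) {
          segs[[seg_id]] <- tibble::tibble(
            segment = seg_id, step = seq_len(k),
            x = pts[seq_len(k), 1], y = pts[seq_len(k), 2],
            z = pts[seq_len(k), 3], diameter_vox = st$diam)
        }
      }
      segs
    })
  }
  centerlines <- if (length(cl)) dplyr::bind_rows(cl) else
    tibble::tibble(segment = integer(), step = integer(), x = numeric(),
                   y = numeric(), z = numeric(), diameter_vox = numeric())
  warnings <- character()
  if (nrow(centerlines)) {
    if (any(centerlines$diameter_vox < 2)) {
      warnings <- "some vessel segments are thinner than 2 voxels"
    }
    vol <- rasterize_tubes(vol, centerlines)
  }
  pam_phantom(vol, voxel_size,
              meta = list(generator = "vessel_tree", params = params,
                          seed = params$seed,
                          centerlines = centerlines, warnings = warnings))
}

# mark voxels within diameter/2 of each centerline point (grouped by radius
# so sphere offset stencils are reused)
rasterize_tubes <- function(vol, centerlines) {
  d <- dim(vol)
  rad <- centerlines$diameter_vox / 2
  rkey <- round(rad, 2)
  for (r in unique(rkey)) {
    rr <- max(r, 0.5)
    span <- ceiling(rr)
    off <- expand.grid(dx = -span:span, dy = -span:span, dz = -span:span)
    off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= rr^2, , drop = FALSE]
    sel <- rkey == r
    cx <- round(centerlines$x[sel]); cy <- round(centerlines$y[sel])
    cz <- round(centerlines$z[sel])
    for (j in seq_len(nrow(off))) {
      ix <- cx + off$dx[j]; iy <- cy + off$dy[j]; iz <- cz + off$dz[j]
      ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
      vol[cbind(ix[ok] + 1, iy[ok] + 1, iz[ok] + 1)] <- 1
    }
  }
  vol
}

#' Edge target: absorbing half-plane at one depth
#'
#' A one-voxel-thick absorbing half-plane with a sharp step across
#' `edge_axis` located exactly at the grid midline, used for edge-spread-
#' function resolution measurements.
#'
#' @param shape Volume shape in voxels.
#' @param voxel_size `(dx, dy, dz)` (m).
#' @param edge_axis `"x"` or `"y"`: the axis along which the step occurs.
#' @param depth Depth index (0-based) of the absorbing slab; default mid-depth.
#' @return A [pam_phantom()] with `meta$edge_index` the first absorbing index.
#' @export
make_edge_target <- function(shape, voxel_size, edge_axis = c("x", "y"),
                             depth = NULL) {
  edge_axis <- match.arg(edge_axis)
  if (is.null(depth)) depth <- shape[3] %/% 2
  vol <- array(0, dim = shape)
  mid <- shape[[if (edge_axis == "x") 1 else 2]] %/% 2
  if (edge_axis == "x") vol[(mid + 1):shape[1], , depth + 1] <- 1
  else vol[, (mid + 1):shape[2], depth + 1] <- 1
  pam_phantom(vol, voxel_size,
              meta = list(generator = "edge_target", edge_axis = edge_axis,
                          edge_index = mid, depth_index = depth))
}

#' Grid target: periodic bars in both axes at one depth
#'
#' @param shape Volume shape in voxels.
#' @param voxel_size `(dx, dy, dz)` (m).
#' @param pitch Bar period (m).
#' @param bar_width Bar width (m), less than `pitch`.
#' @param depth Depth index (0-based) of the pattern slab; default mid-depth.
#' @return A [pam_phantom()] with the pitch/width (voxels) in `meta`.
#' @export
make_grid_target <- function(shape, voxel_size, pitch, bar_width,
                             depth = NULL) {
  if (is.null(depth)) depth <- shape[3] %/% 2
  pitch_vox <- pitch / voxel_size[1]
  bar_vox <- bar_width / voxel_size[1]
  if (pitch_vox < 2) {
    abort("`pitch` below two voxels cannot be represented.",
          class = "spiralpam_invalid_spec")
  }
  ix <- 0:(shape[1] - 1); iy <- 0:(shape[2] - 1)
  bar_x <- (ix %% pitch_vox) < bar_vox
  bar_y <- (iy %% pitch_vox) < bar_vox
  plane <- outer(bar_x, rep(TRUE, shape[2])) | outer(rep(TRUE, shape[1]), bar_y)
  vol <- array(0, dim = shape)
  vol[, , depth + 1] <- plane * 1
  pam_phantom(vol, voxel_size,
              meta = list(generator = "grid_target", pitch_vox = pitch_vox,
                          bar_vox = bar_vox, depth_index = depth))
}

#' Point target: single-voxel absorbers
#'
#' @param shape Volume shape in voxels.
#' @param voxel_size `(dx, dy, dz)` (m).
#' @param positions Tibble/data frame with 0-based voxel indices `ix`, `iy`,
#'   `iz`; may be empty.
#' @return A [pam_phantom()].
#' @export
make_point_target <- function(shape, voxel_size, positions) {
  vol <- array(0, dim = shape)
  positions <- tibble::as_tibble(positions)
  if (nrow(positions)) {
    vol[cbind(positions$ix + 1, positions$iy + 1, positions$iz + 1)] <- 1
  }
  pam_phantom(vol, voxel_size,
              meta = list(generator = "point_target", positions = positions))
}

#' Save / load a phantom as multi-page TIFF plus JSON sidecar
#'
#' @param phantom A [pam_phantom()].
#' @param tiff_path Multi-page TIFF path (depth slices as pages).
#' @param json_path Sidecar path; defaults to `tiff_path` with `.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_phantom <- function(phantom, tiff_path,
                          json_path = paste0(tiff_path, ".json")) {
  EBImage::writeImage(unclass(phantom), tiff_path, type = "tiff",
                      bits.per.sample = 16L)
  meta <- attr(phantom, "meta")
  meta$centerlines <- NULL # tabular ground truth stays in-session
  jsonlite::write_json(
    list(voxel_size = attr(phantom, "voxel_size"),
         origin = attr(phantom, "origin"), meta = meta),
    json_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(tiff_path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(tiff_path, json_path = paste0(tiff_path, ".json")) {
  arr <- as.array(EBImage::readImage(tiff_path))
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pam_phantom(arr, side$voxel_size, side$origin,
              meta = as.list(side$meta))
}
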