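test_that("the pixel-assignment rule honours the documented conventions", {
  # grid center and corner anchors
  px <- position_to_pixel(0, 0, 512, 2.6e-3)
  expect_equal(c(px$ix, px$iy), c(256, 256)) # 255.5 rounds away from zero
  corner <- position_to_pixel(-1.3e-3, -1.3e-3, 512, 2.6e-3)
  expect_equal(c(corner$ix, corner$iy), c(0, 0))
  expect_true(corner$inside)
  out <- position_to_pixel(1.4e-3, 0, 512, 2.6e-3)
  expect_false(out$inside) # flagged, not dropped
  # double-implementation oracle on 1000 random positions
  withr::with_seed(11, {
    x <- runif(1000, -1.4e-3, 1.4e-3)
    y <- runif(1000, -1.4e-3, 1.4e-3)
  })
  got <- position_to_pixel(x, y, 512, 2.6e-3)
  want <- pixel_oracle(x, y, 512, 2.6e-3)
  expect_identical(got$ix, want$ix)
  expect_identical(got$iy, want$iy)
})

test_that("the three-case assignment rule is exact on toy sample sets", {
  g <- 8; fov <- 8e-4 # pixel pitch ~114 um
  st <- acquisition_settings(record_length = 16L)
  pc <- function(i) i / (g - 1) * fov - fov / 2
  u <- sin(seq_len(16)); v <- cos(seq_len(16))
  # case 1: single sample -> trace copied verbatim
  s1 <- make_sample_set(tibble::tibble(x = pc(2), y = pc(3)),
                        matrix(u, 1), st)
  vol1 <- grid_assign(s1, g, fov)
  expect_identical(vol1$data[3, 4, ], u)
  expect_true(vol1$fill_mask[3, 4])
  # case 2: two samples in one pixel -> element-wise mean
  s2 <- make_sample_set(
    tibble::tibble(x = c(pc(2), pc(2) + 1e-6), y = rep(pc(3), 2)),
    rbind(u, v), st)
  vol2 <- grid_assign(s2, g, fov)
  expect_equal(vol2$data[3, 4, ], (u + v) / 2)
  # case 3: empty pixel equidistant between two filled neighbours
  s3 <- make_sample_set(
    tibble::tibble(x = c(pc(2), pc(4)), y = c(pc(3), pc(3))),
    rbind(u, v), st)
  vol3 <- grid_assign(s3, g, fov, k_neighbors = 2, idw_power = 1)
  expect_equal(vol3$data[4, 4, ], (u + v) / 2)
  vol3b <- grid_assign(s3, g, fov, k_neighbors = 2, idw_power = 3)
  expect_equal(vol3b$data[4, 4, ], (u + v) / 2) # symmetric for any power
  expect_false(vol3$fill_mask[4, 4])
  # empty sample set errors
  expect_error(grid_assign(make_sample_set(tibble::tibble(x = numeric(),
                                                          y = numeric()),
                                           matrix(0, 0, 16), st), g, fov),
               class = "spiralpam_reconstruction_error")
})

test_that("pixel-center samples reconstruct idempotently", {
  g <- 6; fov <- 6e-4
  st <- acquisition_settings(record_length = 8L)
  pc <- function(i) i / (g - 1) * fov - fov / 2
  grid <- expand.grid(ix = 0:(g - 1), iy = 0:(g - 1))
  traces <- matrix(rnorm(nrow(grid) * 8), nrow(grid))
  s <- make_sample_set(tibble::tibble(x = pc(grid$ix), y = pc(grid$iy)),
                       traces, st)
  vol <- grid_assign(s, g, fov)
  for (r in seq_len(nrow(grid))) {
    expect_equal(vol$data[grid$ix[r] + 1, grid$iy[r] + 1, ], traces[r, ])
  }
  # conservation: every sample contributed to exactly one direct pixel
  expect_equal(sum(vol$fill_mask), nrow(grid))
})

test_that("interpolated traces stay inside their neighbours' range", {
  g <- 16; fov <- 1.6e-3
  st <- acquisition_settings(record_length = 8L)
  withr::with_seed(5, {
    pos <- tibble::tibble(x = runif(40, -fov / 2, fov / 2),
                          y = runif(40, -fov / 2, fov / 2))
    traces <- matrix(runif(40 * 8), 40)
  })
  s <- make_sample_set(pos, traces, st)
  vol <- grid_assign(s, g, fov, k_neighbors = 4)
  disc <- spiralpam:::fov_disc_mask(g, fov)
  flat <- matrix(vol$data, g * g, 8)
  filled_vals <- flat[which(vol$fill_mask), , drop = FALSE]
  lo <- apply(filled_vals, 2, min); hi <- apply(filled_vals, 2, max)
  for (i in which(disc & !vol$fill_mask)) {
    expect_true(all(flat[i, ] >= lo - 1e-12 & flat[i, ] <= hi + 1e-12))
  }
})

test_that("the Hilbert envelope behaves like an analytic magnitude", {
  n <- 1024
  tt <- seq_len(n)
  x <- 3 * cos(2 * pi * (72 / n) * tt) # integer cycle count: no leakage
  env <- envelope(x)
  interior <- 100:(n - 100)
  expect_equal(env[interior], rep(3, length(interior)), tolerance = 1e-3)
  expect_true(all(env >= abs(x) - 1e-9))
  # Gaussian-modulated tone recovers its envelope within 1% away from edges
  sig <- 60
  gauss <- exp(-(tt - n / 2)^2 / (2 * sig^2))
  xm <- gauss * cos(2 * pi * 0.12 * tt)
  envm <- envelope(xm)
  core <- abs(tt - n / 2) < 2.5 * sig
  expect_lt(max(abs(envm[core] - gauss[core]) / max(gauss)), 0.01)
})

test_that("projections find points at the right place and depth", {
  g <- 12
  vol_arr <- array(0, dim = c(g, g, 64))
  vol_arr[5, 8, 33] <- 1
  m <- map_projection(vol_arr, pixel_size = 1e-5)
  expect_equal(which(m$data == max(m$data), arr.ind = TRUE)[1, ],
               c(row = 5, col = 8))
  expect_equal(sum(m$data > 0.5 * max(m$data)), 1)
  d <- depth_encode(vol_arr, pixel_size = 1e-5)
  expect_equal(d$data[5, 8], 32) # 0-based depth index of the maximum
  expect_true(all(is.na(d$data[-5, ])))
  # all-background case
  d0 <- depth_encode(array(0, dim = c(4, 4, 8)), pixel_size = 1e-5)
  expect_true(all(is.na(d0$data)))
  # MAP is invariant to circular depth shifts of a trace
  shifted <- vol_arr
  shifted[5, 8, ] <- vol_arr[5, 8, c(33:64, 1:32)]
  m2 <- map_projection(shifted, pixel_size = 1e-5)
  expect_equal(max(m2$data), max(m$data), tolerance = 1e-9)
})

test_that("a two-layer phantom yields a bimodal depth histogram", {
  g <- 16
  arr <- array(0, dim = c(g, g, 64))
  arr[1:8, , 21] <- 1
  arr[9:16, , 41] <- 1
  d <- depth_encode(arr, pixel_size = 1e-5)
  tab <- table(d$data)
  expect_setequal(as.integer(names(tab)), c(20, 40))
  expect_equal(unname(as.integer(tab)), c(8 * g, 8 * g))
})

test_that("dense sampling recovers the grid-target pitch within a pixel", {
  g <- 96; fov <- (96 - 1) * 5e-6 # pixel centers coincide with voxel centers
  vxl <- c(5e-6, 5e-6, 5e-6)
  ph <- make_grid_target(c(g, g, 16), vxl, pitch = 80e-6, bar_width = 20e-6,
                         depth = 8)
  st <- acquisition_settings(record_length = 32L, focal_spot_sigma = 2e-6)
  pc <- function(i) i / (g - 1) * fov - fov / 2
  pts <- expand.grid(ix = 0:(g - 1), iy = 0:(g - 1))
  sset <- acquire_at(tibble::tibble(x = pc(pts$ix), y = pc(pts$iy)), ph,
                     settings = st)
  vol <- grid_assign(sset, g, fov)
  m <- map_projection(vol)
  # profile across the bars, away from the orthogonal bar crossings
  profile <- m$data[, 40]
  peaks <- which(profile > 0.7 * max(profile))
  starts <- peaks[c(TRUE, diff(peaks) > 1)]
  expect_equal(diff(starts), rep(16, length(starts) - 1), tolerance = 1 / 16)
})
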