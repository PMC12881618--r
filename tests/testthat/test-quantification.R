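test_that("a Gaussian-blurred edge yields the analytic lateral FWHM", {
  px_size <- 1e-6
  xi <- 1:128
  sigma_px <- 3 # 3.0 um blur
  esf <- 0.1 + 0.8 * pnorm((xi - 64.3) / sigma_px)
  img <- matrix(rep(esf, 32), nrow = 128)
  res <- lateral_resolution(img, px_size)
  expect_equal(res$fwhm, 2 * sqrt(2 * log(2)) * 3e-6, tolerance = 1e-6)
  expect_equal(res$fwhm, 7.06e-6, tolerance = 1e-3)
  expect_equal(res$kind, "lateral")
  # flipping the edge direction leaves the width unchanged
  res_flipped <- lateral_resolution(img[128:1, ], px_size)
  expect_equal(res_flipped$fwhm, res$fwhm, tolerance = 1e-9)
  # an edge along the other axis via edge_axis
  res_y <- lateral_resolution(t(img), px_size, edge_axis = "y")
  expect_equal(res_y$fwhm, res$fwhm, tolerance = 1e-9)
  expect_error(lateral_resolution(matrix(1, 16, 16), px_size),
               class = "spiralpam_degenerate_input")
})

test_that("noisy edges are recovered without bias and bad fits rejected", {
  px_size <- 1e-6
  xi <- 1:128
  esf <- pnorm((xi - 64) / 3)
  fwhms <- withr::with_seed(21, {
    replicate(100, {
      noisy <- esf + rnorm(128, 0, 0.1) # SNR ~ 20 dB
      img <- matrix(rep(noisy, 8), nrow = 128) +
        matrix(rnorm(128 * 8, 0, 0.1), 128)
      lateral_resolution(img, px_size, rmse_threshold = 0.3)$fwhm
    })
  })
  expect_lt(abs(mean(fwhms) - 7.06e-6) / 7.06e-6, 0.05)
  withr::with_seed(3, {
    junk <- matrix(runif(64 * 8), 64)
  })
  junk[50:64, ] <- junk[50:64, ] + 1 # a step buried in heavy noise
  expect_error(lateral_resolution(junk, px_size, rmse_threshold = 0.01),
               class = "spiralpam_fit_error")
})

test_that("axial FWHM of a Gaussian-envelope pulse is exact", {
  st <- acquisition_settings()
  sigma_t <- 13.29e-9
  x <- gauss_pulse(st$sampling_rate, sigma_t, f0 = 60e6)
  res <- axial_resolution(x, st)
  expect_equal(res$fwhm, 2 * sqrt(2 * log(2)) * sigma_t * 1500,
               tolerance = 1e-3)
  expect_equal(res$kind, "axial")
  # carrier phase rotation leaves the envelope width unchanged
  n <- length(x)
  tt <- (0:(n - 1)) / st$sampling_rate
  x_rot <- exp(-(tt - 6 * sigma_t)^2 / (2 * sigma_t^2)) *
    cos(2 * pi * 60e6 * (tt - 6 * sigma_t) + 1.1)
  expect_equal(axial_resolution(x_rot, st)$fwhm, res$fwhm, tolerance = 1e-3)
})

test_that("SNR follows the peak-over-noise-sd definition", {
  withr::with_seed(9, {
    img <- matrix(rnorm(64 * 64, 0, 1), 64)
  })
  img[30:34, 30:34] <- 100
  sig_roi <- list(rows = 28:36, cols = 28:36)
  noise_roi <- list(rows = 1:20, cols = 1:20)
  got <- snr_db(img, sig_roi, noise_roi)
  expect_equal(got, 20 * log10(100 / sd(img[1:20, 1:20])), tolerance = 1e-9)
  expect_equal(got, 40, tolerance = 0.02) # sd ~ 1 by construction
  # gain invariance
  expect_equal(snr_db(img * 7.3, sig_roi, noise_roi), got, tolerance = 1e-9)
  expect_error(snr_db(matrix(1, 8, 8), list(rows = 1:2, cols = 1:2),
                      list(rows = 5:6, cols = 5:6)),
               class = "spiralpam_degenerate_input")
})

test_that("synthetic noise injections are recovered in the SNR", {
  st <- acquisition_settings(record_length = 1024L, noise_sigma = 0.01,
                             seed = 13L)
  ph <- make_point_target(c(64, 64, 64), c(5e-6, 5e-6, 3e-6),
                          tibble::tibble(ix = 31, iy = 31, iz = 30))
  a <- simulate_ascan(ph, c(0, 0), settings = st)
  peak <- max(abs(a$amplitude))
  snr_expect <- 20 * log10(peak / 0.01)
  noise_part <- a$amplitude[200:1024] # well past the arrival
  got <- 20 * log10(peak / sd(noise_part))
  expect_lt(abs(got - snr_expect), 0.5)
})

test_that("vessel masks behave for fixed and Otsu thresholds", {
  expect_error(vessel_mask(matrix(0.5, 16, 16)),
               class = "spiralpam_degenerate_input")
  bin <- matrix(c(0, 1)[1 + (matrix(1:256, 16) %% 3 == 0)], 16)
  expect_identical(unclass(vessel_mask(bin, "fixed", 0.5)) * 1,
                   bin, ignore_attr = TRUE)
  # Otsu separates a bimodal image like the fixed mid threshold
  withr::with_seed(2, {
    img <- matrix(rnorm(4096, 0.2, 0.03), 64)
  })
  img[20:40, 20:40] <- rnorm(441, 0.8, 0.03)
  mo <- vessel_mask(img, "otsu")
  mf <- vessel_mask(img, "fixed", 0.5)
  expect_gt(mean(mo == mf), 0.999)
})

test_that("densely sampled vessel phantoms threshold to their ground truth", {
  vxl <- c(2.6e-3 / 63, 2.6e-3 / 63, 6e-6)
  ph <- make_vessel_phantom(
    vessel_tree_params(n_roots = 2, diameter_range = c(2.5e-4, 4e-4),
                       seed = 4),
    shape = c(64, 64, 32), voxel_size = vxl)
  g <- 64; fov <- (g - 1) * vxl[1]
  pc <- function(i) i / (g - 1) * fov - fov / 2
  pts <- expand.grid(ix = 0:(g - 1), iy = 0:(g - 1))
  st <- acquisition_settings(record_length = 64L, focal_spot_sigma = 15e-6)
  sset <- acquire_at(tibble::tibble(x = pc(pts$ix), y = pc(pts$iy)), ph,
                     settings = st)
  m <- map_projection(grid_assign(sset, g, fov))
  mask <- vessel_mask(m)
  truth <- apply(unclass(ph), c(1, 2), max) > 0
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.8)
})

test_that("morphometric indices satisfy their algebra and limits", {
  px_size <- 5e-6
  # full frame
  full <- matrix(TRUE, 64, 64)
  expect_equal(vessel_metrics(full, px_size)$vad, 1.0)
  # empty mask
  vm0 <- vessel_metrics(matrix(FALSE, 64, 64), px_size)
  expect_equal(vm0$vad, 0)
  expect_true(is.na(vm0$vdi))
  # large digital disc: isoperimetric identity within 5%
  g <- 256
  cc <- outer((1:g - 128.5)^2, (1:g - 128.5)^2, "+")
  disc <- cc <= 110^2
  vmd <- vessel_metrics(disc, px_size)
  expect_equal(vmd$vci, 1.0, tolerance = 0.05)
  # straight bar: analytic width and length
  bar <- matrix(FALSE, 420, 60)
  bar[11:410, 21:40] <- TRUE # 400 x 20 px
  vmb <- vessel_metrics(bar, px_size)
  expect_equal(vmb$vdi, 20 * px_size, tolerance = 0.1)
  expect_equal(vmb$vsd, 400 * px_size / (420 * 60 * px_size^2),
               tolerance = 0.1)
  expect_equal(vmb$vdi * vmb$vsd, vmb$vad, tolerance = 1e-12)
  # the identity also holds on an irregular mask with a real skeleton
  withr::with_seed(17, {
    blob <- make_vessel_phantom(vessel_tree_params(seed = 17),
                                shape = c(96, 96, 32),
                                voxel_size = c(5e-6, 5e-6, 5e-6))
  })
  mask <- apply(unclass(blob), c(1, 2), max) > 0
  vmv <- vessel_metrics(mask, px_size)
  expect_equal(vmv$vdi * vmv$vsd, vmv$vad, tolerance = 1e-12)
})

test_that("VAD is rotation invariant and VCI scale-stable on discs", {
  withr::with_seed(31, {
    m <- matrix(runif(64 * 64) > 0.8, 64)
  })
  px_size <- 5e-6
  expect_equal(vessel_metrics(m, px_size)$vad,
               vessel_metrics(t(m[64:1, ]), px_size)$vad) # 90 deg rotation
  # digital disc VCI approaches 1 from above as radius grows
  vci_of <- function(r, g) {
    cc <- outer((1:g - (g + 1) / 2)^2, (1:g - (g + 1) / 2)^2, "+")
    vessel_metrics(cc <= r^2, px_size)$vci
  }
  v <- c(vci_of(20, 64), vci_of(60, 160), vci_of(110, 256))
  expect_lt(abs(v[3] - 1), abs(v[1] - 1) + 0.02)
  expect_true(all(abs(v - 1) < 0.08))
})

test_that("the diameter split separates macro from micro vessels", {
  px_size <- 5e-6
  bar50 <- matrix(FALSE, 80, 40); bar50[11:70, 16:25] <- TRUE # 50 um wide
  sp <- diameter_split(bar50, px_size)
  expect_equal(sum(sp$macro), 0)
  expect_equal(sp$micro, unclass(bar50), ignore_attr = TRUE)
  bar150 <- matrix(FALSE, 80, 60); bar150[11:70, 16:45] <- TRUE # 150 um
  sp2 <- diameter_split(bar150, px_size)
  expect_equal(sum(sp2$micro), 0)
  # two parallel bars, 60 um and 160 um: at most 2% mixing
  two <- matrix(FALSE, 100, 80)
  two[11:90, 11:22] <- TRUE  # 12 px = 60 um
  two[11:90, 41:72] <- TRUE  # 32 px = 160 um
  sp3 <- diameter_split(two, px_size)
  micro_truth <- two & col(two) <= 22
  macro_truth <- two & col(two) >= 41
  expect_lt(mean(sp3$micro[micro_truth] == FALSE), 0.02)
  expect_lt(mean(sp3$macro[macro_truth] == FALSE), 0.02)
})

test_that("frame series report densities and dB changes", {
  base <- matrix(0.02, 64, 64)
  base[20:44, 10:54] <- 1
  frames <- list(base, base, base)
  fs <- timeseries_quantify(frames, mask_method = "fixed", threshold = 0.5)
  expect_equal(fs$vessel_density, rep(mean(base > 0.5), 3))
  expect_equal(fs$mean_amplitude_db, c(0, 0, 0))
  # halving the amplitude reads -6.02 dB
  fs2 <- timeseries_quantify(list(base, base * 0.5),
                             mask_method = "fixed", threshold = 0.25)
  expect_equal(fs2$mean_amplitude_db[2], 20 * log10(0.5), tolerance = 1e-9)
})

test_that("a constructed constriction sequence is recovered", {
  # vessel widths shrunk to 40% of baseline (a 60% constriction)
  mk_frame <- function(w) {
    m <- matrix(0.01, 128, 128)
    for (cy in c(20, 50, 80, 110)) {
      m[10:118, (cy - w / 2):(cy + w / 2 - 1)] <- 1
    }
    m
  }
  frames <- list(mk_frame(20), mk_frame(8))
  fs <- timeseries_quantify(frames, mask_method = "fixed", threshold = 0.5)
  drop_constructed <- (sum(mk_frame(20) > 0.5) - sum(mk_frame(8) > 0.5)) /
    length(mk_frame(20))
  drop_recovered <- fs$vessel_density[1] - fs$vessel_density[2]
  expect_lt(abs(drop_recovered - drop_constructed), 0.05)
})
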