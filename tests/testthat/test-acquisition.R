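vx <- c(5e-6, 5e-6, 3e-6)
shape <- c(64, 64, 64)
st <- acquisition_settings(record_length = 256L)

test_that("an empty phantom produces a silent A-scan", {
  ph <- pam_phantom(array(0, shape), vx)
  a <- simulate_ascan(ph, c(0, 0), settings = st)
  expect_true(all(a$amplitude == 0))
  expect_equal(nrow(a), 256)
})

test_that("a point absorber arrives at the one-way time of flight", {
  pos <- tibble::tibble(ix = 31, iy = 31, iz = 39)
  ph <- make_point_target(shape, vx, pos)
  org <- attr(ph, "origin")
  z <- org[3] + 39 * vx[3]
  beam <- c(org[1] + 31 * vx[1], org[2] + 31 * vx[2])
  a <- simulate_ascan(ph, beam, impulse = NULL, settings = st)
  k <- which(a$amplitude > 0.5 * max(a$amplitude))
  expect_equal(k - 1, round(z / st$speed_of_sound * st$sampling_rate))
  expect_length(which(a$amplitude != 0), 1)
})

test_that("a band-limited impulse lands with its envelope shape intact", {
  pos <- tibble::tibble(ix = 31, iy = 31, iz = 30)
  ph <- make_point_target(shape, vx, pos)
  org <- attr(ph, "origin")
  z <- org[3] + 30 * vx[3]
  beam <- c(org[1] + 31 * vx[1], org[2] + 31 * vx[2])
  imp <- gauss_pulse(st$sampling_rate, sigma_t = 16e-9, f0 = 35e6)
  a <- simulate_ascan(ph, beam, impulse = imp, settings = st)
  env <- envelope(a)
  fwhm_interp <- function(e, dt = 1) { # half-max width via crossings
    e <- e / max(e)
    i0 <- which.max(e)
    lo <- max(which(e[1:i0] <= 0.5))
    hi <- i0 - 1 + min(which(e[i0:length(e)] <= 0.5))
    left <- approx(e[c(lo, lo + 1)], c(lo, lo + 1), 0.5)$y
    right <- approx(e[c(hi - 1, hi)], c(hi - 1, hi), 0.5)$y
    (right - left) * dt
  }
  # peak within one sample of t = z/c plus the impulse's own peak delay
  t_imp_peak <- (which.max(envelope(imp)) - 1) / st$sampling_rate
  expect_lte(abs((which.max(env) - 1) / st$sampling_rate -
                   (z / st$speed_of_sound + t_imp_peak)),
             1 / st$sampling_rate)
  # envelope width equals the impulse envelope width; cross-check against a
  # direct convolution oracle at 10x oversampling
  fs10 <- 10 * st$sampling_rate
  imp10 <- gauss_pulse(fs10, sigma_t = 16e-9, f0 = 35e6)
  line10 <- numeric(10 * 256)
  line10[round(z / st$speed_of_sound * fs10) + 1] <- 1
  conv10 <- stats::convolve(line10, rev(imp10), type = "open")[1:(10 * 256)]
  env10 <- envelope(conv10)
  expect_equal(fwhm_interp(env), fwhm_interp(env10, dt = 0.1),
               tolerance = 0.05)
  expect_equal(fwhm_interp(env), fwhm_interp(envelope(imp)),
               tolerance = 0.05)
})

test_that("the forward model is linear and scales with absorption", {
  pa <- make_point_target(shape, vx, tibble::tibble(ix = 20, iy = 31, iz = 20))
  pb <- make_point_target(shape, vx, tibble::tibble(ix = 40, iy = 31, iz = 45))
  both <- pam_phantom(pmin(unclass(pa) + unclass(pb), 1), vx)
  a <- simulate_ascan(pa, c(0, 0), settings = st)$amplitude
  b <- simulate_ascan(pb, c(0, 0), settings = st)$amplitude
  ab <- simulate_ascan(both, c(0, 0), settings = st)$amplitude
  expect_equal(ab, a + b, tolerance = 1e-12)
  half <- pam_phantom(unclass(pa) * 0.5, vx)
  expect_equal(simulate_ascan(half, c(0, 0), settings = st)$amplitude,
               a / 2, tolerance = 1e-12)
})

test_that("noise is reproducible under the seed", {
  ph <- make_point_target(shape, vx, tibble::tibble(ix = 31, iy = 31, iz = 30))
  sn <- acquisition_settings(record_length = 128L, noise_sigma = 0.05,
                             seed = 7L)
  a1 <- simulate_ascan(ph, c(0, 0), settings = sn)
  a2 <- simulate_ascan(ph, c(0, 0), settings = sn)
  expect_identical(a1$amplitude, a2$amplitude)
  sn2 <- sn; sn2$seed <- 8L
  expect_false(identical(a1$amplitude,
                         simulate_ascan(ph, c(0, 0), settings = sn2)$amplitude))
})

test_that("a uniform slab looks identical from interior beam positions", {
  vol <- array(0, dim = c(96, 96, 32))
  vol[, , 16] <- 1
  ph <- pam_phantom(vol, vx)
  sset <- acquire_at(tibble::tibble(x = c(0, 3e-5, -4e-5), y = c(0, 2e-5, 1e-5)),
                     ph, settings = st)
  expect_equal(sset$ascans[2, ], sset$ascans[1, ], tolerance = 1e-9)
  expect_equal(sset$ascans[3, ], sset$ascans[1, ], tolerance = 1e-9)
})

test_that("acquire follows the trigger train and handles the empty case", {
  ph <- make_point_target(shape, vx, tibble::tibble(ix = 31, iy = 31, iz = 30))
  tr <- parked_trajectory(0, 0)
  empty <- acquire(tr, prf_schedule(numeric(), numeric(), numeric()), ph,
                   settings = st)
  expect_equal(nrow(empty$ascans), 0)
  got <- acquire(tr, prf_schedule(0, 0.5, 20), ph, settings = st)
  expect_equal(nrow(got$ascans), 10)
  expect_true(all(got$positions$x == 0))
})

test_that("beam positions outside the phantom are rejected", {
  ph <- make_point_target(shape, vx, tibble::tibble(ix = 1, iy = 1, iz = 1))
  expect_error(simulate_ascan(ph, c(1, 0), settings = st),
               class = "spiralpam_range_error")
})

test_that("a too-short record warns about truncation", {
  ph <- make_point_target(shape, vx, tibble::tibble(ix = 31, iy = 31, iz = 60))
  short <- acquisition_settings(record_length = 8L)
  expect_warning(simulate_ascan(ph, c(0, 0), settings = short),
                 class = "spiralpam_truncation_warning")
})

test_that("sample sets round-trip through the container files", {
  ph <- make_point_target(shape, vx, tibble::tibble(ix = 31, iy = 31, iz = 30))
  sset <- acquire_at(tibble::tibble(x = c(0, 1e-5), y = c(0, 0)), ph,
                     settings = acquisition_settings(record_length = 64L))
  stem <- file.path(withr::local_tempdir(), "samples")
  write_sample_set(sset, stem)
  back <- read_sample_set(stem)
  expect_equal(back$ascans, sset$ascans)
  expect_equal(back$positions$x, sset$positions$x)
})
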