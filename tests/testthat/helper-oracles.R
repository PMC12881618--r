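# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation:
# - the beam eigenfrequency comes from a finite-difference discretization of
#   the Euler-Bernoulli operator, not the closed-form mode constant;
# - the transducer response comes from the Mason impedance-matrix three-port
#   solved as a dense linear system per frequency, not the KLM circuit.

# smallest clamped-free eigenfrequency of a uniform circular cantilever,
# 5-point finite differences with ghost-node boundary conditions and
# Richardson extrapolation over two mesh sizes
beam_eigen_freq <- function(E, rho, R, L, n = 400) {
  lam <- function(n) {
    h <- L / n
    A <- matrix(0, n, n)
    add <- function(i, j, v) {
      if (j >= 1 && j <= n) A[i, j] <<- A[i, j] + v
    }
    for (i in 1:n) {
      # w'''' stencil at x_i, unknowns w_1..w_n (w_0 = 0 clamped)
      coef <- c(1, -4, 6, -4, 1)
      idx <- (i - 2):(i + 2)
      for (k in seq_along(idx)) {
        j <- idx[k]
        v <- coef[k]
        if (j == 0) next                      # w_0 = 0
        if (j == -1) { add(i, 1, v); next }   # w'(0) = 0 -> w_{-1} = w_1
        if (j == n + 1) {                     # w''(L) = 0 -> ghost
          add(i, n, 2 * v); add(i, n - 1, -v); next
        }
        if (j == n + 2) {                     # w'''(L) = 0 -> ghost
          # w_{n+2} = 2 w_{n+1} - 2 w_{n-1} + w_{n-2}, with w_{n+1} as above
          add(i, n, 4 * v); add(i, n - 1, -4 * v); add(i, n - 2, v); next
        }
        add(i, j, v)
      }
    }
    ev <- eigen(A / h^4, only.values = TRUE)$values
    min(Re(ev[abs(Im(ev)) < 1e-6 * max(abs(ev))]))
  }
  l1 <- lam(n %/% 2)
  l2 <- lam(n)
  l_ext <- (4 * l2 - l1) / 3 # O(h^2) Richardson
  I <- pi * R^4 / 4
  Ac <- pi * R^2
  sqrt(l_ext * E * I / (rho * Ac)) / (2 * pi)
}

# Mason-model transfer functions of a piezo plate with optional front
# matching layers; all quantities per unit source volt / unit incident force
mason_transfer <- function(piezo, d_piezo, area, f, rs = 50,
                           front_layers = NULL,
                           z_front_load_mrayl = 1.5,
                           z_back_mrayl = 3.05) {
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * f
  zc <- function(v, rho) rho * v * area
  line_T <- function(v, rho, d, wi) {
    g <- wi * d / v
    Z <- zc(v, rho)
    matrix(c(cos(g), 1i * sin(g) / Z, 1i * Z * sin(g), cos(g)), 2, 2)
  }
  zp <- zc(piezo$v, piezo$rho)
  c0 <- piezo$epsr * eps0 * area / d_piezo
  h <- piezo$kt * sqrt(piezo$rho * piezo$v^2 / (piezo$epsr * eps0))
  zl <- z_front_load_mrayl * 1e6 * area
  zb <- z_back_mrayl * 1e6 * area
  ht <- hr <- complex(length(w))
  for (i in seq_along(w)) {
    Tf <- diag(2)
    if (!is.null(front_layers)) {
      for (k in seq_len(nrow(front_layers))) {
        Tf <- Tf %*% line_T(front_layers$longitudinal_velocity[k],
                            front_layers$density[k],
                            front_layers$thickness[k], w[i])
      }
    }
    zfront <- (Tf[1, 1] * zl + Tf[1, 2]) / (Tf[2, 1] * zl + Tf[2, 2])
    g <- w[i] * d_piezo / piezo$v
    z11 <- zp / (1i * tan(g)); z12 <- zp / (1i * sin(g))
    zh <- h / (1i * w[i]); ze <- 1 / (1i * w[i] * c0)
    M <- matrix(c(z11 + zb, z12, zh,
                  z12, z11 + zfront, zh,
                  zh, zh, ze + rs), 3, 3, byrow = TRUE)
    s <- solve(M, c(0, 0, 1))
    uin <- -s[2]
    out <- solve(Tf, c(zfront * uin, uin))
    ht[i] <- out[1]
    fw <- Tf[2, 2] / (Tf[2, 2] + zl * Tf[2, 1])
    uw <- -(Tf[2, 1] / Tf[2, 2]) * fw
    fth <- Tf[1, 1] * fw + Tf[1, 2] * uw
    M2 <- matrix(c(z11 + zb, z12, zh,
                   z12, z11 + zfront, zh,
                   zh, zh, ze + rs), 3, 3, byrow = TRUE)
    s2 <- solve(M2, c(0, fth, 0))
    hr[i] <- -rs * s2[3]
  }
  list(transmit = ht, receive = hr, two_way = ht * hr)
}

# independent re-implementation of the affine + round-half-away pixel rule
pixel_oracle <- function(x, y, grid_size, fov) {
  cont_x <- (x + fov / 2) / fov * (grid_size - 1)
  cont_y <- (y + fov / 2) / fov * (grid_size - 1)
  raw <- function(v) as.integer(trunc(abs(v) + 0.5) * ifelse(v < 0, -1, 1))
  list(ix = raw(cont_x), iy = raw(cont_y))
}

# a parked "trajectory": constant position over a time span, with the class
# and attributes density_map()/trigger_train() expect
parked_trajectory <- function(x, y, t_max = 1, n = 1001) {
  tr <- tibble::tibble(time = seq(0, t_max, length.out = n),
                       x = rep(x, n), y = rep(y, n),
                       phase = factor(rep("imaging", n),
                                      levels = c("imaging", "braking", "decay")))
  class(tr) <- c("pam_trajectory", class(tr))
  tr
}

# Gaussian-enveloped tone sampled at fs
gauss_pulse <- function(fs, sigma_t, f0, t0 = 6 * sigma_t,
                        n = ceiling(2 * t0 * fs)) {
  tt <- (0:(n - 1)) / fs
  exp(-(tt - t0)^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * (tt - t0))
}

make_sample_set <- function(positions, ascans,
                            settings = acquisition_settings()) {
  structure(list(positions = tibble::as_tibble(positions),
                 ascans = ascans, settings = settings),
            class = "pam_sample_set")
}
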