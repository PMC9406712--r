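test_that("apodization window has plateau, zero corners and rectangular
           limit", {
  h <- hologram(matrix(1, 32, 32), 0.1)
  expect_equal(apodize(h, 0)$intensity, h$intensity)
  a <- apodize(h, 0.3)
  expect_equal(a$intensity[1, 1], 0)
  expect_equal(a$intensity[16, 16], 1)
  expect_error(apodize(h, 1.5), "taper_fraction")
})

test_that("demodulation recovers a flat field as constant phase and rejects
           missing carriers", {
  n <- 128L
  U <- complex_field(matrix(1 + 0i, n, n), 0.1)
  h <- synthesize_hologram(U, carrier = c(24, 24) / n)
  u2 <- demodulate(h)
  inner <- 9:120
  ph <- Arg(u2$field)[inner, inner]
  expect_lt(max(abs(ph - mean(ph))), 1e-3)
  # no off-axis order in a plain intensity image
  expect_error(demodulate(hologram(matrix(1, n, n), 0.1)), "no carrier")
  # explicit carrier below the separation bound
  expect_error(demodulate(h, order_center = c(0.02, 0.02),
                          crop_radius = 0.1), "separation")
})

test_that("angular-spectrum propagation is the identity at dz = 0 and unitary
           on a round trip", {
  set.seed(11)
  n <- 64L
  raw <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  u <- complex_field(raw, 0.1)
  expect_identical(propagate_angular_spectrum(u, 0)$field, u$field)
  # band-limit first so the round trip acts on propagating components only
  ub <- propagate_angular_spectrum(propagate_angular_spectrum(u, 1e-9), -1e-9)
  fwd <- propagate_angular_spectrum(ub, 7.3)
  back <- propagate_angular_spectrum(fwd, -7.3)
  expect_lt(max(Mod(back$field - ub$field)), 1e-10)
  expect_error(propagate_angular_spectrum(u, Inf), "finite")
})

test_that("on-axis plane wave advances by the expected global phase", {
  n <- 32L
  u <- complex_field(matrix(1 + 0i, n, n), 0.1)
  dz <- 3.7; lam <- 0.488
  p <- propagate_angular_spectrum(u, dz, lam)
  expect_equal(Mod(p$field), matrix(1, n, n), tolerance = 1e-12)
  delta <- Arg(p$field[1, 1]) - (2 * pi * dz / lam) %% (2 * pi)
  expect_lt(min(abs(delta - c(-2 * pi, 0, 2 * pi))), 1e-9)
})

test_that("Tamura coefficient is sd over mean, scale invariant", {
  a <- matrix(c(1, 1, 3, 3), 2, 2)
  expect_equal(tamura_coefficient(a), 0.5)
  expect_equal(tamura_coefficient(a, sqrt_form = TRUE), sqrt(0.5))
  expect_equal(tamura_coefficient(matrix(2, 4, 4)), 0)
  expect_equal(tamura_coefficient(7 * a), tamura_coefficient(a))
  expect_error(tamura_coefficient(matrix(0, 3, 3)), "zero-mean")
})

test_that("autofocus recovers a constructed defocus within one grid step", {
  n <- 128L
  xg <- matrix(seq(-1, 1, length.out = n), n, n)
  phase <- 1.5 * exp(-(xg^2 + t(xg)^2) / 0.08)
  u0 <- complex_field(exp(1i * phase), 0.1)
  u_def <- propagate_angular_spectrum(u0, 20)
  z <- autofocus(u_def, seq(-30, 30, by = 1))
  expect_lte(abs(as.numeric(z) - (-20)), 1)
  # Tamura landscape has a unique interior minimum for a compact object
  tc <- attr(z, "tc_profile")$tc
  expect_equal(sum(diff(sign(diff(tc))) > 0), 1)
  # in-focus input on a symmetric grid focuses at zero
  z0 <- autofocus(u0, seq(-10, 10, by = 2))
  expect_equal(as.numeric(z0), 0)
  expect_equal(as.numeric(autofocus(u0, 4.2)), 4.2)
})

test_that("reference compensation cancels a common aberration exactly", {
  set.seed(3)
  n <- 48L
  xg <- matrix(seq(-1, 1, length.out = n), n, n)
  aber <- exp(1i * (0.8 * xg^2 + 0.5 * t(xg)))
  obj <- exp(1i * 0.9 * exp(-(xg^2 + t(xg)^2) / 0.2))
  u <- complex_field(obj * aber, 0.1)
  uref <- complex_field(aber, 0.1)
  comp <- compensate_reference(u, uref)
  expect_lt(max(Mod(comp$field - obj)), 1e-10)
  self <- compensate_reference(u, u)
  expect_equal(Mod(self$field), matrix(1, n, n), tolerance = 1e-12)
  zero <- complex_field(matrix(0i, n, n), 0.1)
  expect_error(compensate_reference(u, zero), "pixel")
})

test_that("unwrapping recovers smooth surfaces and preserves congruence", {
  n <- 48L
  ramp <- outer(seq_len(n), seq_len(n), function(i, j) 0.5 * i + 0.2 * j)
  wrapped <- (ramp + pi) %% (2 * pi) - pi
  uw <- unwrap_phase(wrapped)$phase
  # recovered up to one global 2 pi k offset
  off <- mean(uw - ramp)
  expect_equal(off / (2 * pi), round(off / (2 * pi)), tolerance = 1e-9)
  expect_lt(rmse(uw - off, ramp), 1e-6)
  # congruence: rewrapping the output reproduces the input
  rewrap <- (uw + pi) %% (2 * pi) - pi
  expect_equal(rewrap, wrapped, tolerance = 1e-9)
  # an already-smooth map within (-pi, pi] is unchanged
  smooth <- 0.4 * outer(sin(seq_len(n) / 8), cos(seq_len(n) / 9))
  expect_equal(unwrap_phase(smooth)$phase, smooth, tolerance = 1e-9)
})

test_that("windowed-Fourier filtering is exact at zero threshold and reduces
           noise on a smooth surface", {
  set.seed(21)
  n <- 64L
  base <- outer(seq_len(n), seq_len(n), function(i, j)
    0.03 * i + 0.02 * j + 0.8 * sin(i / 12) * cos(j / 15))
  q0 <- qpm(base, 0.1)
  expect_lt(max(abs(wft_denoise(q0, threshold = 0)$phase - base)), 1e-10)
  noisy <- qpm(base + matrix(rnorm(n * n, 0, 0.3), n, n), 0.1)
  den <- wft_denoise(noisy)
  expect_lt(rmse(den$phase, base), rmse(noisy$phase, base))
  # distortion on noise-free input stays small
  expect_lt(rmse(wft_denoise(q0)$phase, base), 1e-2)
  expect_error(wft_denoise(q0, window_size = 128), "window larger")
})
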