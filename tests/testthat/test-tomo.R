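test_that("angle schedule reproduces the printed projection counts", {
  expect_length(angle_schedule(6), 60)
  expect_length(angle_schedule(16), 22)
  expect_equal(angle_schedule(16)[1], 0)
  expect_lt(max(angle_schedule(16)), 360)
})

test_that("sinogram assembly from tilted QPMs matches direct projection", {
  sp <- small_spec(seed = 6L, cl = 0.8)
  t0 <- generate_phantom(sp)
  angles <- seq(0, 330, by = 30)
  tilt <- 45
  n <- sp$grid_size
  N <- 72L
  pad <- (N - n) %/% 2
  qpms <- lapply(seq_along(angles), function(i) {
    pj <- project_phase(t0, angles[i])
    canvas <- matrix(0, N, N)
    canvas[pad + seq_len(n), pad + seq_len(n)] <- t(pj$phase)
    qpm(flowtomo:::rotate_image(canvas, tilt), sp$voxel_size, i)
  })
  # exact-center track isolates the de-tilt/crop/unit-conversion path from
  # the centroid wobble of textured projections
  s <- build_sinogram(qpms, angles, track = center_track(length(qpms), N),
                      tilt = tilt, crop_size = n * sp$voxel_size)
  ref <- project_sinogram(t0, angles)
  # de-tilt + crop + unit conversion agree with the direct forward model
  expect_lt(rmse(s$data, ref$data) / sd(ref$data), 0.02)
  # per-frame integral is angle-independent (mass conservation)
  m <- apply(s$data, 2, sum)
  expect_lt(max(abs(m - mean(m))) / mean(m), 1e-3)
})

test_that("zero tilt is crop-only sinogram assembly", {
  sp <- small_spec(seed = 6L)
  t0 <- generate_phantom(sp)
  angles <- c(0, 90, 180, 270)
  n <- sp$grid_size
  qpms <- lapply(seq_along(angles), function(i)
    qpm(t(project_phase(t0, angles[i])$phase), sp$voxel_size, i))
  s <- build_sinogram(qpms, angles, track = center_track(length(qpms), n),
                      tilt = 0, crop_size = n * sp$voxel_size)
  ref <- project_sinogram(t0, angles)
  expect_lt(rmse(s$data, ref$data) / sd(ref$data), 0.02)
})

test_that("FBP inverts dense-angle noise-free data", {
  t0 <- hard_sphere(n = 48L, voxel = 0.2, radius = 3.2, contrast = 0.02)
  s <- project_sinogram(t0, seq(0, 358, by = 2))
  r <- fbp_reconstruct(s)
  # RMSE below 5% of the disc contrast
  expect_lt(rmse(ri_contrast(r), ri_contrast(t0)), 0.05 * 0.02)
  # all-zero sinogram reconstructs to zero contrast
  z <- sinogram(array(0, c(4, 10, 32)), seq(0, 324, by = 36), 0.2)
  expect_equal(max(abs(ri_contrast(fbp_reconstruct(z)))), 0)
  expect_error(fbp_reconstruct(sinogram(array(0, c(4, 1, 32)), 10, 0.2)),
               "2 distinct angles")
})

test_that("FBP localizes a point-like inclusion to one voxel", {
  v <- array(1.334, c(3, 33, 33))
  v[2, 21, 14] <- 1.40
  t0 <- tomogram(v, 0.2)
  s <- project_sinogram(t0, seq(0, 350, by = 10))
  r <- fbp_reconstruct(s)
  peak <- which(ri_contrast(r) == max(ri_contrast(r)), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(2, 21, 14))), 1)
})

test_that("polynomial annihilation annihilates low-degree polynomials and has
           an exact adjoint", {
  const <- matrix(3.2, 12, 12)
  pa1 <- pa_transform(const, 1)
  expect_true(all(pa1$d1 == 0) && all(pa1$d2 == 0))
  ramp <- outer(1:12, 1:12, function(i, j) 2.5 * i - 1.3 * j + 0.7)
  pa2 <- pa_transform(ramp, 2)
  expect_lt(max(abs(c(pa2$d1, pa2$d2))), 1e-10)
  # k = 1 has nonzero response on the ramp (TV case)
  expect_gt(max(abs(pa_transform(ramp, 1)$d1)), 1)
  expect_error(pa_transform(matrix(0, 3, 3), 4), "extent")
  # adjoint identity <PA x, y> == <x, PA^T y> on random arrays
  set.seed(31)
  for (k in 1:4) {
    x <- matrix(rnorm(20 * 20), 20, 20)
    y <- pa_transform(matrix(rnorm(20 * 20), 20, 20), k)
    lhs <- sum(unlist(pa_transform(x, k)) * c(as.numeric(y$d1),
                                              as.numeric(y$d2)))
    # stack in the same component order as pa_transform output
    lhs <- sum(pa_transform(x, k)$d1 * y$d1) +
      sum(pa_transform(x, k)$d2 * y$d2)
    rhs <- sum(x * pa_adjoint(y, k))
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("projector and its transpose satisfy the adjoint identity", {
  set.seed(17)
  n <- 24L
  A <- flowtomo:::projector_matrix(n, c(0, 33.5, 121, 270.25))
  x <- rnorm(n * n)
  y <- rnorm(nrow(A))
  expect_lt(abs(sum((A %*% x) * y) - sum(x * Matrix::crossprod(A, y))),
            1e-10)
})

test_that("HOTV solves the TV-favourable piecewise-constant case", {
  t0 <- hard_sphere(n = 32L, voxel = 0.2, radius = 2.4, contrast = 0.02)
  s <- sinogram_via_projector(t0, angle_schedule(16))
  r <- hotv_reconstruct(s, hotv_config(order = 1, df = 96, beta = 4,
                                       outer_iterations = 100L,
                                       tolerance = 1e-7))
  expect_gt(ssim_3d(r, t0), 0.99)
})

test_that("order-2 HOTV beats order-1 on a smooth quadratic phantom at 22
           noisy angles", {
  n <- 40L
  g <- (seq_len(n) - (n + 1) / 2) * 0.2
  rx <- array(g, c(n, n, n)); ry <- aperm(rx, c(2, 1, 3))
  rz <- aperm(rx, c(3, 2, 1))
  rho2 <- (rx^2 + ry^2 + rz^2) / 3^2
  t0 <- tomogram(1.334 + 0.05 * pmax(1 - rho2, 0), 0.2)
  s <- project_sinogram(t0, angle_schedule(16), noise_sigma = 0.02,
                        seed = 44L)
  r1 <- suppressMessages(hotv_reconstruct(s, hotv_config(order = 1)))
  r2 <- suppressMessages(hotv_reconstruct(s, hotv_config(order = 2)))
  expect_gt(ssim_3d(r2, t0), ssim_3d(r1, t0))
})

test_that("non-negativity constraint and monotone objective hold", {
  ph <- generate_phantom(small_spec(seed = 19L))
  s <- project_sinogram(ph, angle_schedule(16), noise_sigma = 0.05,
                        seed = 3L)
  r <- suppressMessages(hotv_reconstruct(s, hotv_config(order = 2)))
  expect_gte(min(ri_contrast(r)), 0)
  cv <- attr(r, "convergence")
  obj <- cv$objective
  expect_true(all(diff(obj) <= 1e-6 * abs(obj[-length(obj)])))
  # solution is Radon-consistent within the solver residual
  rp <- project_sinogram(r, s$angles)
  expect_lt(rmse(rp$data, s$data), 2 * 0.05 * 0.488 / (2 * pi) + 0.01)
})

test_that("HOTV-1 agrees with an independent proximal-gradient TV oracle", {
  # common ground: a 2D disc slice, both solvers minimizing the same
  # objective (non-negativity off)
  n <- 48L
  ctr <- (n + 1) / 2
  disc <- 0.02 * (outer(seq_len(n), seq_len(n), function(i, j)
    (i - ctr)^2 + (j - ctr)^2) <= 14^2)
  angles <- angle_schedule(16)
  A <- flowtomo:::projector_matrix(n, angles)
  b <- as.numeric(A %*% as.numeric(disc))
  sdata <- array(0, c(1L, length(angles), n))
  sdata[1, , ] <- t(matrix(b, n, length(angles))) * 0.2
  s <- sinogram(sdata, angles, 0.2)
  cfg <- hotv_config(order = 1, df = 48, beta = 4, nonnegativity = FALSE,
                     outer_iterations = 200L, tolerance = 1e-8)
  r <- suppressMessages(hotv_reconstruct(s, cfg))
  rec <- ri_contrast(r)[1, , ]
  # oracle on the identical normalized objective
  sig <- flowtomo:::projector_norm(A)
  bscale <- max(abs(b))
  xo <- tv_prox_gradient(A / sig, b / bscale, mu = cfg$df, lambda = 1,
                         n = n, iters = 600, prox_iters = 60)
  xo <- matrix(xo, n, n) * bscale / sig
  expect_lt(rmse(rec, xo), 0.01 * 0.02)
})

test_that("solver dispatcher and benchmark table cover the solver family", {
  sp <- phantom_spec(grid_size = 24L, voxel_size = 0.25, cell_radius = 2,
                     seed = 8L)
  bm <- suppressMessages(benchmark_solvers(sp, delta_theta = 16,
                                           noise_sigma = 0.02))
  expect_equal(bm$solver, c("fbp", "hotv-1", "hotv-2", "hotv-3", "hotv-4"))
  expect_true(all(bm$ssim > 0 & bm$ssim <= 1))
  expect_equal(attr(bm, "n_projections"), 22L)
  expect_error(reconstruct(sinogram(array(0, c(2, 3, 8)),
                                    c(0, 10, 20), 0.1), "bogus"),
               "unknown solver")
})
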