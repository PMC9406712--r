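# Shared fixtures and independent oracles, all generated in code.

rmse <- function(a, b) sqrt(mean((a - b)^2))

# phase maps are defined up to a global offset (piston); remove it before RMSE
depiston <- function(a, b) a - mean(a - b)

# hard-edged sphere tomogram (piecewise-constant phantom)
hard_sphere <- function(n = 32L, voxel = 0.2, radius = 2.4, contrast = 0.02,
                        medium = 1.334) {
  g <- (seq_len(n) - (n + 1) / 2) * voxel
  rx <- array(g, c(n, n, n))
  ry <- aperm(rx, c(2, 1, 3))
  rz <- aperm(rx, c(3, 2, 1))
  tomogram(medium + contrast * ((rx^2 + ry^2 + rz^2) <= radius^2), voxel,
           medium)
}

# model-consistent sinogram: forward projection through the solver's own
# sparse operator (per slice along dim 1)
sinogram_via_projector <- function(t, angles) {
  n <- dim(t$values)[1]
  A <- flowtomo:::projector_matrix(n, angles)
  dn <- ri_contrast(t)
  X <- vapply(seq_len(n), function(i) as.numeric(dn[i, , ]),
              numeric(n * n))
  B <- as.matrix(A %*% X) * t$voxel_size
  data <- array(0, c(n, length(angles), n))
  for (i in seq_len(n)) data[i, , ] <- t(matrix(B[, i], n, length(angles)))
  sinogram(data, angles, t$voxel_size, t$medium_ri)
}

# Independent TV oracle: proximal-gradient (ISTA) on
#   min mu/2 ||A x - b||^2 + lambda ||D x||_1
# with the anisotropic-TV prox evaluated by projected gradient ascent on the
# dual. Coded independently of the package's split-Bregman solver.
tv_prox_gradient <- function(A, b, mu, lambda, n, iters = 400,
                             prox_iters = 40, nonneg = FALSE) {
  D <- flowtomo:::pa_matrix(n, 1L)
  LD <- 8                      # ||D||^2 bound for first differences in 2D
  sigma2 <- flowtomo:::projector_norm(A)^2
  step <- 1 / (mu * sigma2)
  x <- numeric(n * n)
  p <- numeric(nrow(D))
  for (it in seq_len(iters)) {
    g <- mu * as.numeric(Matrix::crossprod(A, A %*% x - b))
    v <- x - step * g
    tau <- step * lambda
    # prox_{tau ||D.||_1}(v) = v - D^T p*,  p* in [-tau, tau]^m
    for (j in seq_len(prox_iters)) {
      r <- v - as.numeric(Matrix::crossprod(D, p))
      p <- pmin(pmax(p + (1 / LD) * as.numeric(D %*% r), -tau), tau)
    }
    x <- v - as.numeric(Matrix::crossprod(D, p))
    if (nonneg) x <- pmax(x, 0)
  }
  x
}

fft_freq_test <- function(n) flowtomo:::fft_freq(n)

# rolling track pinned to the exact frame center (no recentering shift)
center_track <- function(n_frames, frame_n) {
  df <- data.frame(frame = seq_len(n_frames), x = 0, y = 0, l = 0)
  structure(list(track = df,
                 centroid_px = matrix((frame_n + 1) / 2, n_frames, 2),
                 pixel_pitch = NA_real_, frame_of_360 = NA_integer_,
                 L360 = NA_real_),
            class = "rolling_track")
}
gaussian_blur3_test <- function(v, s) flowtomo:::gaussian_blur3(v, s)

# tiny textured phantom spec used across tests
small_spec <- function(seed = 5L, n = 32L, cl = 0.5)
  phantom_spec(grid_size = n, voxel_size = 0.2,
               cell_radius = min(2.4, n * 0.2 / 2 - 0.4),
               correlation_length = cl, seed = seed)
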