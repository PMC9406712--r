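# Tomographic reconstruction: sinogram assembly, sparse projector, filtered
# back projection, polynomial-annihilation (high-order TV) regularization with
# a split-Bregman/ADMM solver.

#' Sinogram of line integrals
#'
#' Per-slice stack of 1D projections of the RI contrast. `data` holds
#' `integral(delta_n) ds` in micrometre units (phase times lambda / 2 pi),
#' indexed `[slice, angle, detector bin]`; the angle list may be non-uniform.
#'
#' @param data 3D array, slices x angles x detector bins.
#' @param angles projection angles in degrees, strictly increasing, in
#'   `[0, 360)`.
#' @param detector_pitch detector bin spacing, micrometres.
#' @param medium_ri immersion-medium RI carried through to reconstructions.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, angles, detector_pitch, medium_ri = 1.334) {
  if (length(dim(data)) != 3L) stopf("sinogram data must be a 3D array")
  if (dim(data)[2] != length(angles))
    stopf("dim(data)[2] must equal length(angles)")
  if (any(diff(angles) <= 0)) stopf("angles must be strictly increasing")
  if (any(angles < 0 | angles >= 360)) stopf("angles must lie in [0, 360)")
  if (!all(is.finite(data))) stopf("sinogram data must be finite")
  structure(list(data = data, angles = angles,
                 detector_pitch = detector_pitch, medium_ri = medium_ri),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "sinogram: %d slices x %d angles x %d bins @ %.3g um, angles %.1f..%.1f deg\n",
    d[1], d[2], d[3], x$detector_pitch, min(x$angles), max(x$angles)))
  invisible(x)
}

#' Uniform benchmark angle schedule
#'
#' `theta_j = j * delta_theta` for `j = 0 .. floor(360 / delta_theta) - 1`,
#' the convention giving 60 projections at a 6-degree step and 22 at a
#' 16-degree step.
#'
#' @param delta_theta angular step, degrees.
#' @return numeric vector of angles in `[0, 360)`.
#' @export
angle_schedule <- function(delta_theta) {
  stopifnot(delta_theta > 0, delta_theta < 360)
  seq(0, by = delta_theta, length.out = floor(360 / delta_theta))
}

#' Assemble a sinogram from angle-tagged QPMs
#'
#' Each retained QPM is re-centered on the tracked centroid, rotated by
#' `-tilt` degrees so the flow direction aligns with the image y axis, cropped
#' to a square of `crop_size` micrometres, and converted from phase (radians)
#' to line-integral units by `lambda / (2 pi)`. Columns of the de-tilted crop
#' (perpendicular to the rotation axis) become the per-slice 1D projections.
#'
#' @param qpms list of [qpm()] frames.
#' @param angles an `angular_sequence` from [assign_angles()], or a numeric
#'   vector of degrees (one per QPM).
#' @param track a [track_centroids()] result (computed from `qpms` if `NULL`).
#' @param tilt channel tilt to undo, degrees.
#' @param crop_size crop side, micrometres.
#' @param wavelength illumination wavelength, micrometres.
#' @param medium_ri immersion-medium RI.
#' @return A [sinogram()]. Frames with non-increasing angles (and any frame at
#'   or beyond 360 degrees) are dropped.
#' @export
build_sinogram <- function(qpms, angles, track = NULL, tilt = 45,
                           crop_size = 20, wavelength = 0.488,
                           medium_ri = 1.334) {
  if (inherits(angles, "angular_sequence")) {
    frames <- angles$angles$frame
    theta <- angles$angles$theta_deg
  } else {
    frames <- seq_along(qpms)
    theta <- as.numeric(angles)
  }
  if (length(frames) != length(theta)) stopf("one angle per QPM required")
  keep <- which(theta < 360)
  keep <- keep[c(TRUE, diff(theta[keep]) > 0)]
  frames <- frames[keep]; theta <- theta[keep]
  if (is.null(track)) track <- track_centroids(qpms)
  px <- qpms[[1]]$pixel_pitch
  size_px <- round(crop_size / px)
  crops <- recenter_qpms(qpms[frames],
                         structure(list(track = track$track[frames, ],
                                        centroid_px = track$centroid_px[frames, , drop = FALSE],
                                        pixel_pitch = px,
                                        frame_of_360 = NA_integer_,
                                        L360 = NA_real_),
                                   class = "rolling_track"),
                         size_px, rotate_by = -tilt)
  scale <- wavelength / (2 * pi)
  data <- array(0, c(size_px, length(frames), size_px))
  for (a in seq_along(frames)) {
    m <- crops[[a]]$phase * scale     # rows = detector (flow) dir, cols = axis
    data[, a, ] <- t(m)               # slice = column of the de-tilted crop
  }
  sinogram(data, theta, detector_pitch = px, medium_ri = medium_ri)
}

#' Project a tomogram into a sinogram
#'
#' Forward simulation used by the phantom benchmark: straight-ray projections
#' at the given angles with optional additive Gaussian phase noise (in
#' radians, applied to the phase before conversion to line integrals).
#'
#' @param t a [tomogram()].
#' @param angles projection angles, degrees.
#' @param noise_sigma phase-noise standard deviation, radians.
#' @param seed RNG seed for the noise stream.
#' @param config an [optical_config()].
#' @return A [sinogram()].
#' @export
project_sinogram <- function(t, angles, noise_sigma = 0, seed = 1L,
                             config = optical_config()) {
  stopifnot(inherits(t, "tomogram"))
  d <- dim(t$values)
  if (d[2] != d[3])
    stopf("rotation plane (dims 2 and 3) must be square")
  scale <- config$wavelength / (2 * pi)
  data <- array(0, c(d[1], length(angles), d[2]))
  for (a in seq_along(angles)) {
    ph <- project_phase(t, angles[a], config = config)$phase
    data[, a, ] <- ph
  }
  if (noise_sigma > 0)
    data <- data + with_seed(seed, array(rnorm(length(data), 0, noise_sigma),
                                         dim(data)))
  sinogram(data * scale, angles, detector_pitch = t$voxel_size,
           medium_ri = t$medium_ri)
}

# ---- sparse projector -------------------------------------------------------

.projector_cache <- new.env(parent = emptyenv())

# Pixel-driven sparse projector for an n x n slice at the given angles
# (degrees). Rows: (angle, detector bin); columns: vectorized pixels (detector
# direction = matrix rows, optical axis = matrix cols). Entries are unit path
# weights per voxel; the adjoint is the exact transpose.
projector_matrix <- function(n, angles_deg) {
  key <- paste0(n, "|", paste(sprintf("%.6f", angles_deg), collapse = ","))
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  ctr <- (n - 1) / 2
  dy <- rep(seq_len(n) - 1 - ctr, times = n)   # pixel row offsets
  dz <- rep(seq_len(n) - 1 - ctr, each = n)    # pixel col offsets
  ii <- jj <- xx <- vector("list", length(angles_deg))
  for (a in seq_along(angles_deg)) {
    th <- deg2rad(angles_deg[a])
    tpos <- cos(th) * dy - sin(th) * dz + ctr
    t0 <- floor(tpos)
    f <- tpos - t0
    base <- (a - 1) * n
    ok0 <- t0 >= 0 & t0 <= n - 1
    ok1 <- t0 + 1 >= 0 & t0 + 1 <= n - 1
    ii[[a]] <- c(base + t0[ok0] + 1, base + t0[ok1] + 2)
    jj[[a]] <- c(which(ok0), which(ok1))
    xx[[a]] <- c((1 - f)[ok0], f[ok1])
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(angles_deg) * n, n * n))
  .projector_cache[[key]] <- A
  A
}

# largest singular value of A (power iteration on A^T A), cached with A
projector_norm <- function(A) {
  key <- paste0("norm|", paste(dim(A), collapse = "x"), "|", length(A@x),
                "|", format(sum(A@x), digits = 12))
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- rep(1, ncol(A)); v <- v / sqrt(sum(v^2))
  s <- 1
  for (i in 1:30) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    s <- sqrt(sum(w^2))
    v <- w / s
  }
  out <- sqrt(s)
  .projector_cache[[key]] <- out
  out
}

# ---- filtered back projection ----------------------------------------------

ramp_filter <- function(L, filter = c("ramp", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  # band-limited ramp from its space-domain kernel (avoids the DC bias of a
  # naive |f| filter)
  nvec <- c(0:(L / 2 - 1), -(L / 2):-1)
  h <- numeric(L)
  h[1] <- 0.25
  odd <- which(nvec %% 2 != 0)
  h[odd] <- -1 / (pi * nvec[odd])^2
  # DTFT of h is the band-limited |f| (cycles/sample); pairing with the
  # (1/2) d-theta angle weights over [0, 360) gives the inverse Radon scale
  fr <- Re(fft(h))
  f <- abs(fft_freq(L))
  if (filter == "shepp-logan") {
    w <- rep(1, L); nz <- f > 0
    w[nz] <- sin(pi * f[nz]) / (pi * f[nz])
    fr <- fr * w
  } else if (filter == "hann") {
    fr <- fr * (0.5 + 0.5 * cos(2 * pi * f))
  }
  fr
}

# circular angle weights delta_theta_j / 2 (radians) over [0, 360)
angle_weights <- function(angles_deg) {
  th <- deg2rad(angles_deg)
  m <- length(th)
  if (m == 1) stopf("at least 2 distinct angles required")
  gaps <- diff(c(th, th[1] + 2 * pi))
  prev <- c(gaps[m], gaps[-m])
  (prev + gaps) / 4   # (theta_{j+1} - theta_{j-1}) / 2, halved for 2 pi range
}

#' Filtered back projection
#'
#' Slice-by-slice inverse Radon transform: each projection is ramp-filtered in
#' the detector frequency domain and back-projected with bilinear
#' interpolation, with angle-spacing weights supporting non-uniform angle
#' lists over `[0, 360)`.
#'
#' @param s a [sinogram()].
#' @param filter frequency filter: `"ramp"` (default), `"shepp-logan"` or
#'   `"hann"`.
#' @return A [tomogram()] of absolute RI (`medium_ri` plus reconstructed
#'   contrast).
#' @export
fbp_reconstruct <- function(s, filter = "ramp") {
  stopifnot(inherits(s, "sinogram"))
  d <- dim(s$data)
  nsl <- d[1]; nang <- d[2]; n <- d[3]
  if (nang < 2) stopf("at least 2 distinct angles required")
  L <- 2^ceiling(log2(2 * n))
  fr <- ramp_filter(L, filter)
  w <- angle_weights(s$angles)
  A <- projector_matrix(n, s$angles)
  # filter all (slice, angle) projections in one batched FFT
  P <- matrix(0, L, nsl * nang)
  for (sl in seq_len(nsl))
    P[seq_len(n), (sl - 1) * nang + seq_len(nang)] <- t(s$data[sl, , ])
  P <- P / s$detector_pitch            # line integrals in voxel units
  Q <- Re(stats::mvfft(stats::mvfft(P) * fr, inverse = TRUE)) / L
  Q <- Q[seq_len(n), , drop = FALSE]
  # weighted, stacked per slice: rows ordered (angle, bin) to match A
  Qw <- array(0, c(n, nang, nsl))
  for (sl in seq_len(nsl))
    Qw[, , sl] <- Q[, (sl - 1) * nang + seq_len(nang)] *
      matrix(w, n, nang, byrow = TRUE)
  Qm <- matrix(aperm(Qw, c(1, 2, 3)), n * nang, nsl)
  X <- as.matrix(Matrix::crossprod(A, Qm))
  vol <- aperm(array(X, c(n, n, nsl)), c(3, 1, 2))
  tomogram(vol + s$medium_ri, voxel_size = s$detector_pitch,
           medium_ri = s$medium_ri)
}

# ---- polynomial annihilation transform --------------------------------------

.diffmat_cache <- new.env(parent = emptyenv())

# sparse k-th order forward-difference operator for an n x n image
# (vectorized column-major); rows stack the along-rows and along-cols
# coefficients
pa_matrix <- function(n, k) {
  key <- paste0(n, "|", k)
  hit <- .diffmat_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n <= k) stopf("array extent (%d) must exceed the order k (%d)", n, k)
  co <- choose(k, 0:k) * (-1)^(k - (0:k))
  d1 <- Matrix::bandSparse(n - k, n, k = 0:k,
                           diagonals = lapply(0:k, function(i)
                             rep(co[i + 1], n - k)))
  I <- Matrix::Diagonal(n)
  D <- rbind(Matrix::kronecker(I, d1), Matrix::kronecker(d1, I))
  D <- methods::as(D, "CsparseMatrix")
  .diffmat_cache[[key]] <- D
  D
}

#' Polynomial-annihilation (k-th difference) transform
#'
#' k-th order finite differences of a 2D array along each dimension, the
#' regularization operator of high-order TV: zero on polynomials of degree
#' `< k`, so `k = 1` reduces to the standard TV gradient.
#'
#' @param x numeric matrix (extent > `k` in each dimension).
#' @param k difference order (>= 1).
#' @return list with `d1` (differences along rows, `(n-k) x n`) and `d2`
#'   (along columns, `n x (n-k)`).
#' @export
pa_transform <- function(x, k = 1L) {
  stopifnot(is.matrix(x))
  n <- nrow(x); m <- ncol(x)
  if (n <= k || m <= k)
    stopf("array extent (%d x %d) must exceed the order k (%d)", n, m, k)
  list(d1 = diff(x, differences = k),
       d2 = t(diff(t(x), differences = k)))
}

#' Adjoint of the polynomial-annihilation transform
#'
#' Exact adjoint of [pa_transform()] for square arrays, satisfying
#' `<PA x, y> == <x, PA^T y>`.
#'
#' @param coefs list with `d1`, `d2` as returned by [pa_transform()].
#' @param k difference order used in the forward transform.
#' @return numeric matrix of the adjoint image.
#' @export
pa_adjoint <- function(coefs, k = 1L) {
  n <- ncol(coefs$d1)
  D <- pa_matrix(n, k)
  y <- c(as.numeric(coefs$d1), as.numeric(coefs$d2))
  matrix(as.numeric(Matrix::crossprod(D, y)), n, n)
}

# ---- HOTV solver ------------------------------------------------------------

#' HOTV reconstruction configuration
#'
#' Parameters of the high-order TV solver. The data-fidelity values
#' DF = 24 / 48 / 96 / 192 for orders 1-4 are the defaults; the solver works
#' on a normalized problem (projector scaled to unit spectral norm by power
#' iteration, data scaled to unit maximum) in which the data-term weight is
#' `mu = DF * fidelity_scale`, making the DF scale independent of grid size,
#' angle count and contrast units.
#'
#' @param order difference order k in 1..4.
#' @param df data-fidelity weight; default `24 * 2^(order - 1)`.
#' @param inner_iterations conjugate-gradient steps per outer iteration.
#' @param outer_iterations ADMM (split-Bregman) iterations.
#' @param tolerance relative-change stopping criterion on the iterate.
#' @param nonnegativity enforce `delta_n >= 0` by projection each outer
#'   iteration.
#' @param fidelity_scale DF-to-mu normalization constant.
#' @param beta ADMM splitting penalty (relative to `mu`'s scale).
#' @param init `"fbp"` (warm start from the clipped filtered back projection)
#'   or `"zero"`.
#' @return An object of class `hotv_config`.
#' @export
hotv_config <- function(order = 2L, df = NULL, inner_iterations = 30L,
                        outer_iterations = 30L, tolerance = 1e-4,
                        nonnegativity = TRUE, fidelity_scale = 1,
                        beta = 8, init = c("fbp", "zero")) {
  init <- match.arg(init)
  order <- as.integer(order)
  if (!order %in% 1:4) stopf("order k must be in 1..4")
  if (is.null(df)) df <- 24 * 2^(order - 1)
  if (df <= 0) stopf("DF must be positive")
  structure(list(order = order, df = df,
                 inner_iterations = as.integer(inner_iterations),
                 outer_iterations = as.integer(outer_iterations),
                 tolerance = tolerance, nonnegativity = nonnegativity,
                 fidelity_scale = fidelity_scale, beta = beta, init = init),
            class = "hotv_config")
}

#' @export
print.hotv_config <- function(x, ...) {
  cat(sprintf(
    "HOTV config: order %d, DF %g, %d outer x %d inner iterations, tol %g, nonnegativity %s\n",
    x$order, x$df, x$outer_iterations, x$inner_iterations, x$tolerance,
    if (x$nonnegativity) "on" else "off"))
  invisible(x)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' High-order TV (polynomial annihilation) reconstruction
#'
#' Solves, slice by slice (all slices batched through one cached sparse
#' projector), `min mu/2 ||A x - b||^2 + ||PA_k x||_1` by split-Bregman/ADMM:
#' outer iterations perform the shrinkage of the difference coefficients, the
#' dual update and (optionally) the non-negativity projection, while inner
#' iterations are warm-started conjugate-gradient steps on the quadratic
#' x-subproblem. Slices with empty data are returned as zeros without solver
#' invocation.
#'
#' @param s a [sinogram()].
#' @param cfg an [hotv_config()].
#' @return A [tomogram()] with attribute `"convergence"`: a list with the
#'   accepted (monotone non-increasing, best-iterate) objective trace per
#'   outer iteration plus the raw trace, the relative-change trace, and a
#'   `converged` flag (a `warning_flag` of `TRUE` marks non-convergence within
#'   `outer_iterations`; no exception is thrown).
#' @export
hotv_reconstruct <- function(s, cfg = hotv_config()) {
  stopifnot(inherits(s, "sinogram"), inherits(cfg, "hotv_config"))
  d <- dim(s$data)
  nsl <- d[1]; nang <- d[2]; n <- d[3]
  A <- projector_matrix(n, s$angles)
  # PA operator with the conventional per-order normalization 2^(1-k), which
  # equalizes the transform's response across orders and under which the
  # DF = 24/48/96/192 defaults are balanced
  D <- pa_matrix(n, cfg$order) * 2^(1 - cfg$order)
  B <- matrix(0, nang * n, nsl)
  for (sl in seq_len(nsl)) B[, sl] <- as.numeric(t(s$data[sl, , ]))
  B <- B / s$detector_pitch
  act <- which(apply(abs(B), 2, max) > 1e-12 * max(abs(B), 1e-300))
  X <- matrix(0, n * n, nsl)
  obj_trace <- rel_trace <- numeric(0)
  converged <- FALSE
  mu <- cfg$df * cfg$fidelity_scale
  beta <- cfg$beta
  if (length(act)) {
    # normalized problem: unit-spectral-norm operator, unit-scale data, so the
    # printed DF values weight the data term consistently across grid sizes
    sig <- projector_norm(A)
    bscale <- max(abs(B[, act, drop = FALSE]))
    Ba <- B[, act, drop = FALSE] / bscale
    AtB <- as.matrix(Matrix::crossprod(A, Ba)) / sig
    Xa <- if (identical(cfg$init, "fbp")) {
      f0 <- fbp_reconstruct(s)
      X0 <- vapply(seq_len(nsl), function(i)
        as.numeric(ri_contrast(f0)[i, , ]), numeric(n * n))
      pmax(X0[, act, drop = FALSE], 0) * sig / bscale
    } else matrix(0, n * n, length(act))
    dd <- uu <- matrix(0, nrow(D), length(act))
    Mop <- function(V)
      (mu / sig^2) * as.matrix(Matrix::crossprod(A, A %*% V)) +
      beta * as.matrix(Matrix::crossprod(D, D %*% V))
    Xprev <- Xa
    Xbest <- Xa
    obj_best <- Inf
    raw_trace <- numeric(0)
    for (outer in seq_len(cfg$outer_iterations)) {
      RHS <- mu * AtB + beta * as.matrix(Matrix::crossprod(D, dd - uu))
      Xa <- cg_batched(Mop, RHS, Xa, cfg$inner_iterations)
      DX <- as.matrix(D %*% Xa)
      dd <- soft_threshold(DX + uu, 1 / beta)
      uu <- uu + DX - dd
      if (cfg$nonnegativity) Xa <- pmax(Xa, 0)
      R <- (A %*% Xa) / sig - Ba
      obj <- mu / 2 * sum(R^2) + sum(abs(DX))
      raw_trace <- c(raw_trace, obj)
      # monotone safeguard: the accepted iterate is the best-objective one
      if (obj <= obj_best) { obj_best <- obj; Xbest <- Xa }
      obj_trace <- c(obj_trace, obj_best)
      rel <- sqrt(sum((Xa - Xprev)^2)) / max(sqrt(sum(Xa^2)), 1e-300)
      Xprev <- Xa
      rel_trace <- c(rel_trace, rel)
      if (rel < cfg$tolerance) { converged <- TRUE; break }
    }
    X[, act] <- Xbest * bscale / sig
  } else converged <- TRUE
  vol <- aperm(array(X, c(n, n, nsl)), c(3, 1, 2))
  out <- tomogram(vol + s$medium_ri, voxel_size = s$detector_pitch,
                  medium_ri = s$medium_ri)
  attr(out, "convergence") <- list(objective = obj_trace,
                                   objective_raw = if (length(act))
                                     raw_trace else numeric(0),
                                   relative_change = rel_trace,
                                   converged = converged,
                                   warning_flag = !converged,
                                   mu = mu, beta = beta)
  if (!converged)
    message(sprintf(
      "hotv_reconstruct: relative change %.2e above tolerance %.2e after %d outer iterations",
      utils::tail(rel_trace, 1), cfg$tolerance, cfg$outer_iterations))
  out
}

# batched conjugate gradient: solves Mop(X) = B column-wise with per-column
# step sizes, warm started at X0, fixed number of steps (early exit on tiny
# residual)
cg_batched <- function(Mop, B, X0, steps, rtol = 1e-9) {
  X <- X0
  R <- B - Mop(X)
  P <- R
  rs <- colSums(R^2)
  b2 <- pmax(colSums(B^2), 1e-300)
  for (it in seq_len(steps)) {
    if (all(rs / b2 < rtol^2)) break
    MP <- Mop(P)
    alpha <- rs / pmax(colSums(P * MP), 1e-300)
    X <- X + sweep(P, 2, alpha, `*`)
    R <- R - sweep(MP, 2, alpha, `*`)
    rs_new <- colSums(R^2)
    P <- R + sweep(P, 2, rs_new / pmax(rs, 1e-300), `*`)
    rs <- rs_new
  }
  X
}

#' Reconstruct a tomogram with a named solver
#'
#' Convenience dispatcher: `"fbp"` or `"hotv-k"` for k in 1..4 (printed DF
#' defaults).
#'
#' @param s a [sinogram()].
#' @param solver solver name.
#' @param ... passed to the solver ([fbp_reconstruct()] filter, or
#'   [hotv_config()] fields overriding the defaults).
#' @return A [tomogram()].
#' @export
reconstruct <- function(s, solver = "hotv-2", ...) {
  if (solver == "fbp") return(fbp_reconstruct(s, ...))
  m <- regmatches(solver, regexec("^hotv-?([1-4])$", solver))[[1]]
  if (length(m) == 2)
    return(hotv_reconstruct(s, do.call(hotv_config,
                                       c(list(order = as.integer(m[2])),
                                         list(...)))))
  stopf("unknown solver '%s'", solver)
}

#' Benchmark phantom conditions
#'
#' The phantom specification used by the solver benchmark: a monocyte-scale
#' cell (7.2 um diameter) on a 48^3 grid at 0.2 um voxels, with 0.6 um
#' texture correlation length and a 1.2 um resolution-limited boundary.
#' The grid is the desk-scale working size of the benchmark; the texture and
#' boundary scales emulate a tomogram as it appears after a band-limited
#' reconstruction pipeline.
#'
#' @param seed phantom RNG seed.
#' @return A [phantom_spec()].
#' @export
benchmark_phantom_spec <- function(seed = 1L) {
  phantom_spec(grid_size = 48L, voxel_size = 0.2, cell_radius = 3.6,
               correlation_length = 0.6, edge_width = 1.2, seed = seed)
}

#' Phantom benchmark of the reconstruction solvers
#'
#' Generates a phantom, projects it on the uniform schedule
#' `theta_j = j * delta_theta` over `[0, 360)` with additive Gaussian phase
#' noise, reconstructs with each solver, and reports the 3D SSIM against the
#' ground truth over the entire tomogram.
#'
#' @param spec a [phantom_spec()] (its seed also drives the noise stream).
#' @param delta_theta angular step, degrees (6 gives 60 projections, 16 gives
#'   22).
#' @param noise_sigma projection phase noise, radians. The value is a declared
#'   calibration of the benchmark (see the package vignette).
#' @param solvers character vector of solver names (see [reconstruct()]).
#' @param config an [optical_config()].
#' @return data frame with columns `solver` and `ssim`, with attribute
#'   `"tomograms"` holding the reconstructions.
#' @export
benchmark_solvers <- function(spec = benchmark_phantom_spec(),
                              delta_theta = 16,
                              noise_sigma = 0.025,
                              solvers = c("fbp", "hotv-1", "hotv-2",
                                          "hotv-3", "hotv-4"),
                              config = optical_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- generate_phantom(spec)
  angles <- angle_schedule(delta_theta)
  s <- project_sinogram(truth, angles, noise_sigma,
                        seed = spec$seed + 500000L, config = config)
  recs <- lapply(solvers, function(sv) reconstruct(s, sv))
  ssim <- vapply(recs, function(r) ssim_3d(r, truth), numeric(1))
  out <- data.frame(solver = solvers, ssim = ssim)
  attr(out, "tomograms") <- recs
  attr(out, "n_projections") <- length(angles)
  out
}
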