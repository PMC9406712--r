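#' Numerical phantom specification
#'
#' Describes a seeded 3D phantom cell: a spherical (optionally ellipsoidal)
#' support filled with a smoothed Gaussian random RI field rescaled into
#' `ri_range`, suspended in a medium of index `medium_ri`. The random texture
#' deliberately has no recognizable internal structures; its spatial scale is
#' set by `correlation_length`.
#'
#' @param grid_size voxels per axis (cubic grid).
#' @param voxel_size voxel edge, micrometres.
#' @param medium_ri immersion-medium refractive index.
#' @param ri_range numeric length-2, the min/max refractive index inside the
#'   cell (default `c(1.334, 1.410)`).
#' @param cell_radius cell radius, micrometres.
#' @param correlation_length smoothing length of the internal random field,
#'   micrometres.
#' @param edge_width width of the smooth (raised-cosine) support edge,
#'   micrometres; the default mirrors the resolution-limited boundary a
#'   reconstructed tomogram exhibits (about the 0.8 um lateral resolution of
#'   the imaging system).
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @param axis_ratios length-3 relative semi-axes for an ellipsoidal support
#'   (default sphere).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L, voxel_size = 0.1, medium_ri = 1.334,
                         ri_range = c(1.334, 1.410), cell_radius = 4,
                         correlation_length = 0.6, edge_width = 0.8,
                         seed = 1L, axis_ratios = c(1, 1, 1)) {
  spec <- list(grid_size = as.integer(grid_size), voxel_size = voxel_size,
               medium_ri = medium_ri, ri_range = ri_range,
               cell_radius = cell_radius,
               correlation_length = correlation_length,
               edge_width = edge_width,
               seed = as.integer(seed), axis_ratios = axis_ratios)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$ri_range) != 2 || spec$ri_range[2] < spec$ri_range[1])
    stopf("ri_range must be an increasing [min, max] pair")
  if (spec$ri_range[1] < spec$medium_ri)
    stopf("invariant violated: ri_range[1] (%.4f) must be >= medium_ri (%.4f)",
          spec$ri_range[1], spec$medium_ri)
  if (spec$cell_radius >= spec$grid_size * spec$voxel_size / 2)
    stopf(paste0("invariant violated: cell_radius (%.3g um) must be smaller ",
                 "than half the grid extent (%.3g um)"),
          spec$cell_radius, spec$grid_size * spec$voxel_size / 2)
  if (spec$correlation_length < 0) stopf("correlation_length must be >= 0")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom spec: %d^3 @ %.3g um, cell radius %.3g um, RI [%.4f, %.4f] in %.4f, seed %d\n",
    x$grid_size, x$voxel_size, x$cell_radius, x$ri_range[1], x$ri_range[2],
    x$medium_ri, x$seed))
  invisible(x)
}

#' Generate a seeded phantom cell tomogram
#'
#' Samples white Gaussian noise on the grid, low-pass filters it with a
#' Gaussian kernel of width `correlation_length`, rescales the field inside
#' the cell support affinely into `ri_range`, and blends the support edge with
#' a raised-cosine profile of width `edge_width` (emulating the
#' resolution-limited boundary of a reconstructed tomogram and avoiding
#' aliasing in projections). Voxels outside the support equal `medium_ri`
#' exactly.
#'
#' @param spec a [phantom_spec()].
#' @return A [tomogram()] with attribute `"support"` (the soft support weight
#'   array in `[0, 1]`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$grid_size
  h <- spec$voxel_size
  ax <- spec$cell_radius * spec$axis_ratios / max(spec$axis_ratios)
  ctr <- (n + 1) / 2
  g <- (seq_len(n) - ctr) * h
  rx <- array(g, c(n, n, n))
  ry <- aperm(rx, c(2, 1, 3))
  rz <- aperm(rx, c(3, 2, 1))
  # normalized ellipsoidal radius (units of the cell boundary)
  rho <- sqrt((rx / ax[1])^2 + (ry / ax[2])^2 + (rz / ax[3])^2)
  # smooth raised-cosine support edge (resolution-limited boundary), at least
  # one voxel wide
  edge <- max(spec$edge_width, h) / min(ax)
  tt <- pmin(1, pmax(0, (1 - rho) / edge))
  w <- 0.5 * (1 - cos(pi * tt))
  field <- with_seed(spec$seed, array(rnorm(n^3), c(n, n, n)))
  field <- gaussian_blur3(field, spec$correlation_length / h)
  inside <- w > 0
  dr <- diff(spec$ri_range)
  if (any(inside) && dr > 0) {
    # rescale on the full-weight interior so the declared range is attained
    # exactly after edge blending (rim voxels are clipped into the range)
    core <- if (any(w >= 1)) w >= 1 else inside
    f <- field[core]
    fr <- range(f)
    if (fr[2] > fr[1]) {
      nf <- spec$ri_range[1] + (field - fr[1]) / diff(fr) * dr
    } else nf <- array(spec$ri_range[1], dim(field))
  } else nf <- array(spec$ri_range[1], dim(field))
  values <- spec$medium_ri + w * (nf - spec$medium_ri)
  values <- pmin(pmax(values, spec$medium_ri), spec$ri_range[2])
  out <- tomogram(values, voxel_size = h, medium_ri = spec$medium_ri)
  attr(out, "support") <- w
  out
}

#' Isolevel thresholds of a tomogram
#'
#' Thresholds at given fractions of the maximum RI contrast, used for
#' isosurface rendering and segmentation (conventionally 0.33 and 0.66 of the
#' maximum). Returned on the contrast scale by default; with
#' `absolute = TRUE`, `medium_ri` is added.
#'
#' @param t a [tomogram()].
#' @param fractions numeric vector in `(0, 1]`.
#' @param absolute return absolute RI instead of contrast.
#' @return numeric vector of thresholds, one per fraction.
#' @export
isolevel_thresholds <- function(t, fractions = c(0.33, 0.66),
                                absolute = FALSE) {
  stopifnot(inherits(t, "tomogram"))
  if (length(t$values) == 0) stopf("empty tomogram")
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must lie in (0, 1]")
  dmax <- max(ri_contrast(t))
  thr <- fractions * dmax
  if (absolute) thr <- thr + t$medium_ri
  thr
}
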