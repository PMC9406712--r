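# internal helpers shared across modules

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalized 1D Gaussian kernel truncated at `truncate` sigmas (odd length).
gaussian_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array (reflect boundary).
gaussian_blur3 <- function(vol, sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(vol)
  k <- gaussian_kernel(sigma_vox, truncate)
  out <- .sepconv3_cpp(vol, k)
  array(out, dim(vol))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

deg2rad <- function(x) x * pi / 180

# Rotate a matrix about its center (or an explicit center, 1-based row/col).
rotate_image <- function(img, angle_deg, center = NULL, fill = 0) {
  if (!is.finite(angle_deg)) stopf("rotation angle must be finite")
  if (is.null(center)) center <- (dim(img) + 1) / 2
  .rotate_bilinear_cpp(img, angle_deg, center[1] - 1, center[2] - 1, fill)
}

shift_image <- function(img, drow, dcol, fill = 0) {
  .shift_bilinear_cpp(img, drow, dcol, fill)
}
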