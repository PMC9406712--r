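# Hologram processing: apodization, Fourier demodulation, angular-spectrum
# refocusing with Tamura autofocus, reference compensation, unwrapping, and
# windowed-Fourier denoising.

# FFT sample frequencies in cycles/sample, fftshift-free ordering.
fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

tukey_window <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

#' Apodize a hologram
#'
#' Multiplies the intensity by a separable 2D tapered-cosine (Tukey) window to
#' suppress border diffraction in the Fourier spectrum. The interior plateau
#' is unchanged.
#'
#' @param h a [hologram()].
#' @param taper_fraction Tukey shape parameter in `[0, 1]`: the fraction of
#'   each axis inside the cosine taper (0 = rectangular, 1 = Hann).
#' @return An apodized [hologram()].
#' @export
apodize <- function(h, taper_fraction = 0.2) {
  stopifnot(inherits(h, "hologram"))
  if (taper_fraction < 0 || taper_fraction > 1)
    stopf("taper_fraction must lie in [0, 1]")
  w <- outer(tukey_window(nrow(h$intensity), taper_fraction),
             tukey_window(ncol(h$intensity), taper_fraction))
  hologram(h$intensity * w, h$pixel_pitch, h$frame_index)
}

#' Demodulate an off-axis hologram
#'
#' Extracts the +1 diffraction order from the hologram's Fourier spectrum,
#' re-centers it at DC and inverse-transforms, yielding the complex object
#' amplitude. With `order_center = "auto"` the order is located as the
#' strongest off-center spectral peak (conjugate-pair ambiguity resolved
#' toward positive column frequency).
#'
#' @param h a [hologram()].
#' @param order_center `"auto"` or a length-2 carrier frequency in
#'   cycles/pixel (row, col).
#' @param crop_radius spectral crop radius, cycles/pixel; default half the
#'   carrier magnitude.
#' @return A [complex_field()] with attributes `"carrier"` (cycles/pixel) and
#'   `"crop_radius"`.
#' @export
demodulate <- function(h, order_center = "auto", crop_radius = NULL) {
  stopifnot(inherits(h, "hologram"))
  img <- h$intensity
  nr <- nrow(img); nc <- ncol(img)
  S <- fft(img)
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  FR <- matrix(fr, nr, nc)
  FC <- matrix(fc, nr, nc, byrow = TRUE)
  rad <- sqrt(FR^2 + FC^2)
  if (identical(order_center, "auto")) {
    guard <- max(0.03, crop_radius %||% 0)
    cand <- rad > guard & (FC > 0 | (FC == 0 & FR > 0))
    mag <- Mod(S)
    if (!any(cand)) stopf("no carrier detected")
    i <- which(cand)[which.max(mag[cand])]
    floor_level <- stats::median(mag[rad > guard])
    if (mag[i] <= 0 || mag[i] < 5 * floor_level)
      stopf("no carrier detected")
    carrier <- c(FR[i], FC[i])
  } else {
    carrier <- as.numeric(order_center)
    if (length(carrier) != 2) stopf("order_center must be length 2")
  }
  cmag <- sqrt(sum(carrier^2))
  if (is.null(crop_radius)) crop_radius <- cmag / 2
  if (cmag <= crop_radius)
    stopf("carrier magnitude %.3g below separation bound %.3g cycles/px",
          cmag, crop_radius)
  # nearest spectral bin of the carrier
  pr <- round(carrier[1] * nr) %% nr
  pc <- round(carrier[2] * nc) %% nc
  keep <- rad <= crop_radius       # disk about DC, to be filled from the order
  Sout <- matrix(0+0i, nr, nc)
  idx <- which(keep)
  r0 <- (idx - 1) %% nr
  c0 <- (idx - 1) %/% nr
  src <- ((r0 + pr) %% nr) + nr * ((c0 + pc) %% nc) + 1
  Sout[idx] <- S[src]
  u <- fft(Sout, inverse = TRUE) / (nr * nc)
  out <- complex_field(u, h$pixel_pitch, depth_z = 0)
  attr(out, "carrier") <- c(pr / nr, pc / nc)
  attr(out, "crop_radius") <- crop_radius
  out
}

#' Angular-spectrum propagation
#'
#' Propagates a complex field by `dz` micrometres by multiplying its spectrum
#' with `exp(i 2 pi dz sqrt(1/lambda^2 - fx^2 - fy^2))`; evanescent components
#' (negative argument) are zeroed. `dz = 0` returns the field unchanged.
#'
#' @param u a [complex_field()].
#' @param dz propagation distance, micrometres (positive or negative).
#' @param wavelength wavelength, micrometres.
#' @return A propagated [complex_field()] with `depth_z` advanced by `dz`.
#' @export
propagate_angular_spectrum <- function(u, dz, wavelength = 0.488) {
  stopifnot(inherits(u, "complex_field"))
  if (!is.finite(dz)) stopf("dz must be finite")
  if (dz == 0) return(u)
  nr <- nrow(u$field); nc <- ncol(u$field)
  fx <- fft_freq(nr) / u$pixel_pitch
  fy <- fft_freq(nc) / u$pixel_pitch
  arg <- 1 / wavelength^2 - outer(fx^2, rep(1, nc)) - outer(rep(1, nr), fy^2)
  kz <- sqrt(pmax(arg, 0))
  Hf <- exp(2i * pi * dz * kz)
  Hf[arg < 0] <- 0+0i
  out <- fft(fft(u$field) * Hf, inverse = TRUE) / (nr * nc)
  complex_field(out, u$pixel_pitch, u$depth_z + dz)
}

#' Tamura coefficient
#'
#' Amplitude-contrast sharpness metric: the ratio of the standard deviation to
#' the mean of the field amplitude (population standard deviation). For a
#' phase object the metric is minimized at the in-focus plane. The square-root
#' form `sqrt(sd/mean)` used by part of the literature is a monotone transform
#' with identical argmin and is available via `sqrt_form`.
#'
#' @param u a [complex_field()] or a numeric amplitude matrix.
#' @param sqrt_form if `TRUE`, return `sqrt(sd/mean)`.
#' @return scalar Tamura coefficient.
#' @export
tamura_coefficient <- function(u, sqrt_form = FALSE) {
  a <- if (inherits(u, "complex_field")) Mod(u$field) else abs(u)
  mu <- mean(a)
  if (mu == 0) stopf("zero-mean amplitude: Tamura coefficient undefined")
  tc <- sqrt(mean((a - mu)^2)) / mu
  if (sqrt_form) sqrt(tc) else tc
}

#' Autofocus by Tamura-coefficient minimization
#'
#' Propagates the field to each candidate depth and returns the depth
#' minimizing the Tamura coefficient of the amplitude. Ties are broken toward
#' the smallest `|z|`.
#'
#' @param u a [complex_field()].
#' @param z_candidates numeric vector of candidate depths, micrometres.
#' @param wavelength wavelength, micrometres.
#' @param crop_fraction central fraction of the field the metric is computed
#'   on (avoids the apodized border dominating the amplitude contrast).
#' @return The in-focus depth (scalar, um) with attribute `"tc_profile"`.
#' @export
autofocus <- function(u, z_candidates, wavelength = 0.488,
                      crop_fraction = 0.5) {
  stopifnot(inherits(u, "complex_field"))
  if (length(z_candidates) == 0 || !all(is.finite(z_candidates)))
    stopf("z_candidates must be non-empty and finite")
  d <- dim(u$field)
  roi <- lapply(d, function(n) {
    h <- max(1L, floor(n * crop_fraction / 2))
    ctr <- (n + 1L) %/% 2L
    max(1L, ctr - h):min(n, ctr + h)
  })
  tc <- vapply(z_candidates, function(z)
    tamura_coefficient(
      propagate_angular_spectrum(u, z, wavelength)$field[roi[[1]], roi[[2]]]),
    numeric(1))
  best <- which(tc <= min(tc) * (1 + 1e-12))
  zbar <- z_candidates[best][which.min(abs(z_candidates[best]))]
  attr(zbar, "tc_profile") <- data.frame(z = z_candidates, tc = tc)
  zbar
}

#' Compensate aberrations with a cell-free reference field
#'
#' Divides the object field by a reference field processed identically from a
#' cell-free hologram. Aberration phase common to both cancels; the reference
#' amplitude also flattens illumination non-uniformity.
#'
#' @param u object [complex_field()].
#' @param u_ref reference [complex_field()], same shape and pitch.
#' @param eps minimum reference amplitude, as a fraction of its maximum.
#' @return The compensated [complex_field()].
#' @export
compensate_reference <- function(u, u_ref, eps = 1e-6) {
  stopifnot(inherits(u, "complex_field"), inherits(u_ref, "complex_field"))
  if (!all(dim(u$field) == dim(u_ref$field)) ||
      u$pixel_pitch != u_ref$pixel_pitch)
    stopf("object and reference fields must share shape and pixel pitch")
  aref <- Mod(u_ref$field)
  bad <- sum(aref <= eps * max(aref, .Machine$double.xmin))
  if (bad > 0)
    stopf("reference amplitude below guard at %d pixel(s)", bad)
  complex_field(u$field / u_ref$field, u$pixel_pitch, u$depth_z)
}

#' Unwrap a wrapped phase map
#'
#' Quality-guided flood-fill unwrapping: pixels are unwrapped in decreasing
#' order of local phase-gradient quality, each congruent (mod 2 pi) to its
#' wrapped value. For wrapped versions of a smooth surface with gradients
#' below pi per pixel the surface is recovered up to a global 2 pi k offset.
#'
#' @param wrapped 2D matrix of wrapped phase in `(-pi, pi]`, or a [qpm()].
#' @param pixel_pitch object-space pixel size, micrometres.
#' @param frame_index frame index carried into the output.
#' @return A [qpm()] with unwrapped phase.
#' @export
unwrap_phase <- function(wrapped, pixel_pitch = 1, frame_index = 1L) {
  if (inherits(wrapped, "qpm")) {
    pixel_pitch <- wrapped$pixel_pitch
    frame_index <- wrapped$frame_index
    wrapped <- wrapped$phase
  }
  if (any(wrapped > pi + 1e-9 | wrapped <= -pi - 1e-9))
    stopf("wrapped phase must lie in (-pi, pi]")
  qpm(.unwrap_qg_cpp(wrapped), pixel_pitch, frame_index)
}

#' Windowed-Fourier denoising of a phase map
#'
#' Overlapping-window Fourier filtering: each block is multiplied by a
#' Hamming analysis window, transformed, coefficients with magnitude below
#' `threshold` times the window's RMS coefficient magnitude are zeroed, and
#' blocks are inverse-transformed, multiplied by the synthesis window and
#' overlap-added with normalization by the accumulated squared window. The
#' per-window scale is a robust (median, Rayleigh-calibrated) estimate of the
#' noise coefficient magnitude, so `threshold` is expressed in noise-sigma
#' units (default 3). With `threshold = 0` the transform is an exact
#' partition of unity and the map is returned unchanged.
#'
#' @param q a [qpm()].
#' @param window_size square window side, pixels (>= 4).
#' @param threshold non-negative hard-threshold factor.
#' @param stride window hop, pixels (default `window_size / 4`).
#' @return A denoised [qpm()].
#' @export
wft_denoise <- function(q, window_size = 16L, threshold = 3,
                        stride = NULL) {
  stopifnot(inherits(q, "qpm"))
  w <- as.integer(window_size)
  if (w < 4) stopf("window_size must be >= 4")
  if (threshold < 0) stopf("threshold must be >= 0")
  ph <- q$phase
  nr <- nrow(ph); nc <- ncol(ph)
  if (w > nr || w > nc) stopf("window larger than image")
  if (is.null(stride)) stride <- max(1L, w %/% 4L)
  starts <- function(n) unique(c(seq(1L, n - w + 1L, by = stride), n - w + 1L))
  hamming <- 0.54 - 0.46 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  w2d <- outer(hamming, hamming)
  acc <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (r0 in starts(nr)) for (c0 in starts(nc)) {
    ri <- r0:(r0 + w - 1); ci <- c0:(c0 + w - 1)
    Fb <- fft(w2d * ph[ri, ci])
    if (threshold > 0) {
      scale <- stats::median(Mod(Fb)) / sqrt(log(4))
      Fb[Mod(Fb) < threshold * scale] <- 0+0i
    }
    rec <- Re(fft(Fb, inverse = TRUE)) / (w * w)
    acc[ri, ci] <- acc[ri, ci] + w2d * rec
    den[ri, ci] <- den[ri, ci] + w2d^2
  }
  qpm(acc / den, q$pixel_pitch, q$frame_index)
}

#' Process a hologram sequence into quantitative phase maps
#'
#' Runs the full per-frame chain: apodization, Fourier demodulation (carrier
#' located on the first frame and frozen), angular-spectrum refocusing to the
#' in-focus depth estimated on the first frame by Tamura autofocus, division
#' by the identically processed cell-free reference, quality-guided
#' unwrapping, and (optionally) windowed-Fourier denoising.
#'
#' @param holograms list of [hologram()] frames.
#' @param reference cell-free reference [hologram()].
#' @param config an [optical_config()].
#' @param z_candidates autofocus search depths, micrometres (default
#'   `seq(-20, 20, by = 1)`). The depth is estimated on the first frame and
#'   preserved for the whole sequence.
#' @param order_center,crop_radius,taper_fraction passed to [demodulate()] /
#'   [apodize()].
#' @param denoise logical; apply [wft_denoise()].
#' @param window_size,threshold denoising parameters.
#' @return list with `qpms` (list of [qpm()]), `z_focus`, `carrier`.
#' @export
process_hologram_sequence <- function(holograms, reference, config,
                                      z_candidates = seq(-20, 20, by = 1),
                                      order_center = "auto",
                                      crop_radius = NULL,
                                      taper_fraction = 0.2,
                                      denoise = TRUE, window_size = 16L,
                                      threshold = 3) {
  stopifnot(length(holograms) >= 1)
  u1 <- demodulate(apodize(holograms[[1]], taper_fraction), order_center,
                   crop_radius)
  carrier <- attr(u1, "carrier")
  cr <- attr(u1, "crop_radius")
  zbar <- autofocus(u1, z_candidates, config$wavelength)
  uref <- demodulate(apodize(reference, taper_fraction), carrier, cr)
  uref <- propagate_angular_spectrum(uref, zbar, config$wavelength)
  qpms <- vector("list", length(holograms))
  for (k in seq_along(holograms)) {
    u <- if (k == 1) u1 else
      demodulate(apodize(holograms[[k]], taper_fraction), carrier, cr)
    u <- propagate_angular_spectrum(u, zbar, config$wavelength)
    u <- compensate_reference(u, uref)
    qk <- unwrap_phase(Arg(u$field), u$pixel_pitch, k)
    if (denoise) qk <- wft_denoise(qk, window_size, threshold)
    qpms[[k]] <- qk
  }
  list(qpms = qpms, z_focus = as.numeric(zbar), carrier = carrier)
}
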