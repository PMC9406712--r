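# Forward optical simulation: phase projection of a rotating phantom and
# off-axis hologram synthesis for a cell translating along the tilted channel.

#' Phase projection of a tomogram
#'
#' Straight-ray forward model: the volume is rotated by `angle` degrees about
#' an in-plane axis (trilinear/bilinear interpolation) and the RI contrast is
#' summed along the optical axis, giving
#' `phase(x, y) = (2 pi / lambda) * sum(delta_n) * voxel_size`.
#'
#' @param t a [tomogram()].
#' @param angle projection angle, degrees.
#' @param rotation_axis 1 (array rows, default) or 2: in-plane axis the cell
#'   rolls about; slices along this axis are independent.
#' @param config an [optical_config()] (supplies the wavelength).
#' @return A [qpm()] sampled at the tomogram voxel size.
#' @export
project_phase <- function(t, angle, rotation_axis = 1L,
                          config = optical_config()) {
  stopifnot(inherits(t, "tomogram"))
  if (!is.finite(angle)) stopf("angle must be finite")
  dn <- ri_contrast(t)
  if (rotation_axis == 2L) dn <- aperm(dn, c(2, 1, 3))
  else if (rotation_axis != 1L) stopf("rotation_axis must be 1 or 2")
  s <- .project_volume_cpp(dn, angle)
  phase <- (2 * pi / config$wavelength) * s * t$voxel_size
  qpm(phase, t$voxel_size)
}

#' Synthesize an off-axis hologram
#'
#' Interference of the object field with a tilted plane-wave reference:
#' `H = |U + R|^2` with `R = a exp(2 pi i (f1 r + f2 c))` (`r`, `c` 0-based
#' pixel indices). The carrier must exceed the object bandwidth estimate so
#' the +1 order separates from the autocorrelation term.
#'
#' @param field a [complex_field()] (the object wave U).
#' @param carrier length-2 carrier frequency (row, col), cycles/pixel;
#'   default 0.25 cycles/pixel along the diagonal.
#' @param reference_amplitude amplitude of the reference wave.
#' @return A [hologram()] with attribute `"carrier"`.
#' @export
synthesize_hologram <- function(field, carrier = c(0.25, 0.25) / sqrt(2),
                                reference_amplitude = 1) {
  stopifnot(inherits(field, "complex_field"))
  U <- field$field
  nr <- nrow(U); nc <- ncol(U)
  cmag <- sqrt(sum(carrier^2))
  bw <- object_bandwidth(U)
  if (cmag <= 1.5 * bw)
    stopf("carrier magnitude %.3g cycles/px below required minimum %.3g (1.5 x object bandwidth)",
          cmag, 1.5 * bw)
  ramp <- outer(carrier[1] * (seq_len(nr) - 1), rep(1, nc)) +
    outer(rep(1, nr), carrier[2] * (seq_len(nc) - 1))
  # negative-going reference ramp puts the object term U conj(R) of
  # |U + R|^2 at +carrier in the spectrum, where demodulation extracts it
  R <- reference_amplitude * exp(-2i * pi * ramp)
  H <- Mod(U + R)^2
  out <- hologram(H, field$pixel_pitch)
  attr(out, "carrier") <- carrier
  out
}

# radius (cycles/px) containing 99% of the spectral energy of a field
object_bandwidth <- function(U) {
  nr <- nrow(U); nc <- ncol(U)
  S2 <- Mod(fft(U))^2
  rad <- sqrt(outer(fft_freq(nr)^2, rep(1, nc)) +
              outer(rep(1, nr), fft_freq(nc)^2))
  o <- order(rad)
  csum <- cumsum(S2[o])
  rad[o][which(csum >= 0.99 * csum[length(csum)])[1]]
}

#' Simulate a rolling-cell hologram sequence
#'
#' Generates the phantom, and for each frame projects it at the cumulative
#' rolling angle, embeds the phase map in the camera frame translated along
#' the tilted channel direction, adds Gaussian phase noise, and synthesizes an
#' off-axis hologram. A cell-free reference hologram with the same aberration
#' is returned along with the ground truth (angles, displacements, clean
#' phase maps).
#'
#' @param spec a [phantom_spec()].
#' @param flow a [flow_spec()].
#' @param config an [optical_config()].
#' @param frame_size camera frame side, pixels (object-space sampling equals
#'   the phantom voxel size).
#' @param carrier,reference_amplitude passed to [synthesize_hologram()].
#' @param aberration_peak peak of a smooth quadratic aberration phase shared
#'   by object and reference frames, radians (0 disables).
#' @param z_offset recording-plane defocus applied to every frame, um.
#' @return list of class `rolling_sequence`: `holograms`, `reference`,
#'   `truth` (angles, displacement matrix in um, clean phase maps), `spec`,
#'   `flow`, `config`.
#' @export
simulate_rolling_sequence <- function(spec, flow = flow_spec(),
                                      config = optical_config(),
                                      frame_size = 192L,
                                      carrier = c(0.25, 0.25) / sqrt(2),
                                      reference_amplitude = 1,
                                      aberration_peak = 0.5,
                                      z_offset = 0) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(flow, "flow_spec"))
  ph <- generate_phantom(spec)
  n <- spec$grid_size
  N <- as.integer(frame_size)
  if (N < n) stopf("frame_size must be at least the phantom grid size")
  px <- spec$voxel_size
  ctr <- (N + 1) / 2
  # direction of the flow: tilt_angle degrees from the image y (row) axis
  dir_rc <- c(cos(deg2rad(flow$tilt_angle)), sin(deg2rad(flow$tilt_angle)))
  k <- seq_len(flow$n_frames)
  disp_um <- (k - 1) * flow$translation_per_frame
  disp_px <- outer(disp_um / px, dir_rc)           # frames x (row, col)
  margin_px <- spec$cell_radius / px + 2
  lim <- (N - 1) / 2 - margin_px
  bad <- which(abs(disp_px[, 1]) > lim | abs(disp_px[, 2]) > lim)
  if (length(bad))
    stopf("trajectory exits the field of view at frame %d", bad[1])
  ab <- if (aberration_peak != 0) {
    rr <- (seq_len(N) - ctr) / (N / 2)
    aberration_peak * (outer(rr^2, rep(1, N)) + outer(rep(1, N), rr^2)) / 2 +
      0.1 * aberration_peak * outer(rr, rep(1, N))
  } else matrix(0, N, N)
  angles <- (k - 1) * flow$rotation_per_frame
  noise <- if (flow$noise_sigma > 0)
    with_seed(flow$seed,
              lapply(k, function(i) matrix(rnorm(N * N, 0, flow$noise_sigma),
                                           N, N)))
  else lapply(k, function(i) 0)
  holos <- vector("list", flow$n_frames)
  phases <- vector("list", flow$n_frames)
  pad <- (N - n) %/% 2
  for (i in k) {
    pj <- project_phase(ph, angles[i], config = config)
    canvas <- matrix(0, N, N)
    # de-tilted object frame: rows = flow/detector direction, cols = rolling
    # axis; rotate into the tilted camera frame, then translate along the flow
    canvas[pad + seq_len(n), pad + seq_len(n)] <- t(pj$phase)
    if (flow$tilt_angle != 0) canvas <- rotate_image(canvas, flow$tilt_angle)
    canvas <- shift_image(canvas, disp_px[i, 1], disp_px[i, 2])
    phases[[i]] <- canvas
    U <- complex_field(exp(1i * (canvas + noise[[i]] + ab)), px)
    if (z_offset != 0)
      U <- propagate_angular_spectrum(U, z_offset, config$wavelength)
    holos[[i]] <- synthesize_hologram(U, carrier, reference_amplitude)
    holos[[i]]$frame_index <- i
  }
  Uref <- complex_field(exp(1i * ab), px)
  if (z_offset != 0)
    Uref <- propagate_angular_spectrum(Uref, z_offset, config$wavelength)
  ref <- synthesize_hologram(Uref, carrier, reference_amplitude)
  structure(list(holograms = holos, reference = ref,
                 truth = list(angles = angles,
                              displacements_um = disp_px * px,
                              phases = phases),
                 spec = spec, flow = flow, config = config,
                 carrier = carrier),
            class = "rolling_sequence")
}

#' @export
print.rolling_sequence <- function(x, ...) {
  cat(sprintf(
    "rolling sequence: %d frames of %d x %d px, tilt %g deg, %g deg/frame\n",
    length(x$holograms), nrow(x$holograms[[1]]$intensity),
    ncol(x$holograms[[1]]$intensity), x$flow$tilt_angle,
    x$flow$rotation_per_frame))
  invisible(x)
}
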