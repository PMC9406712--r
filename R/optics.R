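#' Optical configuration of the holographic microscope
#'
#' Defaults mirror a compact lateral-shearing holographic flow cytometer:
#' 488 nm illumination, 55x lateral magnification onto a camera with 5.5 um
#' pixels (0.1 um object-space pixel), NA 0.5, 30 frames/s.
#'
#' @param wavelength illumination wavelength, micrometres.
#' @param magnification lateral magnification (dimensionless).
#' @param camera_pitch camera pixel pitch, micrometres.
#' @param numerical_aperture objective NA.
#' @param frame_rate frames per second.
#' @return An object of class `optical_config` with derived field
#'   `pixel_size` (object space, um).
#' @export
optical_config <- function(wavelength = 0.488, magnification = 55,
                           camera_pitch = 5.5, numerical_aperture = 0.5,
                           frame_rate = 30) {
  stopifnot(wavelength > 0, magnification > 0, camera_pitch > 0,
            numerical_aperture > 0, frame_rate > 0)
  structure(list(wavelength = wavelength, magnification = magnification,
                 camera_pitch = camera_pitch,
                 numerical_aperture = numerical_aperture,
                 frame_rate = frame_rate,
                 pixel_size = camera_pitch / magnification),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "optical config: lambda %.3f um, M %g, pitch %.2f um (%.3g um/px), NA %.2f, %g fps\n",
    x$wavelength, x$magnification, x$camera_pitch, x$pixel_size,
    x$numerical_aperture, x$frame_rate))
  cat(sprintf("  theoretical lateral resolution 0.82*lambda/NA = %.3f um\n",
              lateral_resolution(x)))
  invisible(x)
}

#' Theoretical lateral resolution
#'
#' The coherent-imaging estimate `0.82 * wavelength / NA` in object-space
#' micrometres.
#'
#' @param config an [optical_config()].
#' @return resolution in micrometres.
#' @export
lateral_resolution <- function(config = optical_config()) {
  0.82 * config$wavelength / config$numerical_aperture
}

#' Flow and rolling-motion specification
#'
#' Motion of a cell rolling along the microfluidic channel, which is tilted by
#' `tilt_angle` degrees with respect to the sensor y axis. Rotation is assumed
#' proportional to translation (constant ratio across frames), the assumption
#' under which rolling angles can be recovered from centroid displacements.
#'
#' @param tilt_angle channel tilt, degrees in `[0, 90]` (default 45).
#' @param translation_per_frame in-plane translation per frame, micrometres.
#' @param rotation_per_frame rotation per frame, degrees.
#' @param n_frames number of frames to simulate.
#' @param noise_sigma additive Gaussian phase noise, radians, applied to the
#'   object phase before interference.
#' @param seed integer RNG seed for the noise stream.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(tilt_angle = 45, translation_per_frame = 0.3,
                      rotation_per_frame = 10, n_frames = 40,
                      noise_sigma = 0.08, seed = 1L) {
  if (tilt_angle < 0 || tilt_angle > 90)
    stopf("tilt_angle must lie in [0, 90] degrees")
  stopifnot(n_frames >= 1, noise_sigma >= 0)
  structure(list(tilt_angle = tilt_angle,
                 translation_per_frame = translation_per_frame,
                 rotation_per_frame = rotation_per_frame,
                 n_frames = as.integer(n_frames),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "flow_spec")
}

#' @export
print.flow_spec <- function(x, ...) {
  cat(sprintf(
    "flow spec: tilt %g deg, %.3g um + %.3g deg per frame, %d frames, phase noise sigma %.3g rad\n",
    x$tilt_angle, x$translation_per_frame, x$rotation_per_frame, x$n_frames,
    x$noise_sigma))
  invisible(x)
}
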