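#' Off-axis hologram frame
#'
#' A single recorded or simulated interference intensity frame. Pixel
#' coordinates are 0-based, row-major, origin top-left; `pixel_pitch` is the
#' object-space sampling in micrometres.
#'
#' @param intensity 2D non-negative real matrix.
#' @param pixel_pitch object-space pixel size, micrometres.
#' @param frame_index integer frame index within a sequence.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, pixel_pitch, frame_index = 1L) {
  if (!is.matrix(intensity)) stopf("hologram intensity must be a matrix")
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stopf("hologram intensity must be finite and non-negative")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be positive")
  structure(list(intensity = intensity, pixel_pitch = pixel_pitch,
                 frame_index = as.integer(frame_index)),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("hologram frame %d: %d x %d px @ %.3g um, intensity [%.3g, %.3g]\n",
              x$frame_index, nrow(x$intensity), ncol(x$intensity),
              x$pixel_pitch, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Demodulated complex amplitude
#'
#' @param field 2D complex matrix.
#' @param pixel_pitch object-space pixel size, micrometres.
#' @param depth_z propagation offset from the recording plane, micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(field, pixel_pitch, depth_z = 0) {
  if (!is.matrix(field)) stopf("field must be a matrix")
  if (!all(is.finite(Re(field))) || !all(is.finite(Im(field))))
    stopf("field must be finite")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be positive")
  structure(list(field = field, pixel_pitch = pixel_pitch, depth_z = depth_z),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex field: %d x %d px @ %.3g um, z offset %.3g um\n",
              nrow(x$field), ncol(x$field), x$pixel_pitch, x$depth_z))
  invisible(x)
}

#' Quantitative phase map
#'
#' Unwrapped optical phase in radians, proportional to the line integral of
#' the refractive-index contrast along the optical axis.
#'
#' @param phase 2D real matrix, radians.
#' @param pixel_pitch object-space pixel size, micrometres.
#' @param frame_index integer frame index.
#' @return An object of class `qpm`.
#' @export
qpm <- function(phase, pixel_pitch, frame_index = 1L) {
  if (!is.matrix(phase) || !all(is.finite(phase)))
    stopf("phase must be a finite matrix")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be positive")
  structure(list(phase = phase, pixel_pitch = pixel_pitch,
                 frame_index = as.integer(frame_index)),
            class = "qpm")
}

#' @export
print.qpm <- function(x, ...) {
  cat(sprintf("QPM frame %d: %d x %d px @ %.3g um, phase [%.3g, %.3g] rad\n",
              x$frame_index, nrow(x$phase), ncol(x$phase), x$pixel_pitch,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' @export
plot.qpm <- function(x, ...) {
  n <- dim(x$phase)
  image(x = (seq_len(n[1]) - 1) * x$pixel_pitch,
        y = (seq_len(n[2]) - 1) * x$pixel_pitch,
        z = x$phase, col = hcl.colors(128, "viridis"), asp = 1,
        xlab = "um", ylab = "um", main = "phase (rad)", ...)
  invisible(x)
}
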