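# End-to-end drivers binding the modules: QPMs -> angles -> sinogram ->
# tomogram, and the repeatability experiment.

#' Reconstruct a tomogram from a QPM sequence
#'
#' Full downstream chain for one rolling cell: centroid tracking, TSI-based
#' full-rotation detection on cell-centered crops, proportional angle
#' assignment, sinogram assembly (de-tilt, crop, phase-to-line-integral
#' conversion), and reconstruction with the named solver.
#'
#' @param qpms list of [qpm()] frames.
#' @param tilt channel tilt, degrees.
#' @param crop_size tomographic crop side, micrometres.
#' @param wavelength illumination wavelength, micrometres.
#' @param solver solver name (see [reconstruct()]).
#' @param min_lag minimum lag for [find_full_rotation()], frames.
#' @param medium_ri immersion-medium RI.
#' @param ... passed to [reconstruct()].
#' @return list with `tomogram`, `track`, `angles` (the `angular_sequence`),
#'   `sinogram` and `frame_of_360`.
#' @export
reconstruct_sequence <- function(qpms, tilt = 45, crop_size = 12,
                                 wavelength = 0.488, solver = "hotv-2",
                                 min_lag = 10L, medium_ri = 1.334, ...) {
  track <- track_centroids(qpms)
  px <- qpms[[1]]$pixel_pitch
  size_px <- round(crop_size / px)
  centered <- recenter_qpms(qpms, track, size_px)
  f360 <- find_full_rotation(centered, min_lag = min_lag)
  track$frame_of_360 <- as.integer(f360)
  track$L360 <- track$track$l[f360]
  angles <- assign_angles(track)
  s <- build_sinogram(qpms, angles, track = track, tilt = tilt,
                      crop_size = crop_size, wavelength = wavelength,
                      medium_ri = medium_ri)
  tomo <- reconstruct(s, solver, ...)
  list(tomogram = tomo, track = track, angles = angles, sinogram = s,
       frame_of_360 = as.integer(f360))
}

#' Repeatability experiment on simulated observations
#'
#' Emulates re-observing the same cell: `n_observations` rolling sequences of
#' one phantom are simulated with independent noise, each processed
#' independently through the full hologram -> QPM -> angle-recovery ->
#' reconstruction chain, and the pairwise Pearson correlation matrix of the
#' resulting tomograms is reported.
#'
#' @param spec a [phantom_spec()] (the one cell).
#' @param flow a [flow_spec()]; observation `i` uses noise seed
#'   `flow$seed + i`.
#' @param config an [optical_config()].
#' @param n_observations number of repeated observations.
#' @param frame_size camera frame side, pixels.
#' @param crop_size tomographic crop, micrometres.
#' @param solver reconstruction solver.
#' @param denoise apply windowed-Fourier denoising during processing.
#' @return list with `correlation` (matrix), `mean_correlation`, `tomograms`.
#' @export
repeatability_experiment <- function(spec, flow = flow_spec(),
                                     config = optical_config(),
                                     n_observations = 5L,
                                     frame_size = 160L, crop_size = 12,
                                     solver = "hotv-2", denoise = FALSE) {
  tomos <- vector("list", n_observations)
  for (i in seq_len(n_observations)) {
    fl <- flow
    fl$seed <- flow$seed + i
    seq_i <- simulate_rolling_sequence(spec, fl, config, frame_size)
    proc <- process_hologram_sequence(seq_i$holograms, seq_i$reference,
                                      config, denoise = denoise)
    res <- reconstruct_sequence(proc$qpms, tilt = fl$tilt_angle,
                                crop_size = crop_size,
                                wavelength = config$wavelength,
                                solver = solver)
    tomos[[i]] <- res$tomogram
  }
  cm <- correlation_matrix(tomos)
  list(correlation = cm,
       mean_correlation = attr(cm, "mean_off_diagonal"),
       tomograms = tomos)
}
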