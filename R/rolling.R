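# Rolling-angle recovery: centroid tracking, Tamura similarity index, full-
# rotation detection, and proportional angle assignment.

#' Track the cell centroid across a QPM sequence
#'
#' Each frame is thresholded (Otsu by default), the single qualifying
#' connected component is located, and its phase-weighted centroid computed
#' with sub-pixel precision. Coordinates are re-expressed in micrometres
#' relative to the frame-1 centroid; the displacement `l` of each frame feeds
#' the proportional angle assignment.
#'
#' @param qpms list of [qpm()] frames.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed phase threshold in radians
#'   (`threshold_method = "fixed"`).
#' @param min_area minimum component area, pixels.
#' @param border_margin fraction of each frame edge excluded from
#'   thresholding (the apodized border carries no reliable phase).
#' @return An object of class `rolling_track`: data frame columns `frame`,
#'   `x`, `y` (um, relative to frame 1), `l` (um), plus fields
#'   `centroid_px` (absolute row/col centroids) and placeholders
#'   `frame_of_360`, `L360` filled by [assign_angles()].
#' @export
track_centroids <- function(qpms, threshold_method = c("otsu", "fixed"),
                            threshold = NULL, min_area = 20L,
                            border_margin = 0.1) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(qpms) >= 1)
  cent <- matrix(NA_real_, length(qpms), 2)
  for (k in seq_along(qpms)) {
    ph <- qpms[[k]]$phase
    if (border_margin > 0) {
      m <- dim(ph)
      b1 <- ceiling(m[1] * border_margin); b2 <- ceiling(m[2] * border_margin)
      lo <- min(ph[(b1 + 1):(m[1] - b1), (b2 + 1):(m[2] - b2)])
      ph[c(seq_len(b1), m[1] - seq_len(b1) + 1), ] <- lo
      ph[, c(seq_len(b2), m[2] - seq_len(b2) + 1)] <- lo
    }
    rng <- range(ph)
    if (rng[2] <= rng[1]) stopf("frame %d is constant: no cell found", k)
    thr <- if (threshold_method == "otsu") {
      p01 <- (ph - rng[1]) / diff(rng)
      rng[1] + EBImage::otsu(p01, range = c(0, 1)) * diff(rng)
    } else {
      if (is.null(threshold)) stopf("fixed threshold_method needs `threshold`")
      threshold
    }
    mask <- ph > thr
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    ok <- which(sizes >= min_area)
    if (length(ok) == 0) stopf("frame %d: no component above min_area", k)
    if (length(ok) > 1)
      stopf("frame %d: %d qualifying components (expected 1)", k, length(ok))
    sel <- lab == ok
    w <- ph * sel
    w[w < 0] <- 0
    tot <- sum(w)
    rows <- row(ph); cols <- col(ph)
    cent[k, ] <- c(sum(rows * w), sum(cols * w)) / tot
  }
  px <- qpms[[1]]$pixel_pitch
  rel <- sweep(cent, 2, cent[1, ]) * px
  # image x = columns, y = rows
  df <- data.frame(frame = seq_along(qpms), x = rel[, 2], y = rel[, 1],
                   l = sqrt(rowSums(rel^2)))
  structure(list(track = df, centroid_px = cent, pixel_pitch = px,
                 frame_of_360 = NA_integer_, L360 = NA_real_),
            class = "rolling_track")
}

#' @export
print.rolling_track <- function(x, ...) {
  cat(sprintf("rolling track: %d frames, total displacement %.3g um",
              nrow(x$track), max(x$track$l)))
  if (!is.na(x$frame_of_360))
    cat(sprintf(", full turn at frame %d (L360 = %.3g um)",
                x$frame_of_360, x$L360))
  cat("\n")
  invisible(x)
}

#' Tamura similarity index between two phase maps
#'
#' The Tamura coefficient of the absolute frame-difference map after mean-
#' offset removal: near zero for matching maps (plus noise), larger for
#' structured residuals. Minimized when a rolling cell returns to its initial
#' orientation.
#'
#' @param q1,qk two [qpm()]s of identical shape (cell-centered crops).
#' @return scalar TSI (>= 0).
#' @export
tamura_similarity_index <- function(q1, qk) {
  stopifnot(inherits(q1, "qpm"), inherits(qk, "qpm"))
  if (!all(dim(q1$phase) == dim(qk$phase)))
    stopf("phase maps must share the same shape")
  d <- q1$phase - qk$phase
  d <- abs(d - mean(d))
  m <- mean(d)
  if (m < 1e-12) return(0)
  sqrt(mean((d - m)^2)) / m
}

#' Locate the frame completing a full rotation
#'
#' Returns the frame in `search_window` minimizing the TSI against frame 1;
#' the window excludes the first `min_lag` frames to avoid the trivial
#' self-similarity minimum. QPMs should be cell-centered crops (see
#' [recenter_qpms()]).
#'
#' @param qpms list of cell-centered [qpm()]s.
#' @param search_window integer frame range; default `(min_lag + 1):n`.
#' @param min_lag minimum lag, frames.
#' @return frame index of the 360-degree frame, with attribute `"tsi"`.
#' @export
find_full_rotation <- function(qpms, search_window = NULL, min_lag = 10L) {
  n <- length(qpms)
  if (is.null(search_window)) search_window <- seq(min_lag + 1L, n)
  search_window <- search_window[search_window >= 2 & search_window <= n]
  if (length(search_window) == 0) stopf("empty search window")
  tsi <- vapply(search_window, function(k)
    tamura_similarity_index(qpms[[1]], qpms[[k]]), numeric(1))
  out <- search_window[which.min(tsi)]
  attr(out, "tsi") <- data.frame(frame = search_window, tsi = tsi)
  out
}

#' Re-center QPMs on the tracked centroid
#'
#' Shifts each frame so the tracked centroid sits at the crop center and
#' crops a square window, producing the cell-centered maps used by the TSI
#' and the sinogram assembly.
#'
#' @param qpms list of [qpm()]s.
#' @param track a [rolling_track()][track_centroids()].
#' @param size_px crop side, pixels.
#' @param rotate_by optional in-plane rotation (degrees) applied about the
#'   crop center after recentering (used to de-tilt the flow direction).
#' @return list of cropped [qpm()]s.
#' @export
recenter_qpms <- function(qpms, track, size_px, rotate_by = 0) {
  stopifnot(inherits(track, "rolling_track"))
  n <- dim(qpms[[1]]$phase)
  if (size_px > min(n)) stopf("crop exceeds frame (frame %d)", 1L)
  lapply(seq_along(qpms), function(k) {
    ph <- qpms[[k]]$phase
    ctr <- (dim(ph) + 1) / 2
    sh <- ctr - track$centroid_px[k, ]
    ph <- shift_image(ph, sh[1], sh[2])
    if (rotate_by != 0) ph <- rotate_image(ph, rotate_by)
    i0 <- floor(ctr[1]) - size_px %/% 2
    j0 <- floor(ctr[2]) - size_px %/% 2
    if (i0 < 0 || j0 < 0 || i0 + size_px > dim(ph)[1] ||
        j0 + size_px > dim(ph)[2])
      stopf("crop exceeds frame (frame %d)", k)
    qpm(ph[i0 + seq_len(size_px), j0 + seq_len(size_px)],
        qpms[[k]]$pixel_pitch, qpms[[k]]$frame_index)
  })
}

#' Assign rolling angles from centroid displacements
#'
#' Proportional rotation/translation assignment: `theta_1 = 0` and
#' `theta_k = 360 * l_k / L360`, where `l_k` is the centroid displacement of
#' frame `k` from frame 1 and `L360` the displacement at the full-rotation
#' frame. Frames beyond the full-rotation frame are discarded from the
#' tomographic set.
#'
#' @param track a [rolling_track()][track_centroids()].
#' @param frame_of_360 index of the full-rotation frame (e.g. from
#'   [find_full_rotation()]); defaults to the one stored in the track.
#' @return An object of class `angular_sequence`: data frame columns `frame`
#'   and `theta_deg` for the retained frames, plus `L360`.
#' @export
assign_angles <- function(track, frame_of_360 = track$frame_of_360) {
  stopifnot(inherits(track, "rolling_track"))
  if (is.na(frame_of_360)) stopf("frame_of_360 is not set")
  frame_of_360 <- as.integer(frame_of_360)
  if (frame_of_360 < 2 || frame_of_360 > nrow(track$track))
    stopf("frame_of_360 out of range")
  L360 <- track$track$l[frame_of_360]
  if (L360 <= 0) stopf("L360 must be positive")
  keep <- seq_len(frame_of_360)
  theta <- 360 * track$track$l[keep] / L360
  theta[1] <- 0
  structure(list(angles = data.frame(frame = keep, theta_deg = theta),
                 frame_of_360 = frame_of_360, L360 = L360),
            class = "angular_sequence")
}

#' @export
print.angular_sequence <- function(x, ...) {
  cat(sprintf(
    "angular sequence: %d frames, 0 to 360 deg (L360 = %.3g um), mean step %.3g deg\n",
    nrow(x$angles), x$L360, mean(diff(x$angles$theta_deg))))
  invisible(x)
}

#' Write an angle table
#'
#' @param track a [rolling_track()][track_centroids()].
#' @param angles an [assign_angles()] result.
#' @param path output CSV path.
#' @return the data frame, invisibly.
#' @export
write_angle_table <- function(track, angles, path) {
  keep <- angles$angles$frame
  df <- cbind(track$track[keep, c("frame", "x", "y", "l")],
              theta_deg = angles$angles$theta_deg)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
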