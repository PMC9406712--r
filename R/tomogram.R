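#' Refractive-index tomogram
#'
#' Container for a 3D refractive-index (RI) volume. Values are absolute RI;
#' the RI contrast relative to the immersion medium is `values - medium_ri`.
#'
#' @param values 3D numeric array of refractive index (dimensionless).
#' @param voxel_size voxel edge length in micrometres.
#' @param medium_ri refractive index of the immersion medium (default 1.334,
#'   aqueous buffer at 488 nm).
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(values, voxel_size, medium_ri = 1.334) {
  if (length(dim(values)) != 3L) stopf("tomogram values must be a 3D array")
  if (!all(is.finite(values))) stopf("tomogram values must be finite everywhere")
  if (voxel_size <= 0) stopf("voxel_size must be positive")
  structure(list(values = values, voxel_size = voxel_size,
                 medium_ri = medium_ri),
            class = "tomogram")
}

#' RI contrast of a tomogram
#'
#' @param t a [tomogram()].
#' @return 3D array of `values - medium_ri`.
#' @export
ri_contrast <- function(t) {
  stopifnot(inherits(t, "tomogram"))
  t$values - t$medium_ri
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("RI tomogram: %d x %d x %d voxels, %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  medium RI %.4f, RI range [%.4f, %.4f]\n",
              x$medium_ri, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
summary.tomogram <- function(object, ...) {
  dn <- ri_contrast(object)
  out <- list(
    dim = dim(object$values),
    voxel_size = object$voxel_size,
    medium_ri = object$medium_ri,
    ri_range = range(object$values),
    max_contrast = max(dn),
    support_voxels = sum(dn > 0),
    support_volume_um3 = sum(dn > 0) * object$voxel_size^3
  )
  class(out) <- "summary.tomogram"
  out
}

#' @export
print.summary.tomogram <- function(x, ...) {
  cat(sprintf("RI tomogram %d x %d x %d @ %.3g um\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size))
  cat(sprintf("  RI in [%.4f, %.4f] (medium %.4f, max contrast %.4f)\n",
              x$ri_range[1], x$ri_range[2], x$medium_ri, x$max_contrast))
  cat(sprintf("  %d voxels above medium (%.1f um^3)\n",
              x$support_voxels, x$support_volume_um3))
  invisible(x)
}

#' Plot central slices of a tomogram
#'
#' Draws the central slice along the chosen axis as an image in physical
#' coordinates (micrometres).
#'
#' @param x a [tomogram()].
#' @param slice slice index; defaults to the central slice.
#' @param axis_id axis (1, 2 or 3) the slice is taken along.
#' @param ... passed to [graphics::image()].
#' @export
plot.tomogram <- function(x, slice = NULL, axis_id = 1, ...) {
  d <- dim(x$values)
  if (is.null(slice)) slice <- ceiling(d[axis_id] / 2)
  m <- switch(axis_id, x$values[slice, , ], x$values[, slice, ],
              x$values[, , slice])
  ext <- (dim(m) - 1) * x$voxel_size
  image(x = seq(0, ext[1], length.out = dim(m)[1]),
        y = seq(0, ext[2], length.out = dim(m)[2]),
        z = m, col = hcl.colors(128, "viridis"), asp = 1,
        xlab = "um", ylab = "um",
        main = sprintf("RI slice %d (axis %d)", slice, axis_id), ...)
  invisible(x)
}
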