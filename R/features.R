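# Single-cell morphometrics and similarity metrics computed from tomograms.

#' Segment the cell in a tomogram
#'
#' Voxels with RI contrast above `threshold` are selected, the largest
#' 6-connected component is retained and its interior cavities filled.
#'
#' @param t a [tomogram()].
#' @param threshold RI-contrast threshold (default: the 0.33-of-maximum
#'   isolevel of the tomogram).
#' @return logical 3D mask array.
#' @export
segment_cell <- function(t, threshold = NULL) {
  stopifnot(inherits(t, "tomogram"))
  dn <- ri_contrast(t)
  if (is.null(threshold)) threshold <- isolevel_thresholds(t, 0.33)
  if (threshold < 0) stopf("threshold must be >= 0")
  mask <- dn > threshold
  if (!any(mask)) stopf("no cell at threshold %.4g", threshold)
  lab <- .label3d_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- lab == which.max(sizes)
  .fill_holes3d_cpp(big)
}

#' Morphometric features of a segmented cell
#'
#' Average RI over the mask, biovolume, equivalent spherical diameter, and
#' dry mass from the integrated RI contrast through the specific refraction
#' increment `alpha` (`dry_mass = sum(delta_n) * voxel^3 / alpha`; with
#' `alpha` in mL/g, i.e. um^3/pg, the mass is in picograms).
#'
#' @param t a [tomogram()].
#' @param mask logical mask from [segment_cell()] (computed if `NULL`).
#' @param alpha specific refraction increment, mL/g (conventional 0.2).
#' @param threshold contrast threshold used if `mask` is `NULL`; recorded in
#'   the output.
#' @return An object of class `feature_record` (also a one-row data frame):
#'   `average_ri`, `biovolume` (um^3), `equivalent_diameter` (um), `dry_mass`
#'   (pg), `segmentation_threshold`, `alpha`.
#' @export
compute_features <- function(t, mask = NULL, alpha = 0.2, threshold = NULL) {
  stopifnot(inherits(t, "tomogram"))
  if (alpha <= 0) stopf("alpha must be positive")
  if (is.null(threshold)) threshold <- isolevel_thresholds(t, 0.33)
  if (is.null(mask)) mask <- segment_cell(t, threshold)
  if (!any(mask)) stopf("empty mask")
  v3 <- t$voxel_size^3
  dn <- ri_contrast(t)
  biovolume <- sum(mask) * v3
  out <- data.frame(
    average_ri = mean(t$values[mask]),
    biovolume = biovolume,
    equivalent_diameter = (6 * biovolume / pi)^(1 / 3),
    dry_mass = sum(dn[mask]) * v3 / alpha,
    segmentation_threshold = threshold,
    alpha = alpha)
  class(out) <- c("feature_record", class(out))
  out
}

#' 3D structural similarity index
#'
#' SSIM between two tomograms with an isotropic Gaussian window (sigma 1.5,
#' 11 voxels), standard constants `K1 = 0.01`, `K2 = 0.03`, dynamic range set
#' by the reference's max - min, averaged over the entire volume.
#'
#' @param t candidate [tomogram()].
#' @param truth reference [tomogram()] (fixes the dynamic range).
#' @param sigma Gaussian window standard deviation, voxels.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim_3d <- function(t, truth, sigma = 1.5) {
  stopifnot(inherits(t, "tomogram"), inherits(truth, "tomogram"))
  x <- t$values; y <- truth$values
  if (!all(dim(x) == dim(y)) || t$voxel_size != truth$voxel_size)
    stopf("tomograms must share shape and voxel size")
  L <- max(y) - min(y)
  if (L <= 0) stopf("reference has zero dynamic range")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  k <- gaussian_kernel(sigma, truncate = 3.5)   # 11 taps at sigma = 1.5
  blur <- function(v) array(.sepconv3_cpp(v, k), dim(v))
  mx <- blur(x); my <- blur(y)
  vx <- blur(x * x) - mx^2
  vy <- blur(y * y) - my^2
  cxy <- blur(x * y) - mx * my
  num <- (2 * mx * my + C1) * (2 * cxy + C2)
  den <- (mx^2 + my^2 + C1) * (vx + vy + C2)
  mean(num / den)
}

#' Pairwise correlation matrix of repeated tomograms
#'
#' Pearson correlation of voxel values for each pair of tomograms of one cell
#' observed repeatedly, after optional rigid centroid alignment (integer
#' voxel shifts of the contrast-weighted centroid onto the first tomogram).
#'
#' @param tomograms list of [tomogram()]s with equal shapes.
#' @param align `"centroid"` (default) or `"none"`.
#' @return symmetric correlation matrix with unit diagonal, with attribute
#'   `"mean_off_diagonal"`.
#' @export
correlation_matrix <- function(tomograms, align = c("centroid", "none")) {
  align <- match.arg(align)
  stopifnot(length(tomograms) >= 2)
  dims <- dim(tomograms[[1]]$values)
  vols <- lapply(tomograms, function(t) {
    stopifnot(inherits(t, "tomogram"))
    if (!all(dim(t$values) == dims)) stopf("tomograms must share shape")
    ri_contrast(t)
  })
  if (any(vapply(vols, function(v) max(v) == min(v), logical(1))))
    stopf("constant tomogram: correlation undefined")
  centroid <- function(v) {
    w <- pmax(v, 0); tot <- sum(w)
    vapply(1:3, function(ax) sum(slice.index(v, ax) * w) / tot, numeric(1))
  }
  if (align == "centroid") {
    ref <- centroid(vols[[1]])
    vols <- lapply(vols, function(v) {
      sh <- round(ref - centroid(v))
      if (all(sh == 0)) return(v)
      out <- array(0, dims)
      src <- lapply(1:3, function(ax)
        pmin(pmax(seq_len(dims[ax]) - sh[ax], 1), dims[ax]))
      out[] <- v[src[[1]], src[[2]], src[[3]]]
      out
    })
  }
  m <- length(vols)
  cm <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    cm[i, j] <- cm[j, i] <- cor(as.numeric(vols[[i]]), as.numeric(vols[[j]]))
  attr(cm, "mean_off_diagonal") <- mean(cm[upper.tri(cm)])
  cm
}
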