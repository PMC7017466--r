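#' Parallel-beam projection stack
#'
#' Container for simulated raw detector data: one detector image per
#' rotation angle, on a linear intensity scale (Beer-Lambert:
#' `I = I0 exp(-line integral of absorption)`). For a 3D volume the detector
#' images have one row per detector bin and one column per z-slice; the
#' geometry is parallel-beam and slice-stacked, so each z-slice reconstructs
#' independently.
#'
#' @param intensities 3D array `(ndet, nz, nangles)` of positive intensities
#'   (a 2D `(ndet, nangles)` matrix is accepted for a single slice).
#' @param angles_deg strictly increasing projection angles in degrees.
#' @param detector_pixel_um detector bin pitch in micrometres.
#' @param i0_estimate optional per-angle unattenuated-intensity estimates
#'   (filled by [normalize_stack()]).
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(intensities, angles_deg, detector_pixel_um,
                             i0_estimate = NULL) {
  if (length(dim(intensities)) == 2) {
    intensities <- array(intensities,
                         c(nrow(intensities), 1L, ncol(intensities)))
  }
  stopifnot(length(dim(intensities)) == 3)
  if (length(angles_deg) < 2 || any(diff(angles_deg) <= 0)) {
    stop("need >= 2 strictly increasing angles")
  }
  if (dim(intensities)[3] != length(angles_deg)) {
    stop("angle count does not match intensity pages")
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("all intensities must be positive and finite")
  }
  structure(list(intensities = intensities,
                 angles_deg = as.numeric(angles_deg),
                 detector_pixel_um = as.numeric(detector_pixel_um),
                 i0_estimate = i0_estimate),
            class = "projection_stack")
}

#' Forward-project an absorption phantom (Beer-Lambert, parallel beam)
#'
#' Computes, slice by slice, the parallel line integrals of the absorption
#' field at each angle and converts them to detector intensities
#' `I0 * exp(-integral)`. This is the test oracle for [fbp_reconstruct()].
#'
#' @param phantom_absorption 2D matrix (one slice) or 3D array `(nx, ny, nz)`
#'   of non-negative absorption values (per mm).
#' @param angles_deg projection angles in degrees.
#' @param i0 source intensity; either a single value or one value per angle
#'   (to simulate primary-beam drift).
#' @param voxel_size_um voxel (= detector pixel) size in micrometres.
#' @param ndet number of detector bins; default covers the slice diagonal.
#' @param step_mm ray sampling step; default half a voxel.
#' @return A [projection_stack()].
#' @export
forward_project <- function(phantom_absorption, angles_deg, i0 = 1,
                            voxel_size_um = 100, ndet = NULL,
                            step_mm = NULL) {
  if (any(!is.finite(phantom_absorption))) {
    stop("absorption field contains non-finite values")
  }
  if (any(phantom_absorption < 0)) stop("absorption must be >= 0")
  x <- phantom_absorption
  if (length(dim(x)) == 2 || is.matrix(x)) {
    x <- array(x, c(nrow(x), ncol(x), 1L))
  }
  d <- dim(x)
  pix <- voxel_size_um / 1000
  if (is.null(ndet)) ndet <- ceiling(sqrt(d[1]^2 + d[2]^2)) + 2L
  if (is.null(step_mm)) step_mm <- pix / 2
  if (length(i0) == 1) i0 <- rep(i0, length(angles_deg))
  if (length(i0) != length(angles_deg)) {
    stop("i0 must be scalar or one value per angle")
  }
  if (any(i0 <= 0)) stop("i0 must be positive")
  rad <- angles_deg * pi / 180
  out <- array(0, c(ndet, d[3], length(angles_deg)))
  for (z in seq_len(d[3])) {
    sino <- cpp_project_slice(x[, , z], rad, as.integer(ndet), pix, pix,
                              step_mm)
    out[, z, ] <- sweep(exp(-sino), 2, i0, `*`)
  }
  projection_stack(out, angles_deg, voxel_size_um)
}

#' Detect the unattenuated intensity of one projection
#'
#' Estimates the per-projection I0 from detector regions the specimen does
#' not cover: the median of the top decile of border-column pixels. If the
#' border estimate is unstable (specimen fills the detector), falls back to
#' the global maximum with a warning.
#'
#' @param projection matrix of intensities (detector bins x slices), or a
#'   vector for a single detector row.
#' @param border_fraction fraction of detector bins at each edge treated as
#'   candidate air regions.
#' @return A positive scalar I0 estimate.
#' @export
detect_unattenuated_intensity <- function(projection, border_fraction = 0.1) {
  p <- as.matrix(projection)
  ndet <- nrow(p)
  nb <- max(1L, floor(border_fraction * ndet))
  border <- c(p[seq_len(nb), ], p[seq(ndet - nb + 1L, ndet), ])
  top <- sort(border, decreasing = TRUE)
  top <- top[seq_len(max(1L, ceiling(length(top) / 10)))]
  est <- stats::median(top)
  # air pixels are the brightest in the image; if the border estimate sits
  # well below the global maximum the borders are shadowed by the specimen
  gmax <- max(p)
  if (est < 0.8 * gmax) {
    warning("no stable air region on projection borders; falling back to global maximum")
    est <- gmax
  }
  est
}

#' Fill per-projection I0 estimates into a stack
#'
#' @param stack a [projection_stack()].
#' @param border_fraction passed to [detect_unattenuated_intensity()].
#' @return The stack with `i0_estimate` set (one value per angle).
#' @export
normalize_stack <- function(stack, border_fraction = 0.1) {
  stopifnot(inherits(stack, "projection_stack"))
  na <- length(stack$angles_deg)
  stack$i0_estimate <- vapply(
    seq_len(na),
    function(a) detect_unattenuated_intensity(stack$intensities[, , a],
                                              border_fraction),
    numeric(1))
  stack
}

# Hann-windowed ramp filter applied along the detector axis of a sinogram
# (ndet x nangles), returning filtered values in absorption / mm units.
ramp_filter <- function(sino, ds) {
  ndet <- nrow(sino)
  npad <- 2^ceiling(log2(2 * ndet))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * ds)
  f_ny <- 1 / (2 * ds)
  hann <- 0.5 * (1 + cos(pi * freq / f_ny))
  H <- abs(freq) * hann
  padded <- rbind(sino, matrix(0, npad - ndet, ncol(sino)))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / npad
  filt[seq_len(ndet), , drop = FALSE]
}

#' Filtered back projection of a normalized projection stack
#'
#' Per z-slice: log-normalize each projection with its detected I0
#' (`-ln(I / I0)` — reconstructions are therefore invariant to primary-beam
#' intensity drift), apply a Hann-windowed ramp filter along the detector
#' axis, and back-project over all angles. The resulting absorption field is
#' mapped linearly to unsigned 16-bit grey values such that the volume
#' maximum lands at grey 60000; the scale is recorded in the output's
#' `grey_per_absorption` so grey values remain interpretable as absorption.
#'
#' @param stack a [projection_stack()]; if `i0_estimate` is empty it is
#'   filled via [normalize_stack()].
#' @param nx,ny output slice size in voxels; default `ndet` each.
#' @return A [ct_volume()] with voxel size equal to the detector pitch.
#' @export
fbp_reconstruct <- function(stack, nx = NULL, ny = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  if (is.null(stack$i0_estimate)) stack <- normalize_stack(stack)
  angles <- stack$angles_deg
  coverage <- max(angles) - min(angles)
  if (coverage < 180 - 1e-9) {
    stop(sprintf("angular coverage %.4g deg < 180 deg", coverage))
  }
  if (any(stack$intensities <= 0)) stop("non-positive intensities")
  d <- dim(stack$intensities)
  ndet <- d[1]; nz <- d[2]; na <- d[3]
  if (is.null(nx)) nx <- ndet
  if (is.null(ny)) ny <- ndet
  ds <- stack$detector_pixel_um / 1000
  rad <- angles * pi / 180
  dtheta <- mean(diff(rad))
  # periodicity: k half-turns of coverage each measure the same object
  k_half <- max(1, round((coverage + mean(diff(angles))) / 180))

  recon <- array(0, c(nx, ny, nz))
  for (z in seq_len(nz)) {
    sino <- -log(sweep(stack$intensities[, z, , drop = TRUE],
                       2, stack$i0_estimate, `/`))
    sino <- matrix(sino, ndet, na)
    filt <- ramp_filter(sino, ds)
    bp <- cpp_backproject_slice(filt, rad, as.integer(nx), as.integer(ny),
                                ds, ds)
    recon[, , z] <- bp * dtheta / k_half
  }
  recon[recon < 0] <- 0
  max_abs <- max(recon)
  gpa <- if (max_abs > 0) 60000 / max_abs else 1
  grey <- round(recon * gpa)
  ct_volume(grey, stack$detector_pixel_um, gpa)
}
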