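#' Reconstructed grey-value volume
#'
#' The in-memory form of a reconstructed CT scan: a 3D array of unsigned
#' 16-bit grey values together with the two pieces of metadata without which
#' grey values are meaningless — the voxel spacing and the linear
#' grey-to-absorption scale. Absorption at a voxel is
#' `grey / grey_per_absorption`; the scale is established once per volume at
#' reconstruction (or phantom generation) time and travels with the data
#' through cropping and slicing.
#'
#' Array axes are `(x, y, z)` with `z` the vertical (rachis) axis. Voxel
#' indices are 1-based; the world coordinate of the centre of voxel `i` along
#' an axis is `(i - 0.5) * voxel_size_mm`.
#'
#' @param grey 3D numeric array of integer grey values in `[0, 65535]`.
#' @param voxel_size_um positive voxel spacing in micrometres (isotropic).
#' @param grey_per_absorption positive scale: grey value per unit absorption.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(grey, voxel_size_um, grey_per_absorption) {
  stopifnot(is.array(grey), length(dim(grey)) == 3)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      voxel_size_um <= 0) {
    stop("voxel_size_um must be a single positive number")
  }
  if (!is.numeric(grey_per_absorption) || length(grey_per_absorption) != 1 ||
      grey_per_absorption <= 0) {
    stop("grey_per_absorption must be a single positive number")
  }
  structure(
    list(grey = grey,
         voxel_size_um = as.numeric(voxel_size_um),
         grey_per_absorption = as.numeric(grey_per_absorption)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$grey)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels @ %.4g um, grey/absorption = %.6g\n",
    d[1], d[2], d[3], x$voxel_size_um, x$grey_per_absorption))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$grey)

#' Convert a volume's grey values to absorption
#'
#' @param volume a [ct_volume].
#' @return Numeric 3D array of absorption values (grey divided by the
#'   volume's `grey_per_absorption` scale).
#' @export
absorption <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$grey / volume$grey_per_absorption
}

# voxel size in mm (internal convenience)
voxel_mm <- function(volume) volume$voxel_size_um / 1000

#' Crop a volume to a voxel-index box
#'
#' Metadata (voxel size, absorption scale) is preserved; the crop offset is
#' recorded so world coordinates can be reconstructed.
#'
#' @param volume a [ct_volume].
#' @param box integer vector `c(x0, x1, y0, y1, z0, z1)` of 1-based inclusive
#'   index ranges.
#' @return A `ct_volume` with an `offset_voxels` attribute (0-based offset of
#'   the crop within the parent volume).
#' @export
crop_volume <- function(volume, box) {
  stopifnot(inherits(volume, "ct_volume"), length(box) == 6)
  d <- dim(volume$grey)
  box <- as.integer(box)
  if (any(box[c(1, 3, 5)] < 1) || box[2] > d[1] || box[4] > d[2] ||
      box[6] > d[3] || any(box[c(2, 4, 6)] < box[c(1, 3, 5)])) {
    stop("crop box out of range")
  }
  out <- ct_volume(volume$grey[box[1]:box[2], box[3]:box[4], box[5]:box[6],
                               drop = FALSE],
                   volume$voxel_size_um, volume$grey_per_absorption)
  attr(out, "offset_voxels") <- box[c(1, 3, 5)] - 1L
  out
}

#' Write a volume as a multi-page 16-bit TIFF stack with a JSON sidecar
#'
#' One TIFF page per z-slice; the sidecar (`<path>.json`) records
#' `voxel_size_um` and `grey_per_absorption` (plus any extra metadata given),
#' because grey values are never interpreted without the absorption scale.
#'
#' @param volume a [ct_volume].
#' @param path output TIFF path.
#' @param extra named list of additional sidecar entries (e.g. `rng_seed`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, extra = list()) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume$grey
  pages <- lapply(seq_len(dim(g)[3]), function(z) g[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  sidecar <- c(list(voxel_size_um = volume$voxel_size_um,
                    grey_per_absorption = volume$grey_per_absorption,
                    dim = dim(g)),
               extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist and carry
#'   `voxel_size_um` and `grey_per_absorption` — a missing scale is a hard
#'   error, never guessed.
#' @return A [ct_volume]; extra sidecar fields are attached as the
#'   `sidecar` attribute.
#' @export
read_volume <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar file: ", sidecar_path)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("voxel_size_um", "grey_per_absorption")) {
    if (is.null(sidecar[[key]])) {
      stop("sidecar is missing required key '", key, "'")
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d1 <- dim(pages[[1]])
  grey <- array(0, dim = c(d1[1], d1[2], nz))
  for (z in seq_len(nz)) grey[, , z] <- round(pages[[z]] * 65535)
  vol <- ct_volume(grey, sidecar$voxel_size_um, sidecar$grey_per_absorption)
  attr(vol, "sidecar") <- sidecar
  vol
}
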