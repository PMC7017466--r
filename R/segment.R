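#' Segmentation parameters
#'
#' Tunables of the grain/chaff separation and the touching-seed splitter.
#' Grain is separated from chaff by a two-threshold scheme: a global Otsu
#' threshold on absorption separates material from air, and a second Otsu
#' threshold on the material voxels exploits the higher density of grain
#' (applied only when the material histogram is bimodal). Thin chaff
#' remnants are removed by morphological opening; fused seeds are split by a
#' distance-transform marker watershed.
#'
#' @param grain_threshold absorption threshold overriding the automatic
#'   two-stage Otsu estimate (`NULL` = automatic).
#' @param min_grain_absorption floor on the automatic grain threshold, in
#'   the volume's normalized absorption units. Grain is markedly denser
#'   than rachis/glumes/awns; the floor keeps a fully aborted ear (chaff
#'   only) from being mistaken for grain when the histogram offers no grain
#'   mode. Ignored when `grain_threshold` is given.
#' @param opening_radius_mm ball radius of the morphological opening that
#'   deletes awns/glumes; 0 disables.
#' @param marker_min_distance_mm minimum separation between watershed
#'   markers; fused regions with two distance-map maxima at least this far
#'   apart are split.
#' @param marker_min_radius_mm minimum interior radius (distance-map value)
#'   for a voxel to act as a marker; suppresses spurious maxima.
#' @param saddle_ratio two watershed basins remain separate seeds only when
#'   the distance map between them dips to at most this fraction of the
#'   lower basin peak; shallower saddles are re-merged (they come from the
#'   flat distance ridge of a single elongated seed, not from a fusion
#'   neck).
#' @param min_region_voxels regions smaller than this are treated as debris
#'   and dropped.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(grain_threshold = NULL,
                           min_grain_absorption = 0.4,
                           opening_radius_mm = 0.3,
                           marker_min_distance_mm = 1.5,
                           marker_min_radius_mm = 0.45,
                           saddle_ratio = 0.7,
                           min_region_voxels = 27L) {
  stopifnot(min_grain_absorption >= 0,
            opening_radius_mm >= 0, marker_min_distance_mm > 0,
            marker_min_radius_mm >= 0, saddle_ratio > 0, saddle_ratio <= 1,
            min_region_voxels >= 1)
  structure(list(grain_threshold = grain_threshold,
                 min_grain_absorption = min_grain_absorption,
                 opening_radius_mm = opening_radius_mm,
                 marker_min_distance_mm = marker_min_distance_mm,
                 marker_min_radius_mm = marker_min_radius_mm,
                 saddle_ratio = saddle_ratio,
                 min_region_voxels = as.integer(min_region_voxels)),
            class = "segment_params")
}

# Euclidean distance transform (mm) of a logical mask, with everything
# outside the array border counted as background.
distance_map <- function(mask, vox_mm) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  sq <- cpp_edt_sq(padded, rep(vox_mm, 3))
  sqrt(sq[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)])
}

# Morphological opening by a ball of radius r (mm) via two distance
# transforms (erosion: distance-to-background > r; dilation back).
open_ball <- function(mask, r_mm, vox_mm) {
  if (r_mm <= 0) return(mask)
  d2 <- cpp_edt_sq(mask, rep(vox_mm, 3))
  eroded <- d2 > r_mm^2
  dim(eroded) <- dim(mask)
  d2c <- cpp_edt_sq(!eroded, rep(vox_mm, 3))
  opened <- eroded | (d2c <= r_mm^2 + 1e-12)
  dim(opened) <- dim(mask)
  opened & mask
}

#' Separate the ears within a multi-ear scan
#'
#' Scans hold several ears side by side. A coarse (downsampled) foreground
#' mask is dilated so the parts of one ear (rachis, seeds, awns) merge into
#' one blob while distinct ears, which are several millimetres apart, stay
#' separate; connected components of the blobs are counted against
#' `expected_ears` and each ear is cropped out at full resolution with a
#' principal-axis estimate of its rachis line.
#'
#' @param volume a [ct_volume()].
#' @param expected_ears number of ears the scan is known to contain.
#' @param downsample integer stride of the coarse analysis grid.
#' @param close_mm dilation radius (mm) used to merge the parts of one ear.
#' @param margin_mm crop margin around each ear.
#' @return List of `ear_volume` objects ordered left to right by centroid,
#'   each with elements `volume` (cropped [ct_volume]), `axis_origin`,
#'   `axis_direction` (unit, positive vertical component), `ear_index`, and
#'   `offset_voxels` (0-based offset of the crop in the parent volume).
#' @export
separate_ears <- function(volume, expected_ears, downsample = 4L,
                          close_mm = 2, margin_mm = 1) {
  stopifnot(inherits(volume, "ct_volume"), expected_ears >= 1)
  vox_mm <- voxel_mm(volume)
  d <- dim(volume$grey)
  ds <- as.integer(downsample)
  sub <- volume$grey[seq(1, d[1], by = ds), seq(1, d[2], by = ds),
                     seq(1, d[3], by = ds), drop = FALSE]
  thr <- otsu_threshold(as.numeric(sub))
  fg <- sub > thr
  if (!any(fg)) stop("no foreground found; expected ", expected_ears, " ears")
  w <- max(1L, ceiling(close_mm / (vox_mm * ds)))
  blob <- cpp_box_max_filter(array(as.numeric(fg), dim(fg)),
                             rep(w, 3L)) > 0
  dim(blob) <- dim(fg)
  lab <- cpp_label_components(blob, 26L)
  sizes <- tabulate(lab[fg], nbins = attr(lab, "n_components"))
  keep <- which(sizes >= 32)  # coarse voxels of real foreground per blob
  if (length(keep) != expected_ears) {
    stop(sprintf("found %d ear component(s), expected %d",
                 length(keep), expected_ears))
  }
  fg_idx <- which(fg, arr.ind = TRUE)
  fg_lab <- lab[fg]
  ears <- lapply(keep, function(k) {
    pts <- fg_idx[fg_lab == k, , drop = FALSE]
    # back to full-resolution voxel indices
    full <- sweep(pts - 1L, 2, rep(ds, 3), `*`) + 1L
    m <- ceiling(margin_mm / vox_mm)
    box <- c(max(1L, min(full[, 1]) - m), min(d[1], max(full[, 1]) + ds + m),
             max(1L, min(full[, 2]) - m), min(d[2], max(full[, 2]) + ds + m),
             max(1L, min(full[, 3]) - m), min(d[3], max(full[, 3]) + ds + m))
    cropped <- crop_volume(volume, box)
    # principal axis of the coarse foreground, in the cropped frame (mm)
    pts_mm <- sweep(voxel_centre_mm(full, vox_mm), 2,
                    (box[c(1, 3, 5)] - 1) * vox_mm)
    ctr <- colMeans(pts_mm)
    ev <- eigen(stats::cov(pts_mm), symmetric = TRUE)
    axis <- ev$vectors[, 1]
    if (axis[3] < 0) axis <- -axis
    list(volume = cropped,
         axis_origin = ctr,
         axis_direction = axis,
         offset_voxels = attr(cropped, "offset_voxels"),
         centroid_x_mm = mean(voxel_centre_mm(full[, 1], vox_mm)))
  })
  ord <- order(vapply(ears, `[[`, 0, "centroid_x_mm"))
  ears <- ears[ord]
  for (i in seq_along(ears)) {
    ears[[i]]$ear_index <- i
    class(ears[[i]]) <- "ear_volume"
  }
  ears
}

#' Build a seed region from a voxel mask
#'
#' Low-level constructor, mainly for building regions from rasterized test
#' shapes or externally produced masks. The mask's TRUE voxels become the
#' region; grey values default to the absorption scale (i.e. absorption 1
#' per voxel) when no grey array is given.
#'
#' @param mask 3D logical array.
#' @param voxel_size_um voxel size in micrometres.
#' @param grey_per_absorption grey-to-absorption scale.
#' @param grey optional 3D numeric array of grey values matching `mask`.
#' @param label region label.
#' @return A `seed_region`.
#' @export
seed_region_from_mask <- function(mask, voxel_size_um = 100,
                                  grey_per_absorption = 1, grey = NULL,
                                  label = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, any(mask))
  coords <- which(mask, arr.ind = TRUE)
  g <- if (is.null(grey)) rep(grey_per_absorption, nrow(coords)) else
    grey[coords]
  make_seed_region(label, coords, g,
                   list(voxel_size_um = voxel_size_um,
                        grey_per_absorption = grey_per_absorption))
}

# Build a seed_region from voxel coordinates within an ear volume.
make_seed_region <- function(label, coords, grey_values, volume,
                             touches_another = FALSE) {
  bbox <- c(range(coords[, 1]), range(coords[, 2]), range(coords[, 3]))
  structure(list(label = as.integer(label),
                 coords = coords,
                 grey = grey_values,
                 bbox = as.integer(bbox),
                 voxel_size_um = volume$voxel_size_um,
                 grey_per_absorption = volume$grey_per_absorption,
                 touches_another = isTRUE(touches_another)),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("<seed_region> label %d, %d voxels%s\n", x$label,
              nrow(x$coords), if (x$touches_another) " (split)" else ""))
  invisible(x)
}

# Logical mask of a region over its bounding box, padded by `pad` background
# voxels on every side.
region_mask <- function(region, pad = 1L) {
  b <- region$bbox
  d <- c(b[2] - b[1], b[4] - b[3], b[6] - b[5]) + 1L + 2L * pad
  m <- array(FALSE, d)
  m[cbind(region$coords[, 1] - b[1], region$coords[, 2] - b[3],
          region$coords[, 3] - b[5]) + 1L + pad] <- TRUE
  m
}

# Grey-value block of a region over its bounding box (0 outside the region).
region_block <- function(region, pad = 1L) {
  b <- region$bbox
  d <- c(b[2] - b[1], b[4] - b[3], b[6] - b[5]) + 1L + 2L * pad
  g <- array(0, d)
  g[cbind(region$coords[, 1] - b[1], region$coords[, 2] - b[3],
          region$coords[, 3] - b[5]) + 1L + pad] <- region$grey
  g
}

# World-coordinate (mm) voxel centres of a region within its ear volume.
region_coords_mm <- function(region) {
  voxel_centre_mm(region$coords, region$voxel_size_um / 1000)
}

# World coordinates (mm) of the region's surface voxels only (those with a
# face neighbour outside the region). Extent-type descriptors (minimum
# covering sphere, Feret widths) are determined by boundary voxels, so they
# can be computed on this much smaller set without changing the result.
region_surface_coords_mm <- function(region) {
  m <- region_mask(region, pad = 1L)
  d <- dim(m)
  core <- m[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  filled <-
    m[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE] &
    m[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE] &
    m[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1), drop = FALSE] &
    m[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1), drop = FALSE] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2), drop = FALSE] &
    m[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3], drop = FALSE]
  surf <- which(core & !filled, arr.ind = TRUE)
  b <- region$bbox
  surf[, 1] <- surf[, 1] + b[1] - 1L
  surf[, 2] <- surf[, 2] + b[3] - 1L
  surf[, 3] <- surf[, 3] + b[5] - 1L
  voxel_centre_mm(surf, region$voxel_size_um / 1000)
}

# Find watershed markers in a component's distance map: local maxima of the
# distance map at least `min_dist` apart and at least `min_radius` deep.
find_markers <- function(edt, vox_mm, min_dist, min_radius) {
  w <- max(1L, round(min_dist / vox_mm))
  mx <- cpp_box_max_filter(edt, rep(w, 3L))
  cand <- which(edt >= min_radius & edt == mx)
  if (length(cand) == 0) return(matrix(0L, 0, 3))
  ai <- arrayInd(cand, dim(edt))
  v <- edt[cand]
  ord <- order(-v)
  ai <- ai[ord, , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(ai))) {
    if (length(chosen) == 0) {
      chosen <- i
    } else {
      dmin <- min(sqrt(rowSums(
        (sweep(ai[chosen, , drop = FALSE], 2, ai[i, ]))^2))) * vox_mm
      if (dmin >= min_dist) chosen <- c(chosen, i)
    }
  }
  ai[chosen, , drop = FALSE]
}

# Split one connected component into seed regions via marker watershed on
# the negated distance map, then undo splits whose inter-basin saddle is
# shallow: two basins stay separate seeds only when the distance map dips to
# at most `saddle_ratio` of the lower basin peak between them. This keeps
# genuinely fused seeds (narrow contact neck) apart while re-merging the
# tied plateau maxima an elongated seed's flat distance ridge produces.
split_component <- function(mask, vox_mm, params) {
  whole <- function() list(list(coords = which(mask, arr.ind = TRUE),
                                split = FALSE))
  edt <- distance_map(mask, vox_mm)
  markers_xyz <- find_markers(edt, vox_mm, params$marker_min_distance_mm,
                              params$marker_min_radius_mm)
  n <- nrow(markers_xyz)
  if (n <= 1) return(whole())
  markers <- array(0L, dim(mask))
  markers[markers_xyz] <- seq_len(n)
  lab <- cpp_watershed(-edt, markers, mask)
  peaks <- edt[markers_xyz]

  # union-find merge of basins separated by shallow saddles
  saddles <- cpp_basin_saddles(lab, edt)
  parent <- seq_len(n)  # integer union-find forest
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(saddles) > 0) {
    for (r in seq_len(nrow(saddles))) {
      a <- find(as.integer(saddles[r, 1]))
      b <- find(as.integer(saddles[r, 2]))
      if (a != b &&
          saddles[r, 3] > params$saddle_ratio * min(peaks[a], peaks[b])) {
        parent[max(a, b)] <- as.integer(min(a, b))
      }
    }
  }
  groups <- vapply(seq_len(n), find, 0L)
  storage.mode(groups) <- "integer"
  for (g in unique(groups)) lab[lab %in% which(groups == g)] <- g
  ids <- unique(groups)
  if (length(ids) <= 1) return(whole())

  sizes <- tabulate(lab[lab > 0], nbins = n)
  big <- ids[sizes[ids] >= params$min_region_voxels]
  if (length(big) <= 1) return(whole())
  tiny <- setdiff(ids, big)
  for (t in tiny) {
    dmk <- rowSums(sweep(markers_xyz[big, , drop = FALSE], 2,
                         markers_xyz[t, ])^2)
    lab[lab == t] <- big[which.min(dmk)]
  }
  lapply(big, function(k) {
    list(coords = which(lab == k, arr.ind = TRUE), split = TRUE)
  })
}

#' Segment the seeds of one ear
#'
#' Separates grain from chaff (rachis, glumes, awns) and air, removes thin
#' structures by morphological opening, labels the remaining 26-connected
#' components, and splits components holding more than one seed with a
#' distance-transform marker watershed. Regions produced by splitting are
#' flagged `touches_another`.
#'
#' @param ear an `ear_volume` from [separate_ears()], or a bare
#'   [ct_volume()] (treated as a single pre-cropped ear).
#' @param params a [segment_params()].
#' @return List of `seed_region` objects ordered bottom to top by centroid;
#'   empty (with a warning) when no voxel exceeds the grain threshold, which
#'   is a valid outcome for fully aborted ears.
#' @export
segment_seeds <- function(ear, params = segment_params()) {
  volume <- if (inherits(ear, "ct_volume")) ear else ear$volume
  stopifnot(inherits(volume, "ct_volume"), inherits(params, "segment_params"))
  vox_mm <- voxel_mm(volume)
  A <- absorption(volume)

  thr <- params$grain_threshold
  if (is.null(thr)) {
    # subsample deterministically for the histograms on big volumes
    vals <- as.numeric(A)
    if (length(vals) > 4e6) vals <- vals[seq(1, length(vals), length.out = 4e6)]
    thr1 <- otsu_threshold(vals)
    mat_vals <- vals[vals > thr1]
    thr <- thr1
    if (length(mat_vals) > 100) {
      thr2 <- otsu_threshold(mat_vals)
      lo <- mat_vals[mat_vals <= thr2]
      hi <- mat_vals[mat_vals > thr2]
      if (length(lo) > 10 && length(hi) > 10 &&
          (mean(hi) - mean(lo)) > 2 * (sd(lo) + sd(hi))) {
        thr <- thr2  # bimodal material: grain is the denser class
      }
    }
    thr <- max(thr, params$min_grain_absorption)
  }
  mask <- A > thr
  if (!any(mask)) {
    warning("no voxels above the grain threshold; returning zero regions")
    return(list())
  }
  mask <- open_ball(mask, params$opening_radius_mm, vox_mm)
  if (!any(mask)) {
    warning("no voxels above the grain threshold after opening; returning zero regions")
    return(list())
  }
  lab <- cpp_label_components(mask, 26L)
  ncomp <- attr(lab, "n_components")
  fg_lin <- which(lab > 0L)
  fg_lab <- lab[fg_lin]
  sizes <- tabulate(fg_lab, nbins = ncomp)
  keep <- which(sizes >= params$min_region_voxels)
  fg_idx <- arrayInd(fg_lin, dim(lab))
  by_comp <- split(seq_along(fg_lin), fg_lab)

  regions <- list()
  for (k in keep) {
    idx <- fg_idx[by_comp[[as.character(k)]], , drop = FALSE]
    b <- c(range(idx[, 1]), range(idx[, 2]), range(idx[, 3]))
    pad <- 1L
    dims_c <- c(b[2] - b[1], b[4] - b[3], b[6] - b[5]) + 1L + 2L * pad
    mask_c <- array(FALSE, dims_c)
    mask_c[cbind(idx[, 1] - b[1], idx[, 2] - b[3], idx[, 3] - b[5]) + 1L +
             pad] <- TRUE
    parts <- split_component(mask_c, vox_mm, params)
    for (p in parts) {
      co <- p$coords
      co[, 1] <- co[, 1] + b[1] - 1L - pad
      co[, 2] <- co[, 2] + b[3] - 1L - pad
      co[, 3] <- co[, 3] + b[5] - 1L - pad
      if (nrow(co) < params$min_region_voxels) next
      grey_vals <- volume$grey[co]
      regions[[length(regions) + 1L]] <-
        make_seed_region(length(regions) + 1L, co, grey_vals, volume,
                         touches_another = p$split)
    }
  }
  if (length(regions) == 0) return(regions)
  cz <- vapply(regions, function(r) mean(r$coords[, 3]), 0)
  regions <- regions[order(cz)]
  for (i in seq_along(regions)) regions[[i]]$label <- i
  regions
}

#' Orient a seed along its principal axes
#'
#' Principal-axis transformation in 3D: eigen-decomposition of the voxel
#' coordinate covariance, eigenvalues descending, with the sign convention
#' that each eigenvector's largest-magnitude component is positive. When
#' eigenvalues tie (an isotropic seed such as a perfect cube or sphere) the
#' eigenbasis is not unique and any orthonormal frame may be returned.
#'
#' @param region a `seed_region`.
#' @return List with `rotation` (3x3, rows are the principal axes; rotated
#'   coordinates are `rotation %*% (x - centroid)`), `centroid_mm`,
#'   `extents_mm` (projected extents along the axes, longest first, plus one
#'   voxel), and `eigenvalues`.
#' @export
orient_seed <- function(region) {
  stopifnot(inherits(region, "seed_region"))
  pts <- region_coords_mm(region)
  if (nrow(pts) < 4) stop("need >= 4 voxels to orient a seed")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] <= 1e-12 * max(ev$values[1], 1e-300)) {
    stop("degenerate covariance: voxels are coplanar")
  }
  R <- t(ev$vectors)  # rows = eigenvectors, eigenvalues descending
  for (i in 1:3) {
    if (R[i, which.max(abs(R[i, ]))] < 0) R[i, ] <- -R[i, ]
  }
  proj <- (pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% t(R)
  vox_mm <- region$voxel_size_um / 1000
  extents <- apply(proj, 2, function(p) diff(range(p))) + vox_mm
  list(rotation = R, centroid_mm = ctr, extents_mm = extents,
       eigenvalues = ev$values)
}

# Trilinear interpolation of a 3D array at fractional voxel indices
# (1-based voxel-centre convention); 0 outside.
trilinear <- function(arr, pts) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    wgt <- (dx * fx + (1 - dx) * (1 - fx)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (dz * fz + (1 - dz) * (1 - fz))
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    if (any(ok)) {
      val[ok] <- val[ok] + wgt[ok] *
        arr[cbind(xi[ok], yi[ok], zi[ok])]
    }
  }
  val
}

#' Cross-section of a seed at its maximum diameter
#'
#' The planar grey-value slice through the seed centroid spanned by the
#' first and second principal axes, resampled at voxel resolution; the 2D
#' view used for fast visual inspection of each seed.
#'
#' @param region a `seed_region`.
#' @param oriented result of [orient_seed()] (computed when `NULL`).
#' @return Numeric matrix (grey values, 0 outside the seed) with attribute
#'   `pixel_size_um`.
#' @export
max_diameter_cross_section <- function(region, oriented = NULL) {
  stopifnot(inherits(region, "seed_region"))
  if (is.null(oriented)) oriented <- orient_seed(region)
  vox_mm <- region$voxel_size_um / 1000
  pad <- 1L
  block <- region_block(region, pad = pad)
  b <- region$bbox
  # centroid in block voxel-index units
  ctr_idx <- oriented$centroid_mm / vox_mm + 0.5 -
    c(b[1], b[3], b[5]) + 1L + pad
  e1 <- oriented$rotation[1, ]
  e2 <- oriented$rotation[2, ]
  n1 <- ceiling(oriented$extents_mm[1] / vox_mm / 2) + 1L
  n2 <- ceiling(oriented$extents_mm[2] / vox_mm / 2) + 1L
  u <- seq(-n1, n1)
  v <- seq(-n2, n2)
  grid <- expand.grid(u = u, v = v)
  pts <- matrix(ctr_idx, nrow(grid), 3, byrow = TRUE) +
    outer(grid$u, e1) + outer(grid$v, e2)
  img <- matrix(trilinear(block, pts), length(u), length(v))
  attr(img, "pixel_size_um") <- region$voxel_size_um
  img
}
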