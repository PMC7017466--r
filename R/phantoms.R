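#' Phantom specification for synthetic reconstructed ear volumes
#'
#' Describes a population of virtual wheat ears to rasterize into a
#' reconstructed grey-value volume with exact per-seed ground truth. The
#' geometry emulates what a normalized CT reconstruction of real ears shows:
#' a vertical rachis, seeds attached in rows around it, thin awns, optional
#' crease cavities and germ notches on stressed seeds, and additive detector
#' noise.
#'
#' Seeds are superellipsoids \eqn{|u/a|^p + |v/b|^p + |w/c|^p \le 1} with the
#' long semiaxis `c` vertical, the short semiaxis `a` pointing radially away
#' from the rachis and `b` tangential. Ranges are sampled uniformly per seed.
#' A `small_seed_fraction` of seeds is scaled by `small_seed_scale`,
#' producing the shrivelled sub-2-mm class seen under combined stress.
#'
#' @param n_ears number of ears placed side by side in one volume.
#' @param seeds_per_ear integer count or length-2 range (inclusive).
#' @param seed_semiaxes_mm list with elements `a`, `b`, `c`: each a single
#'   positive length in mm or a length-2 range. Defaults bracket a healthy
#'   grain of about 23 mm\eqn{^3}.
#' @param small_seed_fraction fraction of seeds drawn from the shrivelled
#'   class (semiaxes scaled by `small_seed_scale`).
#' @param small_seed_scale multiplicative semiaxis scale for small seeds.
#' @param superellipsoid_exponent shape exponent `p`; 2 = ellipsoid, larger
#'   values give more angular seeds.
#' @param crease_fraction fraction in `[0, 1]` of seeds carved with a crease
#'   channel (and germ notch).
#' @param crease_depth_frac crease channel radius as a fraction of the radial
#'   semiaxis `a`.
#' @param germ_notch_frac germ notch sphere radius as a fraction of `b`.
#' @param shrivel_amplitude dimensionless boundary perturbation strength
#'   (`>= 0`); 0 disables.
#' @param touch_fraction fraction of seeds arranged as deliberately touching
#'   pairs (the truth table marks the pairs).
#' @param touch_overlap_mm centre-to-centre shortening that makes a touching
#'   pair's masks meet.
#' @param seed_attenuation absorption of grain material (per mm).
#' @param chaff_attenuation absorption of rachis/awns; must be strictly below
#'   `seed_attenuation` (grain is denser than chaff).
#' @param noise_sd additive Gaussian noise standard deviation in grey values.
#'   The default is 5 % of the seed grey level.
#' @param grey_per_absorption linear grey scale; the default maps the seed
#'   absorption to grey 60000, leaving 16-bit headroom for noise.
#' @param voxel_size_um isotropic voxel size. The default 100 um keeps desk
#'   phantoms small; real scans use finer sampling.
#' @param rachis_radius_mm,awn_fraction,awn_length_mm,awn_radius_mm chaff
#'   geometry.
#' @param n_rows number of seed rows around the rachis.
#' @param phyllotaxis_deg azimuthal angle between consecutive rows.
#' @param seed_gap_mm vertical clearance between consecutive seeds in a row.
#' @param radial_gap_mm clearance between rachis surface and seed.
#' @param margin_mm empty border around the ear.
#' @param max_ear_length_mm packing limit; seeds that will not fit raise an
#'   error naming the first non-placeable seed.
#' @param density_factor true weight per unit (volume x absorption),
#'   g / (mm^3 x absorption unit); used only for the ground-truth weight.
#' @param rng_seed integer seed; identical specs generate identical volumes.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_ears = 1L,
                         seeds_per_ear = c(20L, 60L),
                         seed_semiaxes_mm = list(a = c(1.05, 1.35),
                                                 b = c(1.25, 1.55),
                                                 c = c(2.90, 3.60)),
                         small_seed_fraction = 0.15,
                         small_seed_scale = 0.65,
                         superellipsoid_exponent = 2,
                         crease_fraction = 0.3,
                         crease_depth_frac = 0.5,
                         germ_notch_frac = 0.25,
                         shrivel_amplitude = 0,
                         touch_fraction = 0.1,
                         touch_overlap_mm = 0.25,
                         seed_attenuation = 0.8,
                         chaff_attenuation = 0.3,
                         noise_sd = 3000,
                         grey_per_absorption = 75000,
                         voxel_size_um = 100,
                         rachis_radius_mm = 0.75,
                         awn_fraction = 0.3,
                         awn_length_mm = 8,
                         awn_radius_mm = 0.15,
                         n_rows = 4L,
                         phyllotaxis_deg = 90,
                         seed_gap_mm = 0.4,
                         radial_gap_mm = 0.5,
                         margin_mm = 1,
                         max_ear_length_mm = 150,
                         density_factor = 0.0017,
                         rng_seed = 1L) {
  spec <- as.list(environment())
  norm_range <- function(x, name) {
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || any(!is.finite(x)) || any(x <= 0) || x[1] > x[2]) {
      stop("invalid range for ", name)
    }
    x
  }
  spec$seeds_per_ear <- norm_range(seeds_per_ear, "seeds_per_ear")
  spec$seed_semiaxes_mm <- list(
    a = norm_range(seed_semiaxes_mm$a %||% seed_semiaxes_mm[[1]], "semiaxis a"),
    b = norm_range(seed_semiaxes_mm$b %||% seed_semiaxes_mm[[2]], "semiaxis b"),
    c = norm_range(seed_semiaxes_mm$c %||% seed_semiaxes_mm[[3]], "semiaxis c"))
  if (spec$chaff_attenuation >= spec$seed_attenuation) {
    stop("chaff_attenuation must be strictly below seed_attenuation")
  }
  if (spec$crease_fraction < 0 || spec$crease_fraction > 1) {
    stop("crease_fraction must lie in [0, 1]")
  }
  if (spec$shrivel_amplitude < 0) stop("shrivel_amplitude must be >= 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  for (nm in c("seed_attenuation", "chaff_attenuation", "voxel_size_um",
               "grey_per_absorption", "rachis_radius_mm", "density_factor")) {
    if (spec[[nm]] <= 0) stop(nm, " must be positive")
  }
  if (spec$n_ears < 1) stop("n_ears must be >= 1")
  if (spec$touch_fraction < 0 || spec$touch_fraction > 1) {
    stop("touch_fraction must lie in [0, 1]")
  }
  # resolvability: every semiaxis must span >= 4 voxels
  vox_mm <- spec$voxel_size_um / 1000
  min_semi <- min(unlist(spec$seed_semiaxes_mm)) *
    (if (spec$small_seed_fraction > 0) spec$small_seed_scale else 1)
  if (min_semi < 4 * vox_mm) {
    stop(sprintf(
      "voxel size %.3g um too coarse: smallest semiaxis %.3g mm spans < 4 voxels",
      spec$voxel_size_um, min_semi))
  }
  structure(spec, class = "phantom_spec")
}

# closed-form superellipsoid volume, 8abc Gamma(1+1/p)^3 / Gamma(1+3/p)
superellipsoid_volume <- function(a, b, c, p = 2) {
  8 * a * b * c * gamma(1 + 1 / p)^3 / gamma(1 + 3 / p)
}

# Rasterize one superellipsoid seed into logical mask over a voxel box.
# Returns list(ix, iy, iz, inside) with `inside` an array over the box.
rasterize_seed <- function(seed, dims, vox_mm, p, crease_depth_frac,
                           germ_notch_frac, shrivel_amplitude) {
  a <- seed$a; b <- seed$b; c <- seed$c
  phi <- seed$azimuth_rad
  slack <- 1 + shrivel_amplitude
  rx <- max(a, b) * slack + vox_mm
  ix <- seq(max(1L, floor((seed$cx - rx) / vox_mm)),
            min(dims[1], ceiling((seed$cx + rx) / vox_mm + 1)))
  iy <- seq(max(1L, floor((seed$cy - rx) / vox_mm)),
            min(dims[2], ceiling((seed$cy + rx) / vox_mm + 1)))
  iz <- seq(max(1L, floor((seed$cz - c * slack - vox_mm) / vox_mm)),
            min(dims[3], ceiling((seed$cz + c * slack + vox_mm) / vox_mm + 1)))
  xs <- voxel_centre_mm(ix, vox_mm) - seed$cx
  ys <- voxel_centre_mm(iy, vox_mm) - seed$cy
  zs <- voxel_centre_mm(iz, vox_mm) - seed$cz
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  u <- cos(phi) * X + sin(phi) * Y   # radial (outward from rachis)
  v <- -sin(phi) * X + cos(phi) * Y  # tangential
  m_xy <- abs(u / a)^p + abs(v / b)^p
  m_z <- abs(zs / c)^p
  M <- outer(m_xy, rep(1, nz)) + outer(matrix(1, nx, ny), m_z)
  if (shrivel_amplitude > 0) {
    U <- outer(u, rep(1, nz))
    V <- outer(v, rep(1, nz))
    W <- outer(matrix(0, nx, ny), rep(1, nz)) +
      outer(matrix(1, nx, ny), zs)
    rr <- sqrt(U^2 + V^2 + W^2)
    rr[rr == 0] <- 1e-9
    theta <- acos(pmin(1, pmax(-1, W / rr)))
    azim <- atan2(V, U)
    g <- sin(3 * theta + seed$ph1) * cos(2 * azim + seed$ph2)
    inside <- M^(1 / p) <= 1 + shrivel_amplitude * g
  } else {
    inside <- M <= 1
  }
  if (isTRUE(seed$has_crease)) {
    r_crease <- crease_depth_frac * a
    crease_xy <- (u - a)^2 + v^2 <= r_crease^2
    inside <- inside & !outer(crease_xy, rep(TRUE, nz))
    if (germ_notch_frac > 0) {
      r_g <- germ_notch_frac * b
      g3 <- outer(u^2 + v^2, rep(1, nz)) +
        outer(matrix(1, nx, ny), (zs + c)^2)
      inside <- inside & !(g3 <= r_g^2)
    }
  }
  list(ix = ix, iy = iy, iz = iz, inside = inside)
}

# Place the seeds of one ear: rows around the rachis, staggered vertically,
# deliberately touching pairs stacked in the same row.
layout_ear_seeds <- function(spec, n_seeds) {
  sax <- spec$seed_semiaxes_mm
  small <- runif(n_seeds) < spec$small_seed_fraction
  scale <- ifelse(small, spec$small_seed_scale, 1)
  seeds <- data.frame(
    seed = seq_len(n_seeds),
    a = runif(n_seeds, sax$a[1], sax$a[2]) * scale,
    b = runif(n_seeds, sax$b[1], sax$b[2]) * scale,
    c = runif(n_seeds, sax$c[1], sax$c[2]) * scale,
    small = small,
    has_crease = runif(n_seeds) < spec$crease_fraction,
    awned = runif(n_seeds) < spec$awn_fraction,
    ph1 = runif(n_seeds, 0, 2 * pi),
    ph2 = runif(n_seeds, 0, 2 * pi),
    touch_pair = 0L
  )
  n_pairs <- floor(round(spec$touch_fraction * n_seeds) / 2)
  if (n_pairs > 0) {
    partners <- matrix(seq_len(2 * n_pairs), ncol = 2, byrow = TRUE)
    seeds$touch_pair[partners[, 1]] <- seq_len(n_pairs)
    seeds$touch_pair[partners[, 2]] <- seq_len(n_pairs)
  }

  n_rows <- spec$n_rows
  pitch0 <- 2 * mean(sax$c) + spec$seed_gap_mm
  cursor <- ((seq_len(n_rows) - 1) / n_rows) * pitch0  # stagger rows
  seeds$row <- NA_integer_
  seeds$cz <- NA_real_
  row_i <- 0L
  i <- 1L
  while (i <= n_seeds) {
    row_i <- (row_i %% n_rows) + 1L
    ci <- seeds$c[i]
    z1 <- cursor[row_i] + ci
    pair <- seeds$touch_pair[i] > 0 && i < n_seeds &&
      seeds$touch_pair[i + 1L] == seeds$touch_pair[i]
    if (pair) {
      cj <- seeds$c[i + 1L]
      z2 <- z1 + ci + cj - spec$touch_overlap_mm
      top <- z2 + cj
    } else {
      top <- z1 + ci
    }
    if (top > spec$max_ear_length_mm) {
      stop(sprintf(
        "impossible packing: seed %d cannot be placed within %.4g mm ear length",
        i, spec$max_ear_length_mm))
    }
    seeds$row[i] <- row_i
    seeds$cz[i] <- z1
    if (pair) {
      seeds$row[i + 1L] <- row_i
      seeds$cz[i + 1L] <- z2
      i <- i + 2L
    } else {
      i <- i + 1L
    }
    cursor[row_i] <- top + spec$seed_gap_mm
  }
  seeds$azimuth_rad <- (seeds$row - 1) * spec$phyllotaxis_deg * pi / 180
  r0 <- spec$rachis_radius_mm + spec$radial_gap_mm + seeds$a
  seeds$cx <- r0 * cos(seeds$azimuth_rad)
  seeds$cy <- r0 * sin(seeds$azimuth_rad)
  seeds
}

# Rasterize a thin rod (awn) into an absorption array, value = chaff.
rasterize_rod <- function(absorp, p0, p1, radius, value, vox_mm) {
  dims <- dim(absorp)
  lo <- pmin(p0, p1) - radius - vox_mm
  hi <- pmax(p0, p1) + radius + vox_mm
  ix <- seq(max(1L, floor(lo[1] / vox_mm)), min(dims[1], ceiling(hi[1] / vox_mm)))
  iy <- seq(max(1L, floor(lo[2] / vox_mm)), min(dims[2], ceiling(hi[2] / vox_mm)))
  iz <- seq(max(1L, floor(lo[3] / vox_mm)), min(dims[3], ceiling(hi[3] / vox_mm)))
  if (!length(ix) || !length(iy) || !length(iz)) return(absorp)
  xs <- voxel_centre_mm(ix, vox_mm); ys <- voxel_centre_mm(iy, vox_mm)
  zs <- voxel_centre_mm(iz, vox_mm)
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
  t <- pmin(1, pmax(0, t))
  dist2 <- (X - (p0[1] + t * d[1]))^2 + (Y - (p0[2] + t * d[2]))^2 +
    (Z - (p0[3] + t * d[3]))^2
  sub <- absorp[ix, iy, iz]
  sel <- dist2 <= radius^2
  sub[sel] <- pmax(sub[sel], value)
  absorp[ix, iy, iz] <- sub
  absorp
}

generate_single_ear <- function(spec) {
  vox_mm <- spec$voxel_size_um / 1000
  n_rng <- spec$seeds_per_ear
  n_seeds <- if (n_rng[1] == n_rng[2]) as.integer(n_rng[1]) else
    sample(seq(n_rng[1], n_rng[2]), 1L)
  seeds <- layout_ear_seeds(spec, n_seeds)

  reach <- sqrt(seeds$cx^2 + seeds$cy^2) + pmax(seeds$a, seeds$b) *
    (1 + spec$shrivel_amplitude)
  half_xy <- max(reach, spec$rachis_radius_mm) + spec$margin_mm
  z0 <- spec$margin_mm
  seeds$cz <- seeds$cz + z0
  top <- max(seeds$cz + seeds$c)
  nz <- ceiling((top + (if (any(seeds$awned)) spec$awn_length_mm else 0) +
                   spec$margin_mm) / vox_mm)
  nxy <- 2 * ceiling(half_xy / vox_mm) + 1L
  centre_xy <- (nxy / 2) * vox_mm
  seeds$cx <- seeds$cx + centre_xy
  seeds$cy <- seeds$cy + centre_xy

  absorp <- array(0, dim = c(nxy, nxy, nz))
  labels <- array(0L, dim = c(nxy, nxy, nz))

  # rachis cylinder
  iz_r <- seq(max(1L, floor((z0 * 0.5) / vox_mm)),
              min(nz, ceiling((top + 0.5) / vox_mm)))
  xs <- voxel_centre_mm(seq_len(nxy), vox_mm)
  disc <- outer((xs - centre_xy)^2, (xs - centre_xy)^2, "+") <=
    spec$rachis_radius_mm^2
  sub <- absorp[, , iz_r]
  sub[rep(disc, length(iz_r))] <- spec$chaff_attenuation
  absorp[, , iz_r] <- sub

  # awns: thin rods rising from awned seed tops, tilted outward
  for (k in which(seeds$awned)) {
    s <- seeds[k, ]
    dir_r <- c(cos(s$azimuth_rad), sin(s$azimuth_rad), 0)
    d <- dir_r * 0.35 + c(0, 0, 1)
    d <- d / sqrt(sum(d^2))
    p0 <- c(s$cx, s$cy, s$cz + 0.9 * s$c)
    p1 <- p0 + d * spec$awn_length_mm
    absorp <- rasterize_rod(absorp, p0, p1, spec$awn_radius_mm,
                            spec$chaff_attenuation, vox_mm)
  }

  # seeds (grain attenuation), with collision detection
  seeds$voxel_count <- 0L
  p <- spec$superellipsoid_exponent
  for (k in seq_len(n_seeds)) {
    s <- as.list(seeds[k, ])
    ras <- rasterize_seed(s, dim(absorp), vox_mm, p,
                          spec$crease_depth_frac, spec$germ_notch_frac,
                          spec$shrivel_amplitude)
    inside <- ras$inside
    lsub <- labels[ras$ix, ras$iy, ras$iz]
    clash <- inside & lsub > 0L
    if (any(clash)) {
      other <- unique(lsub[clash])
      pair_ok <- s$touch_pair > 0 &&
        all(seeds$touch_pair[other] == s$touch_pair)
      if (!pair_ok) {
        stop(sprintf(
          "impossible packing: seed %d overlaps seed %d without being a touching pair",
          k, other[1]))
      }
    }
    seeds$voxel_count[k] <- sum(inside)
    lsub[inside & lsub == 0L] <- k
    labels[ras$ix, ras$iy, ras$iz] <- lsub
    asub <- absorp[ras$ix, ras$iy, ras$iz]
    asub[inside] <- pmax(asub[inside], spec$seed_attenuation)
    absorp[ras$ix, ras$iy, ras$iz] <- asub
  }

  if (any(seeds$voxel_count == 0)) {
    stop("seed rasterized to zero voxels; voxel size too coarse")
  }
  list(absorp = absorp, seeds = seeds, centre_xy = centre_xy, z0 = z0,
       ear_top = top)
}

#' Generate a synthetic reconstructed ear volume with ground truth
#'
#' Rasterizes the ear population described by a [phantom_spec()] into a
#' 16-bit grey-value volume (one or more ears side by side) and returns the
#' exact per-seed truth used by the recovery tests: centre, semiaxes,
#' rasterized volume, closed-form (uncarved) volume, attenuation, axial
#' position, crease/touch flags, and per-ear totals including a ground-truth
#' weight `volume x attenuation x density_factor`.
#'
#' Identical specs (including `rng_seed`) produce bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ear_phantom` with elements `volume`
#'   ([ct_volume]), `truth` (list with data frames `seeds` and `ears`), and
#'   `spec`.
#' @export
generate_ear_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, {
    ears <- lapply(seq_len(spec$n_ears), function(e) generate_single_ear(spec))

    gap_vox <- ceiling(5 / (spec$voxel_size_um / 1000))  # 5 mm between ears
    nxs <- vapply(ears, function(e) dim(e$absorp)[1], 0L)
    nys <- vapply(ears, function(e) dim(e$absorp)[2], 0L)
    nzs <- vapply(ears, function(e) dim(e$absorp)[3], 0L)
    nx <- sum(nxs) + gap_vox * (spec$n_ears - 1L)
    ny <- max(nys); nz <- max(nzs)
    absorp <- array(0, dim = c(nx, ny, nz))
    vox_mm <- spec$voxel_size_um / 1000

    seed_rows <- list()
    ear_rows <- list()
    x_off <- 0L
    for (e in seq_len(spec$n_ears)) {
      blk <- ears[[e]]
      d <- dim(blk$absorp)
      absorp[x_off + seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <-
        pmax(absorp[x_off + seq_len(d[1]), seq_len(d[2]), seq_len(d[3])],
             blk$absorp)
      s <- blk$seeds
      s$cx <- s$cx + x_off * vox_mm
      vol_mm3 <- s$voxel_count * vox_mm^3
      axial <- s$cz - min(s$cz)
      seed_rows[[e]] <- data.frame(
        ear = e, seed = s$seed,
        centre_x_mm = s$cx, centre_y_mm = s$cy, centre_z_mm = s$cz,
        semi_a_mm = s$a, semi_b_mm = s$b, semi_c_mm = s$c,
        small = s$small, has_crease = s$has_crease,
        touch_pair = s$touch_pair,
        voxel_count = s$voxel_count,
        volume_mm3 = vol_mm3,
        analytic_volume_mm3 = superellipsoid_volume(
          s$a, s$b, s$c, spec$superellipsoid_exponent),
        mean_attenuation = spec$seed_attenuation,
        min_diameter_true_mm = 2 * pmin(s$a, s$b, s$c),
        weight_g = vol_mm3 * spec$seed_attenuation * spec$density_factor,
        axial_position_mm = axial
      )
      ear_rows[[e]] <- data.frame(
        ear = e,
        n_seeds = nrow(s),
        n_touching = sum(s$touch_pair > 0),
        ear_length_mm = diff(range(s$cz)),
        axis_x_mm = blk$centre_xy + x_off * vox_mm,
        axis_y_mm = blk$centre_xy,
        total_true_volume_mm3 = sum(vol_mm3),
        total_true_weight_g = sum(vol_mm3) * spec$seed_attenuation *
          spec$density_factor,
        n_sieved_true = sum(2 * pmin(s$a, s$b, s$c) >= 2.0),
        n_small_true = sum(2 * pmin(s$a, s$b, s$c) < 2.0)
      )
      x_off <- x_off + d[1] + gap_vox
    }

    grey <- absorp * spec$grey_per_absorption
    if (spec$noise_sd > 0) {
      grey <- grey + rnorm(length(grey), 0, spec$noise_sd)
    }
    grey <- round(pmin(65535, pmax(0, grey)))
    dim(grey) <- c(nx, ny, nz)

    structure(
      list(volume = ct_volume(grey, spec$voxel_size_um,
                              spec$grey_per_absorption),
           truth = list(seeds = do.call(rbind, seed_rows),
                        ears = do.call(rbind, ear_rows)),
           spec = spec),
      class = "ear_phantom")
  })
}

#' @export
print.ear_phantom <- function(x, ...) {
  cat(sprintf("<ear_phantom> %d ear(s), %d seeds, volume %s\n",
              nrow(x$truth$ears), nrow(x$truth$seeds),
              paste(dim(x$volume$grey), collapse = " x ")))
  invisible(x)
}

#' Write a phantom to disk (TIFF volume + truth tables)
#'
#' @param phantom an `ear_phantom` from [generate_ear_volume()].
#' @param dir output directory (created if needed). Writes `volume.tif` with
#'   its JSON sidecar, `truth_seeds.csv` and `truth_ears.json`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ear_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "volume.tif"),
               extra = list(rng_seed = phantom$spec$rng_seed))
  write.csv(phantom$truth$seeds, file.path(dir, "truth_seeds.csv"),
            row.names = FALSE)
  jsonlite::write_json(phantom$truth$ears, file.path(dir, "truth_ears.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
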