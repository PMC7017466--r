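# Independent oracles and shape builders used across the test files.

# --- exhaustive smallest-enclosing-sphere oracle -----------------------------
# The minimum covering sphere is determined by a support set of 1 to 4
# points lying on its boundary. Enumerate every support subset, build the
# sphere with those points on its boundary, and keep the smallest sphere
# that contains all points.

sphere_through_points <- function(P) {
  m <- nrow(P)
  if (m == 1) return(list(centre = P[1, ], radius = 0))
  if (m == 2) {
    c0 <- colMeans(P)
    return(list(centre = c0, radius = sqrt(sum((P[1, ] - c0)^2))))
  }
  # centre = P1 + sum lambda_i (P_i - P1) with (c - P1).(P_i - P1) = |P_i - P1|^2/2
  v <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
  A <- 2 * v %*% t(v)
  b <- rowSums(v^2)
  lam <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(lam)) return(NULL)  # degenerate subset
  c0 <- P[1, ] + as.numeric(t(v) %*% lam)
  list(centre = c0, radius = sqrt(sum((P[1, ] - c0)^2)))
}

min_sphere_bruteforce <- function(points) {
  n <- nrow(points)
  best <- NULL
  for (m in 1:min(4, n)) {
    for (idx in utils::combn(n, m, simplify = FALSE)) {
      s <- sphere_through_points(points[idx, , drop = FALSE])
      if (is.null(s)) next
      d <- sqrt(rowSums(sweep(points, 2, s$centre)^2))
      if (max(d) <= s$radius + 1e-9 &&
          (is.null(best) || s$radius < best$radius)) {
        best <- s
      }
    }
  }
  best
}

# --- brute-force surface scan ------------------------------------------------
surface_count_bruteforce <- function(mask) {
  d <- dim(mask)
  count <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else FALSE,
      if (i < d[1]) mask[i + 1, j, k] else FALSE,
      if (j > 1) mask[i, j - 1, k] else FALSE,
      if (j < d[2]) mask[i, j + 1, k] else FALSE,
      if (k > 1) mask[i, j, k - 1] else FALSE,
      if (k < d[3]) mask[i, j, k + 1] else FALSE)
    if (!all(nb)) count <- count + 1L
  }
  count
}

# --- dense-direction Feret width oracle -------------------------------------
# Width convention shared with the package: voxel-centre extent plus the
# mean of the inner (point) and outer (voxel cube) hull supports. The
# oracle minimizes it independently: a dense random direction scan followed
# by an exhaustive local grid search around the best direction.
feret_width_at <- function(pts_mm, vox_mm, dirs) {
  proj <- pts_mm %*% t(dirs)
  apply(proj, 2, function(p) diff(range(p))) +
    vox_mm * (1 + rowSums(abs(dirs))) / 2
}

min_feret_bruteforce <- function(pts_mm, vox_mm, n_dir = 2048) {
  set.seed(4242)
  dirs <- matrix(rnorm(3 * n_dir), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  widths <- feret_width_at(pts_mm, vox_mm, dirs)
  d0 <- dirs[which.min(widths), ]
  theta0 <- acos(max(-1, min(1, d0[3])))
  phi0 <- atan2(d0[2], d0[1])
  grid <- expand.grid(theta = theta0 + seq(-0.12, 0.12, length.out = 49),
                      phi = phi0 + seq(-0.12, 0.12, length.out = 49))
  gdirs <- cbind(sin(grid$theta) * cos(grid$phi),
                 sin(grid$theta) * sin(grid$phi),
                 cos(grid$theta))
  min(min(widths), min(feret_width_at(pts_mm, vox_mm, gdirs)))
}

# --- rasterized shapes as seed regions --------------------------------------
# Ellipsoid with semiaxes (mm), optionally rotated, digitized at vox mm.
raster_ellipsoid_mask <- function(semi, vox, rot = diag(3)) {
  r_max <- max(semi)
  n <- 2L * ceiling(r_max / vox + 1) + 1L
  ctr <- (n + 1) / 2
  # generic sub-voxel lattice offset: keeps voxel centres off the exact
  # shape centre and boundary (a real scan never aligns with the specimen)
  xs <- ((1:n) - ctr + 0.37) * vox
  X <- array(rep(xs, times = n * n), c(n, n, n))
  Y <- array(rep(rep(xs, each = n), times = n), c(n, n, n))
  Z <- array(rep(xs, each = n * n), c(n, n, n))
  # local coordinates: u = R (x, y, z)
  U <- rot[1, 1] * X + rot[1, 2] * Y + rot[1, 3] * Z
  V <- rot[2, 1] * X + rot[2, 2] * Y + rot[2, 3] * Z
  W <- rot[3, 1] * X + rot[3, 2] * Y + rot[3, 3] * Z
  (U / semi[1])^2 + (V / semi[2])^2 + (W / semi[3])^2 <= 1
}

raster_ellipsoid_region <- function(semi, vox, rot = diag(3),
                                    grey_per_absorption = 1) {
  mask <- raster_ellipsoid_mask(semi, vox, rot)
  seed_region_from_mask(mask, voxel_size_um = vox * 1000,
                        grey_per_absorption = grey_per_absorption)
}

raster_sphere_region <- function(radius, vox, ...) {
  raster_ellipsoid_region(rep(radius, 3), vox, ...)
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

random_rotation <- function() {
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_r)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small default phantoms for the unit tests (few seeds, quick)
tiny_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_ears = 1L, seeds_per_ear = 6L,
                   small_seed_fraction = 0, crease_fraction = 0,
                   touch_fraction = 0, awn_fraction = 0.5,
                   rng_seed = 99L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}
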