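# Per-grain digital traits: covering sphere, aspect ratio, surface, sieve,
# mass index, calibration.

test_that("minimum covering sphere handles the degenerate contracts", {
  s <- min_covering_sphere(matrix(c(1, 2, 3), 1))
  expect_equal(s$centre, c(1, 2, 3))
  expect_equal(s$radius, 0)
  s2 <- min_covering_sphere(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(s2$centre, c(1, 0, 0))
  expect_equal(s2$radius, 1)
  expect_error(min_covering_sphere(matrix(0, 0, 3)), "at least one")
})

test_that("covering sphere agrees with the exhaustive support-set oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    pts <- matrix(runif(3 * n, -5, 5), n, 3)
    got <- min_covering_sphere(pts)
    want <- min_sphere_bruteforce(pts)
    expect_equal(got$radius, want$radius, tolerance = 1e-9)
    d <- sqrt(rowSums(sweep(pts, 2, got$centre)^2))
    expect_lte(max(d), got$radius + 1e-9)
  }
})

test_that("aspect ratio spans its shape limits", {
  # digitized sphere of radius 20 voxels is nearly 1
  expect_gte(aspect_ratio(raster_sphere_region(2, vox = 0.1)), 0.95)
  # 1 x 1 x 200 voxel rod: closed form r_eq / r_mcs
  rod <- array(TRUE, c(1, 1, 200))
  reg <- seed_region_from_mask(rod, voxel_size_um = 1000)
  want <- (3 * 200 / (4 * pi))^(1 / 3) / (199 / 2)
  expect_equal(aspect_ratio(reg), want, tolerance = 0.02)
  # single voxel is 1 by convention
  one <- array(TRUE, c(1, 1, 1))
  expect_equal(aspect_ratio(seed_region_from_mask(one)), 1)
})

test_that("surface voxel counting matches enumeration and brute force", {
  one <- array(TRUE, c(1, 1, 1))
  expect_equal(surface_voxel_count(seed_region_from_mask(one)), 1L)
  cube3 <- array(TRUE, c(3, 3, 3))
  expect_equal(surface_voxel_count(seed_region_from_mask(cube3)), 26L)
  mask <- raster_ellipsoid_mask(c(1, 1, 1), vox = 0.1)  # r = 10 voxels
  reg <- seed_region_from_mask(mask, voxel_size_um = 100)
  expect_equal(surface_voxel_count(reg), surface_count_bruteforce(mask))
  # surface/volume ordering: sphere far below an equal-count plane
  n_vox <- sum(mask)
  side <- floor(sqrt(n_vox))
  plane <- array(TRUE, c(side, side, 1))
  reg_p <- seed_region_from_mask(plane, voxel_size_um = 100)
  sv <- function(r) surface_voxel_count(r) / nrow(r$coords)
  expect_lt(sv(reg), sv(reg_p))
})

test_that("minimal diameter approximates the smallest Feret width", {
  expect_gte(min_diameter(raster_sphere_region(1.25, vox = 0.1)), 2.4)
  expect_lt(min_diameter(raster_sphere_region(0.75, vox = 0.1)), 2.0)
  reg <- raster_ellipsoid_region(c(3, 1.5, 0.8), vox = 0.1)
  got <- min_diameter(reg)
  expect_lt(abs(got - 1.6) / 1.6, 0.05)
  # dense-direction brute force as the oracle
  want <- min_feret_bruteforce(earct:::region_surface_coords_mm(reg), 0.1)
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("aspect ratio and minimal diameter are rotation invariant", {
  set.seed(5)
  ar <- md <- numeric(10)
  for (i in 1:10) {
    reg <- raster_ellipsoid_region(c(2.5, 1.4, 1.1), vox = 0.06,
                                   rot = random_rotation())
    ar[i] <- aspect_ratio(reg)
    md[i] <- min_diameter(reg)
  }
  expect_lt(diff(range(ar)) / mean(ar), 0.03)
  expect_lt(diff(range(md)) / mean(md), 0.03)
  # the lattice-aligned orientation is the degenerate special case; it may
  # deviate by the digitization bias but stays close
  base <- raster_ellipsoid_region(c(2.5, 1.4, 1.1), vox = 0.06)
  expect_lt(abs(min_diameter(base) - mean(md)) / mean(md), 0.06)
  expect_lt(abs(aspect_ratio(base) - mean(ar)) / mean(ar), 0.03)
})

test_that("the sieve partitions exactly and respects its cutoff", {
  tr <- data.frame(seed = 1:6,
                   min_diameter_mm = c(2.5, 1.4, 2.01, 1.99, 3.2, 0.4))
  sv <- apply_sieve(tr, cutoff_mm = 2.0)
  expect_equal(sv$retained$seed, c(1, 3, 5))
  expect_equal(nrow(sv$retained) + nrow(sv$omitted), nrow(tr))
  expect_equal(nrow(apply_sieve(tr, cutoff_mm = 0)$retained), nrow(tr))
})

test_that("mass index and centre of mass follow the absorption weighting", {
  # homogeneous region: V = 10 mm^3 at absorption 0.8 -> 8.0
  mask <- array(TRUE, c(10, 10, 100))  # 10000 voxels at 100 um = 10 mm^3
  grey <- array(0.8, dim(mask))
  reg <- seed_region_from_mask(mask, voxel_size_um = 100,
                               grey_per_absorption = 1, grey = grey)
  mi <- uncalibrated_mass_index(reg)
  expect_equal(mi$mass_index, 8, tolerance = 1e-12)
  expect_equal(mi$volume_mm3, 10, tolerance = 1e-12)
  # two voxels, absorptions 0.2 and 0.6: com sits 0.75 of the way to the
  # denser voxel
  m2 <- array(TRUE, c(2, 1, 1))
  g2 <- array(c(0.2, 0.6), dim(m2))
  mi2 <- uncalibrated_mass_index(
    seed_region_from_mask(m2, voxel_size_um = 1000, grey = g2))
  expect_equal(mi2$centre_of_mass_mm[1], 0.5 + 0.75 * 1)
  # a missing absorption scale is a hard error
  reg_bad <- reg
  reg_bad$grey_per_absorption <- NULL
  expect_error(uncalibrated_mass_index(reg_bad), "grey_per_absorption")
})

test_that("carving voxels decreases volume and mass index monotonically", {
  reg <- raster_sphere_region(0.8, vox = 0.1, grey_per_absorption = 2)
  mask <- earct:::region_mask(reg, pad = 0L)
  set.seed(9)
  prev_mi <- uncalibrated_mass_index(reg)$mass_index
  prev_n <- nrow(reg$coords)
  for (i in 1:20) {
    inside <- which(mask)
    mask[sample(inside, 1)] <- FALSE
    r2 <- seed_region_from_mask(mask, voxel_size_um = 100,
                                grey_per_absorption = 2,
                                grey = array(2, dim(mask)))
    mi <- uncalibrated_mass_index(r2)$mass_index
    expect_lt(mi, prev_mi)
    expect_equal(nrow(r2$coords), prev_n - 1L)
    prev_mi <- mi
    prev_n <- prev_n - 1L
  }
})

test_that("a carved cavity strictly lowers the mass index", {
  solid <- raster_ellipsoid_mask(c(1.5, 1.2, 2.5), vox = 0.1)
  carved <- solid
  carved[15:25, 15:25, 20:35] <- FALSE
  mk <- function(m) uncalibrated_mass_index(
    seed_region_from_mask(m, voxel_size_um = 100))$mass_index
  expect_lt(mk(carved), mk(solid))
})

test_that("calibration recovers the correction factor", {
  v <- c(1, 2, 3, 4)
  cal <- fit_calibration(v, 2 * v)
  expect_equal(cal$factor_k, 2)
  expect_equal(cal$residual_rms, 0)
  # 5% multiplicative noise, true k = 0.05, n = 30: recovered within 2%
  set.seed(7)
  virt <- runif(30, 5, 50)
  act <- 0.05 * virt * (1 + rnorm(30, 0, 0.05))
  cal2 <- fit_calibration(virt, act)
  # closed-form slope as the oracle
  expect_equal(cal2$factor_k, sum(virt * act) / sum(virt^2), tolerance = 1e-12)
  expect_lt(abs(cal2$factor_k - 0.05) / 0.05, 0.02)
  expect_error(fit_calibration(1, 2), "at least 2")
  expect_error(fit_calibration(c(0, 1), c(1, 2)), "positive")
})

test_that("the through-origin estimator is unbiased under multiplicative noise", {
  set.seed(13)
  k_true <- 0.0017
  est <- replicate(200, {
    v <- runif(100, 100, 1200)
    a <- k_true * v * (1 + rnorm(100, 0, 0.1))
    fit_calibration(v, a)$factor_k
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - k_true), 3 * se + 1e-12)
})

test_that("the full trait table checks out against phantom truth", {
  sp <- tiny_phantom_spec(seeds_per_ear = 8L, rng_seed = 41L)
  ph <- generate_ear_volume(sp)
  regs <- segment_seeds(separate_ears(ph$volume, 1)[[1]])
  cal <- fit_calibration(
    vapply(regs, function(r) uncalibrated_mass_index(r)$mass_index, 0)[1:2],
    ph$truth$seeds$weight_g[order(ph$truth$seeds$centre_z_mm)][1:2])
  tt <- compute_all_traits(regs, cal, ear_id = 1L)
  expect_equal(nrow(tt), 8)
  truth <- ph$truth$ears
  expect_lt(abs(sum(tt$volume_mm3) - truth$total_true_volume_mm3) /
              truth$total_true_volume_mm3, 0.05)
  expect_lt(abs(sum(tt$virtual_weight_g) - truth$total_true_weight_g) /
              truth$total_true_weight_g, 0.05)
  expect_true(all(tt$aspect_ratio > 0 & tt$aspect_ratio <= 1))
  expect_true(all(tt$surface_voxels >= 1 & tt$surface_voxels <= tt$voxel_count))
  expect_equal(tt$volume_mm3, tt$voxel_count * (0.1)^3, tolerance = 1e-12)
  # single-voxel region: documented degenerate row
  one <- seed_region_from_mask(array(TRUE, c(1, 1, 1)))
  row1 <- compute_all_traits(list(one))
  expect_equal(row1$aspect_ratio, 1)
  expect_equal(row1$surface_voxels, 1L)
})
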