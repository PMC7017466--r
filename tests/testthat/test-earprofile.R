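# Ear-level aggregation: ordering, profiles, evaluation, group summaries.

fake_traits <- function(z, w, ear_id = 1L, sieve = TRUE) {
  n <- length(z)
  data.frame(ear_id = ear_id, seed_label = seq_len(n),
             voxel_count = 1000L, volume_mm3 = 1,
             virtual_weight_g = w,
             com_x_mm = 0, com_y_mm = 0, com_z_mm = z,
             mean_attenuation = 0.8, aspect_ratio = 0.5,
             surface_voxels = 400L, surface_to_volume = 0.4,
             min_diameter_mm = ifelse(rep_len(sieve, n), 2.4, 1.5),
             passes_sieve = rep_len(sieve, n),
             touches_another = FALSE,
             axial_position_mm = NA_real_, axial_position_norm = NA_real_)
}

test_that("seeds are ordered and positions normalized bottom to top", {
  tt <- order_and_normalize(fake_traits(c(5, 0, 10), c(2, 1, 3)))
  expect_equal(tt$virtual_weight_g, c(1, 2, 3))
  expect_equal(tt$axial_position_norm, c(0, 0.5, 1))
  expect_equal(tt$axial_position_mm, c(0, 5, 10))
  # reversing the axis direction must not flip the bottom seed
  tt2 <- order_and_normalize(fake_traits(c(5, 0, 10), c(2, 1, 3)),
                             axis = list(origin = c(0, 0, 0),
                                         direction = c(0, 0, -1)))
  expect_equal(tt2$virtual_weight_g, c(1, 2, 3))
  # idempotence: re-running on an ordered table is a no-op
  expect_equal(order_and_normalize(tt), tt)
  # single seed sits at position 0
  expect_equal(order_and_normalize(fake_traits(4, 1))$axial_position_norm, 0)
})

test_that("ordering matches the phantom construction", {
  sp <- tiny_phantom_spec(seeds_per_ear = 9L, rng_seed = 19L)
  ph <- generate_ear_volume(sp)
  ear <- separate_ears(ph$volume, 1)[[1]]
  tt <- compute_all_traits(segment_seeds(ear), ear_id = 1L)
  tt <- order_and_normalize(tt, list(origin = ear$axis_origin,
                                     direction = ear$axis_direction))
  truth_z <- sort(ph$truth$seeds$centre_z_mm)
  off_z <- ear$offset_voxels[3] * sp$voxel_size_um / 1000
  expect_equal(order(tt$com_z_mm + off_z), order(truth_z))
  expect_equal(tt$axial_position_norm[1], 0)
  expect_equal(tt$axial_position_norm[nrow(tt)], 1)
})

test_that("weight profiles follow the constructed position pattern", {
  # mid-ear seeds twice as heavy as the extremes -> central maximum
  z <- seq(0, 30, length.out = 21)
  w <- ifelse(abs(z - 15) < 8, 0.04, 0.02)
  rec <- ear_record(order_and_normalize(fake_traits(z, w)))
  prof <- weight_position_profile(list(rec), n_bins = 5)
  expect_equal(which.max(prof$mean_weight_g), 3)
  expect_equal(prof$mean_weight_g[1], 0.02)
  expect_equal(prof$mean_weight_g[5], 0.02)
  # flat weights give a flat profile
  rec2 <- ear_record(order_and_normalize(fake_traits(z, rep(0.03, 21))))
  prof2 <- weight_position_profile(list(rec2), n_bins = 5)
  expect_true(all(abs(prof2$mean_weight_g - 0.03) < 1e-12))
  # single seed occupies exactly one bin; empty bins are NA
  rec3 <- ear_record(order_and_normalize(fake_traits(4, 0.05)))
  prof3 <- weight_position_profile(list(rec3), n_bins = 4)
  expect_equal(sum(prof3$n_seeds), 1)
  expect_equal(sum(is.na(prof3$mean_weight_g)), 3)
  expect_error(weight_position_profile(list(rec), n_bins = 1), "n_bins")
})

test_that("profile mass is conserved exactly", {
  set.seed(3)
  recs <- lapply(1:5, function(e) {
    n <- sample(5:25, 1)
    ear_record(order_and_normalize(
      fake_traits(sort(runif(n, 0, 40)), runif(n, 0.01, 0.05), ear_id = e)))
  })
  prof <- weight_position_profile(recs, n_bins = 20)
  total_from_bins <- sum(prof$mean_weight_g * prof$n_seeds, na.rm = TRUE)
  total_direct <- sum(vapply(recs, function(r) r$total_virtual_weight_g, 0))
  expect_equal(total_from_bins, total_direct, tolerance = 1e-12)
})

test_that("ear records balance their sieve counts and totals", {
  tt <- order_and_normalize(
    rbind(fake_traits(c(0, 5, 10), c(1, 2, 3), sieve = TRUE),
          fake_traits(c(2, 8), c(0.1, 0.2), sieve = FALSE)))
  rec <- ear_record(tt)
  expect_equal(rec$n_seeds_sieved + rec$n_seeds_small, rec$n_seeds)
  expect_equal(rec$total_virtual_weight_g, 6.3, tolerance = 1e-12)
  expect_equal(rec$total_weight_sieved_g, 6, tolerance = 1e-12)
})

test_that("virtual-vs-actual evaluation reports r-squared per contract", {
  recs <- lapply(1:6, function(e) {
    ear_record(order_and_normalize(
      fake_traits(seq(0, 20, length.out = 4 + e), 0.01 * e, ear_id = e)))
  })
  virt <- vapply(recs, function(r) r$total_virtual_weight_g, 0)
  counts <- vapply(recs, function(r) r$n_seeds_sieved, 0)
  actual <- data.frame(ear_id = 1:6, actual_weight_g = virt,
                       actual_count = counts)
  ev <- evaluate_against_actual(recs, actual)
  expect_equal(ev$r2_weight, 1)
  expect_equal(ev$r2_count, 1)
  # invariance under positive affine transforms of the actual values
  actual2 <- transform(actual, actual_weight_g = 3 * actual_weight_g + 0.7)
  expect_equal(evaluate_against_actual(recs, actual2)$r2_weight, 1)
  # constant actual vector: r2 undefined, NA with a message
  actual3 <- transform(actual, actual_weight_g = 1)
  expect_message(ev3 <- evaluate_against_actual(recs, actual3), "constant")
  expect_true(is.na(ev3$r2_weight))
  # disjoint ids cannot be evaluated
  actual4 <- transform(actual, ear_id = ear_id + 100)
  expect_error(evaluate_against_actual(recs, actual4), "fewer than 2")
})

test_that("sample r-squared matches the designed population value", {
  set.seed(21)
  n <- 100
  v <- rnorm(n, 1.5, 0.45)
  a <- v + rnorm(n, 0, 0.15)  # population r2 = 0.45^2/(0.45^2+0.15^2) = 0.9
  recs <- lapply(seq_len(n), function(e) {
    ear_record(fake_traits(c(0, 10), c(v[e] / 2, v[e] / 2), ear_id = e))
  })
  actual <- data.frame(ear_id = seq_len(n), actual_weight_g = a,
                       actual_count = 2)
  suppressMessages(ev <- evaluate_against_actual(recs, actual))
  expect_lt(abs(ev$r2_weight - 0.9), 0.08)
})

test_that("group summaries average per ear before pooling", {
  tt1 <- fake_traits(c(0, 10), c(0.02, 0.04), ear_id = 1L)
  tt2 <- fake_traits(c(0, 10, 20), c(0.06, 0.08, 0.10), ear_id = 2L)
  groups <- data.frame(ear_id = 1:2, group = c("D", "DH"))
  gs <- group_summary(rbind(tt1, tt2), groups)
  w_D <- gs$mean[gs$group == "D" & gs$trait == "seed_weight_g"]
  expect_equal(w_D, 0.03)
  expect_equal(gs$mean[gs$group == "DH" & gs$trait == "seed_weight_g"], 0.08)
  expect_equal(gs$mean[gs$group == "D" & gs$trait == "seed_count"], 2)
  # one ear per group: group mean equals that ear's per-seed mean
  expect_equal(gs$n_ears, rep(1L, nrow(gs)), ignore_attr = TRUE)
  # recovered ordering of two constructed volume populations
  set.seed(2)
  tts <- list()
  grp <- data.frame(ear_id = integer(0), group = character(0))
  for (e in 1:10) {
    big <- e <= 5
    t_e <- fake_traits(seq(0, 20, 5), runif(5, 0.01, 0.05), ear_id = e + 10L)
    t_e$volume_mm3 <- rnorm(5, if (big) 23 else 8, 1)
    tts[[e]] <- t_e
    grp <- rbind(grp, data.frame(ear_id = e + 10L,
                                 group = if (big) "D" else "DH"))
  }
  gs2 <- group_summary(do.call(rbind, tts), grp)
  vol <- setNames(gs2$mean[gs2$trait == "seed_volume_mm3"],
                  gs2$group[gs2$trait == "seed_volume_mm3"])
  expect_gt(vol["D"], vol["DH"])
  # empty labels are excluded with a warning
  grp_bad <- rbind(grp, data.frame(ear_id = 99L, group = ""))
  expect_warning(group_summary(do.call(rbind, tts), grp_bad), "excluded")
})
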