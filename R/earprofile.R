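#' Order seeds along the ear and normalize their positions
#'
#' Sorts seeds bottom to top by the scalar projection of their centre of
#' mass onto the ear axis and fills `axial_position_mm` (distance from the
#' first seed) and `axial_position_norm` (0 = first seed detected at the
#' bottom of the ear, 1 = last seed at the top). The axis direction carries
#' a dominant-vertical sign convention (positive vertical component), so the
#' bottom seed is always position 0 regardless of how the axis was handed
#' in. A single seed sits at position 0 by convention. Re-running on an
#' already ordered table is a no-op.
#'
#' @param traits trait table from [compute_all_traits()] (one ear).
#' @param axis list with `origin` and `direction` (length-3 each), e.g. the
#'   `axis_origin`/`axis_direction` of an `ear_volume`; defaults to the
#'   vertical axis.
#' @return The trait table, sorted, with axial positions filled.
#' @export
order_and_normalize <- function(traits, axis = NULL) {
  stopifnot(is.data.frame(traits))
  if (nrow(traits) == 0) return(traits)
  if (is.null(axis)) axis <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  if (dir[3] < 0) dir <- -dir  # bottom -> top orientation
  com <- as.matrix(traits[, c("com_x_mm", "com_y_mm", "com_z_mm")])
  t_proj <- as.numeric((com - matrix(axis$origin, nrow(com), 3,
                                     byrow = TRUE)) %*% dir)
  ord <- order(t_proj)
  traits <- traits[ord, , drop = FALSE]
  t_proj <- t_proj[ord]
  traits$axial_position_mm <- t_proj - t_proj[1]
  span <- t_proj[length(t_proj)] - t_proj[1]
  traits$axial_position_norm <- if (span > 0) {
    (t_proj - t_proj[1]) / span
  } else {
    rep(0, length(t_proj))
  }
  rownames(traits) <- NULL
  traits
}

#' Aggregate one ear's seeds into an ear record
#'
#' @param traits ordered trait table of one ear (see
#'   [order_and_normalize()]).
#' @param ear_id identifier (taken from the table when `NULL`).
#' @return List of class `ear_record` with the ordered seeds and the
#'   aggregate yield components: total virtual weight (all seeds, summed in
#'   table order), sieved total weight, sieved and sub-sieve seed counts,
#'   and the axial span from first to last seed.
#' @export
ear_record <- function(traits, ear_id = NULL) {
  stopifnot(is.data.frame(traits))
  if (is.null(ear_id)) {
    ear_id <- if (nrow(traits) > 0) traits$ear_id[1] else NA_integer_
  }
  structure(list(
    ear_id = ear_id,
    seeds = traits,
    n_seeds = nrow(traits),
    total_virtual_weight_g = sum(traits$virtual_weight_g),
    total_weight_sieved_g = sum(traits$virtual_weight_g[traits$passes_sieve]),
    n_seeds_sieved = sum(traits$passes_sieve),
    n_seeds_small = sum(!traits$passes_sieve),
    ear_length_seed_span_mm = if (nrow(traits) > 1) {
      max(traits$axial_position_mm) - min(traits$axial_position_mm)
    } else 0
  ), class = "ear_record")
}

#' @export
print.ear_record <- function(x, ...) {
  cat(sprintf(
    "<ear_record> ear %s: %d seeds (%d sieved, %d small), %.4g g virtual\n",
    format(x$ear_id), x$n_seeds, x$n_seeds_sieved, x$n_seeds_small,
    x$total_virtual_weight_g))
  invisible(x)
}

#' Mean seed weight along the normalized ear position
#'
#' Pools the seeds of all ears — including sub-sieve seeds — into bins of
#' width `1/n_bins` over the normalized position `[0, 1]` (last bin closed)
#' and reports the per-bin mean virtual seed weight. Empty bins are reported
#' as `NA`, not zero.
#'
#' @param ears list of `ear_record` objects.
#' @param n_bins number of position bins (>= 2).
#' @return Data frame with `bin`, `position_mid`, `n_seeds`,
#'   `mean_weight_g`.
#' @export
weight_position_profile <- function(ears, n_bins = 20L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(ears) == 0) stop("need at least one ear")
  seeds <- do.call(rbind, lapply(ears, function(e) {
    e$seeds[, c("axial_position_norm", "virtual_weight_g")]
  }))
  if (nrow(seeds) == 0) stop("need at least one seed")
  bin <- pmin(floor(seeds$axial_position_norm * n_bins) + 1L, n_bins)
  n <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) {
    sum(seeds$virtual_weight_g[bin == b])
  }, 0)
  data.frame(bin = seq_len(n_bins),
             position_mid = (seq_len(n_bins) - 0.5) / n_bins,
             n_seeds = n,
             mean_weight_g = ifelse(n > 0, sums / n, NA_real_))
}

#' Evaluate virtual against actual per-ear measurements
#'
#' Pairs each ear's virtual totals with hand-threshed reference
#' measurements and reports coefficients of determination (squared Pearson
#' correlation) for total seed weight and for the count of sieve-passing
#' seeds, plus the scatter pairs for plotting.
#'
#' @param ears list of `ear_record` objects.
#' @param actual data frame with columns `ear_id`, `actual_weight_g`,
#'   `actual_count`.
#' @return List of class `evaluation_report` with `pairs`, `r2_weight`,
#'   `r2_count` (NA with a message when the actual values are constant),
#'   and `unmatched_ids`.
#' @export
evaluate_against_actual <- function(ears, actual) {
  stopifnot(is.data.frame(actual),
            all(c("ear_id", "actual_weight_g", "actual_count") %in%
                  names(actual)))
  virt <- data.frame(
    ear_id = vapply(ears, function(e) e$ear_id, numeric(1)),
    virtual_weight_g = vapply(ears, function(e) e$total_virtual_weight_g,
                              numeric(1)),
    virtual_count = vapply(ears, function(e) e$n_seeds_sieved, numeric(1)))
  pairs <- merge(virt, actual, by = "ear_id")
  unmatched <- c(setdiff(virt$ear_id, actual$ear_id),
                 setdiff(actual$ear_id, virt$ear_id))
  if (nrow(pairs) < 2) stop("fewer than 2 matched ears")
  r2 <- function(v, a) {
    if (sd(a) == 0 || sd(v) == 0) {
      message("constant values: r2 undefined, reported as NA")
      return(NA_real_)
    }
    cor(v, a)^2
  }
  structure(list(pairs = pairs,
                 r2_weight = r2(pairs$virtual_weight_g, pairs$actual_weight_g),
                 r2_count = r2(pairs$virtual_count, pairs$actual_count),
                 unmatched_ids = unmatched),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d ears: r2 weight = %.3f, r2 count = %.3f\n",
              nrow(x$pairs), x$r2_weight, x$r2_count))
  invisible(x)
}

#' Per-group summary of seed-set characteristics
#'
#' Averages each trait per ear first and only then summarizes per group
#' (mean, SD, n of ears) — seeds are never pooled across ears. Covers the
#' six seed-set characteristics: single-seed weight, volume, spherical
#' ratio, surface, mean attenuation, and seed count per ear.
#'
#' @param traits trait table covering one or more ears (`ear_id` column).
#' @param groups data frame with columns `ear_id` and `group`; ears with an
#'   empty or missing group label are excluded with a warning.
#' @return Data frame with one row per group and trait
#'   (`group`, `trait`, `mean`, `sd`, `n_ears`).
#' @export
group_summary <- function(traits, groups) {
  stopifnot(is.data.frame(traits), is.data.frame(groups),
            all(c("ear_id", "group") %in% names(groups)))
  bad <- is.na(groups$group) | groups$group == ""
  if (any(bad)) {
    warning(sum(bad), " ear(s) with empty group label excluded")
    groups <- groups[!bad, , drop = FALSE]
  }
  per_ear <- do.call(rbind, lapply(split(traits, traits$ear_id), function(tt) {
    data.frame(ear_id = tt$ear_id[1],
               seed_weight_g = mean(tt$virtual_weight_g),
               seed_volume_mm3 = mean(tt$volume_mm3),
               spherical_ratio = mean(tt$aspect_ratio),
               seed_surface = mean(tt$surface_voxels),
               mean_attenuation = mean(tt$mean_attenuation),
               seed_count = nrow(tt))
  }))
  merged <- merge(per_ear, groups, by = "ear_id")
  trait_cols <- c("seed_weight_g", "seed_volume_mm3", "spherical_ratio",
                  "seed_surface", "mean_attenuation", "seed_count")
  out <- do.call(rbind, lapply(split(merged, merged$group), function(g) {
    do.call(rbind, lapply(trait_cols, function(tc) {
      data.frame(group = g$group[1], trait = tc,
                 mean = mean(g[[tc]]), sd = sd(g[[tc]]),
                 n_ears = nrow(g))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Plot the seed-weight-by-position profile
#'
#' @param profile output of [weight_position_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_ear_profile <- function(profile, ...) {
  graphics::plot(profile$position_mid, profile$mean_weight_g, type = "b",
                 xlab = "normalized ear position (0 = bottom seed)",
                 ylab = "mean seed weight [g]", ...)
}
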