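#' Grain-set recovery experiment on a synthetic ear population
#'
#' The package's accuracy benchmark: generates a population of single-ear
#' phantoms with known ground truth, runs ear separation, seed segmentation
#' and trait extraction on each, fits the virtual-weight calibration on a
#' subset of ears, and scores three figures of merit against the truth:
#'
#' * `count_accuracy` — pooled fraction of seeds correctly recovered by
#'   segmentation (see [segmentation_count_accuracy()]),
#' * `r2_weight` — coefficient of determination between the calibrated
#'   virtual total seed weight per ear and the ground-truth weight,
#' * `r2_count` — coefficient of determination between virtual and true
#'   sieve-passing seed counts, restricted to the ears generated without
#'   touching pairs.
#'
#' A `touching_ear_fraction` of the ears is generated with deliberately
#' touching seed pairs (a tenth of their seeds, i.e. one to three fused
#' pairs per ear) to exercise the watershed splitter; the remaining ears are
#' touch-free and form the `r2_count` subset.
#'
#' @param n_ears number of phantom ears.
#' @param seeds_per_ear range of seeds per ear, sampled uniformly.
#' @param touching_ear_fraction fraction of ears carrying touching pairs.
#' @param calibration_subset fraction of ears used to fit the weight
#'   calibration (at least 2 ears).
#' @param params a [segment_params()].
#' @param spec_overrides named list of [phantom_spec()] arguments applied to
#'   every ear (e.g. a different `noise_sd`).
#' @param rng_seed integer master seed; per-ear generator seeds are derived
#'   from it.
#' @param progress print one line per ear.
#' @return List with `per_ear` (data frame), `count_accuracy`, `r2_weight`,
#'   `r2_count`, `calibration` (the fitted model), and `n_seeds_total`.
#' @export
grain_recovery_experiment <- function(n_ears = 50L,
                                      seeds_per_ear = c(20L, 60L),
                                      touching_ear_fraction = 0.1,
                                      calibration_subset = 0.1,
                                      params = segment_params(),
                                      spec_overrides = list(),
                                      rng_seed = 1L,
                                      progress = FALSE) {
  stopifnot(n_ears >= 2)
  plan <- with_seed(rng_seed, {
    list(ear_seeds = sample.int(.Machine$integer.max - 1L, n_ears),
         touching = seq_len(n_ears) <= round(touching_ear_fraction * n_ears))
  })
  rows <- vector("list", n_ears)
  for (e in seq_len(n_ears)) {
    args <- c(list(seeds_per_ear = seeds_per_ear,
                   touch_fraction = if (plan$touching[e]) 0.1 else 0,
                   rng_seed = plan$ear_seeds[e]),
              spec_overrides)
    spec <- do.call(phantom_spec, args)
    ph <- generate_ear_volume(spec)
    ear <- separate_ears(ph$volume, 1L)[[1]]
    regions <- segment_seeds(ear, params)
    traits <- compute_all_traits(regions, identity_calibration(), ear_id = e)
    tr_ear <- ph$truth$ears
    rows[[e]] <- data.frame(
      ear = e,
      touching_ear = plan$touching[e],
      n_true = tr_ear$n_seeds,
      n_recovered = nrow(traits),
      n_sieved_true = tr_ear$n_sieved_true,
      n_sieved_recovered = sum(traits$passes_sieve),
      true_weight_g = tr_ear$total_true_weight_g,
      virtual_mass_index = sum(traits$virtual_weight_g),
      true_volume_mm3 = tr_ear$total_true_volume_mm3,
      virtual_volume_mm3 = sum(traits$volume_mm3))
    if (progress) {
      message(sprintf("ear %d/%d: %d/%d seeds", e, n_ears,
                      rows[[e]]$n_recovered, rows[[e]]$n_true))
    }
  }
  per_ear <- do.call(rbind, rows)

  n_fit <- max(2L, ceiling(calibration_subset * n_ears))
  fit_idx <- unique(round(seq(1, n_ears, length.out = n_fit)))
  calib <- fit_calibration(per_ear$virtual_mass_index[fit_idx],
                           per_ear$true_weight_g[fit_idx])
  per_ear$virtual_weight_g <- calib$factor_k * per_ear$virtual_mass_index

  nt <- per_ear[!per_ear$touching_ear, ]
  list(per_ear = per_ear,
       count_accuracy = segmentation_count_accuracy(per_ear$n_recovered,
                                                    per_ear$n_true),
       r2_weight = cor(per_ear$virtual_weight_g, per_ear$true_weight_g)^2,
       r2_count = cor(nt$n_sieved_recovered, nt$n_sieved_true)^2,
       calibration = calib,
       n_seeds_total = sum(per_ear$n_true))
}
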