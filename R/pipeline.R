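#' Pipeline configuration
#'
#' Validated configuration for the end-to-end run: input volume (or phantom
#' specification), ear count, segmentation parameters, sieve cutoff,
#' calibration source and output location. Unknown keys in a config file are
#' rejected at load time.
#'
#' @param out_dir output directory for all artifacts.
#' @param input path to a volume TIFF (with JSON sidecar); `NULL` to
#'   generate the phantom described by `phantom` instead.
#' @param phantom a [phantom_spec()] (used when `input` is `NULL`).
#' @param expected_ears number of ears in the volume; defaults to the
#'   phantom's `n_ears` when a phantom is used.
#' @param sieve_cutoff_mm virtual sieve cutoff, default 2.0 mm.
#' @param segmentation a [segment_params()].
#' @param calibration_file JSON file holding a previously fitted
#'   `factor_k`; overrides subset fitting.
#' @param calibration_subset fraction of ears used to fit the weight
#'   calibration against the actual measurements (default 0.10, i.e. a
#'   subset of about 10 % of ears).
#' @param actual_file CSV with `ear_id, actual_weight_g, actual_count`
#'   reference measurements; for phantom runs the ground truth is used when
#'   no file is given.
#' @param n_bins bins of the seed-weight position profile.
#' @param rng_seed integer seed for the whole run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input = NULL,
                            phantom = NULL,
                            expected_ears = NULL,
                            sieve_cutoff_mm = 2.0,
                            segmentation = segment_params(),
                            calibration_file = NULL,
                            calibration_subset = 0.10,
                            actual_file = NULL,
                            n_bins = 20L,
                            rng_seed = 1L) {
  if (is.null(input) && is.null(phantom)) {
    stop("either an input volume or a phantom spec is required")
  }
  if (!is.null(phantom) && !inherits(phantom, "phantom_spec")) {
    stop("phantom must be a phantom_spec")
  }
  if (!inherits(segmentation, "segment_params")) {
    stop("segmentation must be a segment_params")
  }
  if (sieve_cutoff_mm < 0) stop("sieve_cutoff_mm must be >= 0")
  if (calibration_subset <= 0 || calibration_subset > 1) {
    stop("calibration_subset must lie in (0, 1]")
  }
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (is.null(expected_ears)) {
    expected_ears <- if (!is.null(phantom)) phantom$n_ears else 1L
  }
  if (expected_ears < 1) stop("expected_ears must be >= 1")
  structure(list(out_dir = out_dir, input = input, phantom = phantom,
                 expected_ears = as.integer(expected_ears),
                 sieve_cutoff_mm = sieve_cutoff_mm,
                 segmentation = segmentation,
                 calibration_file = calibration_file,
                 calibration_subset = calibration_subset,
                 actual_file = actual_file,
                 n_bins = as.integer(n_bins),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Nested `phantom:` and `segmentation:` maps are validated through
#' [phantom_spec()] and [segment_params()]; unknown keys anywhere raise an
#' error.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$phantom)) raw$phantom <- do.call(phantom_spec, raw$phantom)
  if (!is.null(raw$segmentation)) {
    raw$segmentation <- do.call(segment_params, raw$segmentation)
  }
  do.call(pipeline_config, raw)
}

#' Pooled seed-count recovery accuracy
#'
#' Fraction of true seeds correctly recovered across a set of ears:
#' `1 - sum(|recovered - true|) / sum(true)`, clipped at 0. Both missed and
#' spuriously split seeds count against the accuracy.
#'
#' @param recovered_counts integer vector of recovered seed counts per ear.
#' @param true_counts matching ground-truth counts.
#' @return Accuracy in `[0, 1]`.
#' @export
segmentation_count_accuracy <- function(recovered_counts, true_counts) {
  stopifnot(length(recovered_counts) == length(true_counts),
            all(true_counts > 0))
  max(0, 1 - sum(abs(recovered_counts - true_counts)) / sum(true_counts))
}

#' Run the full grain-set phenotyping pipeline
#'
#' Executes phantom generation (or volume loading), ear separation, seed
#' segmentation, trait extraction, the virtual sieve, weight calibration on
#' a subset of ears, ear profiles and the virtual-vs-actual evaluation, and
#' writes all artifacts plus a run manifest (configuration, seed, per-stage
#' timings, warnings) to `config$out_dir`. Any stage error halts the run
#' with the stage name; the manifest is then marked incomplete.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `traits`, `ears` (records),
#'   `calibration`, `profile`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("earct")),
                   rng_seed = config$rng_seed,
                   sieve_cutoff_mm = config$sieve_cutoff_mm,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   complete = FALSE, stages = list(), warnings = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        write_manifest()
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  truth <- NULL
  volume <- stage("input", {
    if (is.null(config$input)) {
      ph <- generate_ear_volume(config$phantom)
      truth <- ph$truth  # stage exprs evaluate in this frame
      ph$volume
    } else {
      read_volume(config$input)
    }
  })

  ears_v <- stage("separate_ears",
                  separate_ears(volume, config$expected_ears))

  seg <- stage("segment_seeds", lapply(ears_v, function(e) {
    segment_seeds(e, config$segmentation)
  }))

  traits <- stage("traits", {
    tabs <- lapply(seq_along(seg), function(i) {
      tt <- compute_all_traits(seg[[i]], identity_calibration(),
                               ear_id = i,
                               sieve_cutoff_mm = config$sieve_cutoff_mm)
      order_and_normalize(tt, list(origin = ears_v[[i]]$axis_origin,
                                   direction = ears_v[[i]]$axis_direction))
    })
    do.call(rbind, tabs)
  })

  actual <- stage("actual", {
    if (!is.null(config$actual_file)) {
      read.csv(config$actual_file)
    } else if (!is.null(truth)) {
      data.frame(ear_id = truth$ears$ear,
                 actual_weight_g = truth$ears$total_true_weight_g,
                 actual_count = truth$ears$n_sieved_true)
    } else {
      NULL
    }
  })

  calibration <- stage("calibration", {
    if (!is.null(config$calibration_file)) {
      raw <- jsonlite::read_json(config$calibration_file,
                                 simplifyVector = TRUE)
      structure(list(factor_k = raw$factor_k,
                     n_fit = raw$n_fit %||% NA_integer_,
                     residual_rms = raw$residual_rms %||% NA_real_),
                class = "calibration_model")
    } else if (!is.null(actual) && length(unique(traits$ear_id)) >= 2) {
      virt <- vapply(split(traits, traits$ear_id),
                     function(tt) sum(tt$virtual_weight_g), 0)
      ids <- as.numeric(names(virt))
      m <- match(ids, actual$ear_id)
      ok <- !is.na(m) & virt > 0
      n_fit <- max(2L, ceiling(config$calibration_subset * sum(ok)))
      pick <- which(ok)[unique(round(seq(1, sum(ok),
                                         length.out = min(n_fit, sum(ok)))))]
      fit_calibration(virt[pick], actual$actual_weight_g[m[pick]])
    } else {
      warning("no reference weights available; virtual weights are uncalibrated")
      identity_calibration()
    }
  })
  traits$virtual_weight_g <- traits$virtual_weight_g * calibration$factor_k

  records <- stage("ear_records", {
    lapply(split(traits, traits$ear_id), ear_record)
  })

  profile <- stage("profile", {
    if (nrow(traits) > 0) {
      weight_position_profile(records, config$n_bins)
    } else NULL
  })

  evaluation <- stage("evaluate", {
    if (!is.null(actual) && length(records) >= 2) {
      evaluate_against_actual(records, actual)
    } else NULL
  })

  stage("write_outputs", {
    write.csv(traits, file.path(config$out_dir, "traits.csv"),
              row.names = FALSE)
    ears_df <- do.call(rbind, lapply(records, function(e) {
      data.frame(ear_id = e$ear_id, n_seeds = e$n_seeds,
                 n_seeds_sieved = e$n_seeds_sieved,
                 n_seeds_small = e$n_seeds_small,
                 total_virtual_weight_g = e$total_virtual_weight_g,
                 total_weight_sieved_g = e$total_weight_sieved_g,
                 ear_length_seed_span_mm = e$ear_length_seed_span_mm)
    }))
    write.csv(ears_df, file.path(config$out_dir, "ears.csv"),
              row.names = FALSE)
    if (!is.null(profile)) {
      write.csv(profile, file.path(config$out_dir, "profile.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(unclass(calibration),
                         file.path(config$out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(evaluation)) {
      jsonlite::write_json(list(r2_weight = evaluation$r2_weight,
                                r2_count = evaluation$r2_count,
                                pairs = evaluation$pairs),
                           file.path(config$out_dir, "evaluation.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(truth)) {
      write.csv(truth$seeds, file.path(config$out_dir, "truth_seeds.csv"),
                row.names = FALSE)
      rec_counts <- vapply(records, function(e) e$n_seeds, 0)
      manifest$recovery <- list(
        n_ears = length(records),
        n_true_seeds = nrow(truth$seeds),
        n_recovered_seeds = sum(rec_counts),
        count_accuracy = segmentation_count_accuracy(
          rec_counts, truth$ears$n_seeds))
    }
    NULL
  })

  manifest$complete <- TRUE
  write_manifest()
  invisible(list(traits = traits, ears = records, calibration = calibration,
                 profile = profile, evaluation = evaluation,
                 manifest = manifest))
}
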