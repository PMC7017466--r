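# earct — grain-set phenotyping of cereal ears from X-ray CT

Grain yield components of wheat — seed number, seed weight, and their
arrangement along the ear — are usually measured destructively by hand
threshing, which loses the per-seed detail (position along the spike,
shape, internal cavities) that matters when comparing accessions under
drought and heat stress. X-ray computed tomography lets all of this be
read non-destructively from a single scan. `earct` implements the full
analysis chain for people who work with such scans or want to validate
algorithms for them:

* **Reconstruction (simplified).** Parallel-beam forward projection
  (Beer–Lambert) and filtered back projection with a Hann-windowed ramp
  filter. Each projection is normalized by the automatically detected
  unattenuated intensity I₀, so reconstructed grey values are a stable
  linear measure of physical absorption; the grey→absorption scale travels
  with every volume in a JSON sidecar and is never guessed.
* **Segmentation.** Separation of the ears scanned together, grain/chaff
  separation by a two-stage Otsu threshold on absorption plus
  morphological opening, 26-connected labeling, and splitting of touching
  seeds with a distance-transform marker watershed (shallow-saddle basins
  are re-merged so elongated single seeds are not cut apart).
* **Per-grain digital traits.** Voxel count, volume in mm³, virtual
  weight, absorption-weighted centre of mass, mean attenuation, surface
  voxels (voxels face-connected to the background), surface/volume ratio,
  minimal Feret diameter, and the 3D spherical aspect ratio
  r_eq / r_mcs — the radius of the equal-volume sphere over the radius of
  the exact minimum covering sphere (Welzl's algorithm): 1 for a sphere,
  → 0 for a thin rod.
* **Virtual sieve and weight calibration.** Seeds with a diameter below
  2.0 mm in every direction are omitted virtually, mimicking the threshing
  sieve. The virtual weight is k · volume · mean absorption, with the
  single correction factor k fitted as a least-squares slope through the
  origin on a small (~10 %) subset of ears with hand-threshed reference
  weights.
* **Ear profiles and evaluation.** Seeds are ordered along the ear axis
  (position 0 = bottom seed, 1 = top seed), pooled into position bins for
  seed-weight profiles, and per-ear virtual totals are compared with
  actual measurements by r².
* **Synthetic phantoms.** A generator that rasterizes whole virtual ears —
  rachis, superellipsoid seeds in staggered rows, thin awns, crease
  cavities and germ notches, shrivelled small seeds, detector noise — with
  exact per-seed ground truth, so every stage above is testable without
  scanner data.

3D voxel primitives (connected components, Euclidean distance transform,
marker watershed, smallest enclosing sphere, projection/backprojection)
are implemented in C++ via Rcpp.

## Worked example

Generate a 30-seed ear phantom, segment it, calibrate the virtual weight
on the three bottom seeds, and extract the trait table:

```r
library(earct)
spec    <- phantom_spec(n_ears = 1, seeds_per_ear = 30, rng_seed = 11)
phantom <- generate_ear_volume(spec)
#> <ear_phantom> 1 ear(s), 30 seeds, volume 101 x 101 x 650

ear   <- separate_ears(phantom$volume, expected_ears = 1)[[1]]
seeds <- segment_seeds(ear)
length(seeds)
#> [1] 30

calib <- fit_calibration(virtual = ..., actual = ...)  # 3 reference seeds
calib
#> <calibration_model> k = 0.0017156 (n = 3, residual RMS = 0.000173)

traits <- order_and_normalize(
  compute_all_traits(seeds, calib, ear_id = 1),
  list(origin = ear$axis_origin, direction = ear$axis_direction))
head(traits[, c("volume_mm3", "virtual_weight_g", "mean_attenuation",
                "aspect_ratio", "min_diameter_mm", "passes_sieve")], 5)
#>   volume_mm3 virtual_weight_g mean_attenuation aspect_ratio min_diameter_mm passes_sieve
#> 1     18.362           0.0252           0.7999       0.5409             2.2         TRUE
#> 2     18.596           0.0255           0.7989       0.5746             2.3         TRUE
#> 3      5.191           0.0071           0.8001       0.5483             1.3        FALSE
#> 4      7.629           0.0105           0.7997       0.5534             1.7        FALSE
#> 5      5.998           0.0082           0.7993       0.5351             1.4        FALSE

ear_record(traits)
#> <ear_record> ear 1: 30 seeds (22 sieved, 8 small), 0.7025 g virtual
```

Reading the output: the two plump seeds (≈ 18 mm³, aspect ratio ≈ 0.55,
width > 2 mm) pass the virtual sieve; the shrivelled ones (≈ 5–8 mm³,
width < 2 mm) would fall through a real 2 mm sieve and are counted
separately. The calibrated virtual ear weight, 0.7025 g, recovers the
phantom's ground-truth seed weight of 0.6996 g to within half a percent.
The mean attenuation of ≈ 0.80 is the phantom's grain absorption,
demonstrating that grey values stay physically interpretable through the
pipeline.

`run_pipeline(pipeline_config(...))` chains all stages (including
multi-ear volumes, the sieve, calibration, profiles, evaluation and a run
manifest); `inst/cli/earct.R` wraps it for shell use.

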