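---
title: "Methods: CT grain-set phenotyping with earct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT grain-set phenotyping with earct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`earct` measures grain yield components of cereal ears from X-ray CT
volumes: how many seeds an ear set, how much each weighs, how they are
shaped, and where they sit along the spike. This vignette explains the
models and algorithms behind each stage, the parameters that matter, and
the choices made where the design was genuinely open. It states no
empirical results; the numbers the package produces come from its test
suite and from `scripts/acceptance.R`.

## The absorption model and reconstruction

All downstream quantities rest on one physical contract: voxel grey
values are a **linear measure of X-ray absorption**. A `ct_volume` is a
16-bit grey array plus `voxel_size_um` and `grey_per_absorption`;
`absorption = grey / grey_per_absorption`. A volume without its scale is
rejected outright — raw grey values are meaningless for weighing seeds.

The reconstruction stage is a deliberately simplified, desk-verifiable
CT model:

* **Geometry.** Parallel-beam, slice-stacked: each horizontal slice is
  projected and reconstructed independently. Real scanners use helical
  cone-beam trajectories; everything downstream of reconstruction only
  needs a normalized absorption volume, so the simpler geometry (which
  has closed-form test phantoms) stands in. Helical weighting is a
  non-goal.
* **Forward model.** Beer–Lambert: a detector bin records
  `I0 * exp(-∫ mu ds)`, sampled by bilinear interpolation at half-voxel
  steps along each ray.
* **I₀ normalization.** Each projection's unattenuated intensity is
  estimated as the median of the top decile of border-column pixels
  (robust to noise; the borders see air when the specimen does not fill
  the detector). If that estimate falls below 80 % of the projection
  maximum the borders are evidently shadowed; the global maximum is used
  instead, with a warning. Because every projection is normalized by its
  own I₀, reconstructions are invariant to primary-beam drift — the
  property that makes mean attenuation usable as a density proxy.
* **Filter.** Ramp filter with a Hann window, cutoff at Nyquist, applied
  by FFT on a zero-padded detector axis. The window trades a little
  resolution for noise robustness; the filter choice is otherwise
  standard.
* **Angular bookkeeping.** Coverage below 180° is an error. For k
  half-turns of coverage the backprojection sum is divided by k
  (projections are π-periodic in parallel geometry).
* **Grey mapping.** One global linear scale per volume maps the maximum
  reconstructed absorption to grey 60 000, leaving 16-bit headroom for
  noise; the scale is written to the sidecar.

The reconstruction is monochromatic. Real spectra are polychromatic, so
a scanner's "absorption" is an effective value for its spectrum; the
package reports its own consistent unit and claims no conversion to
g/cm³.

## What the phantom generator emulates

`phantom_spec()` / `generate_ear_volume()` rasterize whole virtual ears
with exact per-seed ground truth. The geometry emulates the features a
normalized reconstruction of a real ear shows:

* a vertical **rachis** cylinder (default radius 0.75 mm) at chaff
  absorption 0.3 — grain, at 0.8, is markedly denser, which is the
  physical handle the segmentation uses;
* **seeds** as superellipsoids (exponent 2 = ellipsoid by default) with
  the long semiaxis vertical, arranged in `n_rows = 4` staggered rows
  around the rachis. Default semiaxis ranges (a 1.05–1.35, b 1.25–1.55,
  c 2.90–3.60 mm) give plump grains of roughly 19–28 mm³, the size class
  of a healthy wheat grain; a `small_seed_fraction` (default 0.15) is
  scaled by 0.65, producing shrivelled seeds of roughly 5–8 mm³ whose
  minimal width falls below the 2 mm sieve — the class that appears
  under combined drought and heat;
* **crease cavities** carved as a half-cylindrical channel along the
  long axis on the radial side (radius `crease_depth_frac * a`) plus a
  spherical **germ notch** at the lower pole, reproducing the hollow
  seed morphology of stressed grain with two parameters;
* thin **awns** (radius 0.15 mm rods) rising from a fraction of seed
  tips, and additive Gaussian **detector noise** (default sd 3000 grey ≈
  5 % of the seed grey level);
* deliberately **touching seed pairs** (`touch_fraction`), placed in the
  same row with a 0.25 mm overlap so their masks fuse into one
  component; the truth table marks the pairs so splitting can be scored
  separately.

Ground truth records, per seed, the centre, semiaxes, rasterized volume
(the voxel count of the generation mask — exact for the digitized
object), the closed-form uncarved volume for convergence checks, mean
attenuation, crease/touch flags and axial position; per ear, totals
including a true weight `volume × attenuation × density_factor`. The
default `density_factor` 0.0017 g/(mm³·absorption) makes a 23 mm³ grain
at absorption 0.8 weigh ≈ 0.031 g, matching the order of real single
grain weights.

What the phantoms do **not** emulate: partial-volume blur at seed
boundaries (rasterization is binary), scatter, beam hardening, glume
wraps in contact with grain, or biological variation beyond uniform
semiaxis ranges. Passing the recovery tests therefore shows the pipeline
is correct on sharp-boundary, two-class-contrast data; on real scans the
thresholds see blurred edges and the voxel-count accuracy will be
bounded by partial-volume effects (visible in the package's own
projection→reconstruction→segmentation round trip, where reconstructed
seed masks shrink slightly while mean attenuation stays within a few
percent).

Packing is guarded: rows are vertically staggered and seeds keep a
radial clearance from the rachis; any residual overlap between
non-paired seeds, or an ear exceeding `max_ear_length_mm`, is an error
naming the first non-placeable seed. Seeds narrower than 4 voxels across
a semiaxis are rejected as unresolvable. The default voxel size is
100 µm — coarser than a real scanner's ~31 µm sampling — to keep desk
phantoms around 100 × 100 × 1000 voxels; it is a plain parameter.

## Segmentation

`separate_ears()` works on an 8×-coarsened grid (stride 4 of a coarse
max, i.e. ~0.4 mm cells at the default voxel size): Otsu foreground,
then a ~2 mm dilation so the parts of one ear — rachis, seed crowns,
awns — merge into a single blob while ears, several millimetres apart,
stay distinct. Blob components are counted against `expected_ears`
(mismatch is an error reporting the found count), ordered left to right,
cropped at full resolution, and given a principal-axis estimate of the
rachis line with the sign convention that the vertical component is
positive. The dilation step exists because an ear's parts need not be
voxel-connected (grain does not touch the low-density rachis after
thresholding).

`segment_seeds()` separates grain from everything else:

1. **Air/material threshold:** Otsu on the absorption histogram.
2. **Grain/chaff threshold:** a second Otsu on the material voxels,
   accepted only when the material histogram is genuinely bimodal
   (class-mean separation exceeding twice the summed class standard
   deviations); otherwise the first threshold stands. A floor
   `min_grain_absorption` (default 0.4, in normalized absorption units)
   keeps a fully aborted ear — rachis and awns only — from being
   mistaken for grain; such an ear returns zero regions with a warning,
   which is a valid outcome.
3. **Opening** by a ball of radius 0.3 mm (two distance transforms)
   removes awns, glume remnants and threshold noise.
4. **Labeling** with 26-connectivity; components under
   `min_region_voxels = 27` are dropped as debris.
5. **Splitting:** per component, the Euclidean distance transform is
   computed and its local maxima (box-filter plateau maxima at least
   `marker_min_distance_mm = 1.5` apart and at least
   `marker_min_radius_mm = 0.45` deep) seed a priority-flood marker
   watershed on the negated distance map. Basins are then re-merged
   when the saddle between them is shallow — above `saddle_ratio = 0.7`
   of the lower basin peak. This last step is essential: an elongated
   seed's distance ridge is flat to within discretization and yields
   tied plateau maxima far apart, which are not fusion necks. A genuine
   pair of touching seeds meets at a narrow neck whose saddle is well
   below the basin peaks, so the relative criterion is scale-invariant
   across plump and shrivelled seeds. Regions produced by splitting are
   flagged `touches_another`.

Connectivity conventions are fixed once: 26-connectivity for region
labeling and flooding, 6-connectivity (faces) for the surface operator.
Voxel indices are 1-based with axis order (x, y, z), z vertical, and
world position `(index − 0.5) × voxel size` — the R-native counterpart
of a 0-based convention, chosen so array indexing in R code reads
naturally.

## Traits

* **Volume** is `voxel_count × voxel³` exactly.
* **Mass index** is `volume × mean absorption` (algebraically the
  per-voxel absorption sum times the voxel volume), the quantity the
  calibration factor multiplies; the centre of mass is the
  absorption-weighted mean voxel position from the same pass.
* **Minimum covering sphere**: exact (Welzl's move-to-front algorithm,
  recursion bounded by the 4-point support, deterministic internal
  shuffle), computed on the region's surface voxels only — boundary
  voxels are a superset of the convex-hull vertices, so the result is
  identical and the input is an order of magnitude smaller. The test
  suite keeps an exhaustive support-subset oracle at tolerance 1e-9.
* **Aspect ratio** = r_eq / r_mcs, clipped to ≤ 1; a single-voxel
  region is defined as 1 (its covering radius at the centre-point
  representation is 0). The 27-voxel segmentation floor means the
  pipeline itself never meets that case.
* **Surface** counts region voxels with at least one face neighbour in
  the background (the volume border counts as background). It counts
  voxels, not exposed faces.
* **Minimal diameter** (the sieve criterion) is the smallest projected
  extent over directions: a deterministic 128-direction Fibonacci
  sphere scan followed by a Nelder–Mead refinement of the best
  direction, because a coarse scan alone overestimates the width of
  strongly anisotropic seeds. Per direction the width of the digitized
  solid is taken as the voxel-centre extent plus
  `vox · (1 + |dx|+|dy|+|dz|) / 2` — the mean of the inner (centres)
  and outer (cube corners) hull supports. This convention is exact
  along lattice axes and stays within about a quarter voxel of the
  smooth-solid width in oblique directions, instead of chasing
  staircase crevices of the voxelization (which run up to a full voxel
  below the smooth width). Widths at this accuracy make the 2.0 mm
  sieve flag reliable for seeds whose true width is not within half a
  voxel of the cutoff.
* **Calibration** is a single global slope through the origin,
  `k = Σ(virtual·actual) / Σ(virtual²)` — one scalar correction factor,
  not an affine fit, fitted by default on ~10 % of ears and applied to
  all. The estimator is unbiased under multiplicative noise.

## Ear profiles and evaluation

Seeds are ordered by the scalar projection of their centre of mass onto
the ear axis; normalized position is 0 at the first (bottom) seed and 1
at the last (top) seed, with a single seed at 0 by convention. Weight
profiles pool seeds of all ears — including sub-sieve seeds — into
`n_bins = 20` equal bins of normalized position (the profile resolution
is a free choice; 20 gives ~2–3 seeds per bin per ear population at
typical grain counts); empty bins are `NA`, never zero, and binned
means times counts reconstruct the pooled total exactly. Evaluation
against hand-threshed reference tables reports r² as the squared
Pearson correlation for per-ear weight and sieved seed count; a
constant reference vector yields `NA` with a message rather than a
spurious value. Group summaries average per ear first and only then per
group — seed-level pooling across ears would weight big ears more.

## The benchmark experiment

`grain_recovery_experiment()` is the package's accuracy benchmark and
what `scripts/acceptance.R` runs: 50 single-ear phantoms with 20–60
seeds each at the generator defaults above, with 10 % of the ears
carrying deliberately touching pairs (a tenth of their seeds). The
ear-level (rather than seed-level) reading of "10 % touching pairs" is
a design choice: it exercises the splitter while leaving a touch-free
subset on which sieved-count fidelity can be scored separately.
Recovery is scored as pooled count accuracy
`1 − Σ|recovered − true| / Σ true` — both missed and spuriously split
seeds count against it — plus r² of calibrated virtual weight and of
sieved counts against truth. Per-ear generator seeds are drawn from one
master seed, so the whole experiment is reproducible from a single
integer.

## Numerical choices and degenerate inputs

* Distance transforms are exact squared Euclidean (separable
  lower-envelope algorithm) with anisotropic spacing support; masks are
  padded so the array border is background where that is the correct
  physical reading (opening, per-component splitting, surfaces).
* The watershed priority queue breaks elevation ties FIFO, making
  splits deterministic.
* `orient_seed()` demands ≥ 4 non-coplanar voxels and errors on
  coplanar input; eigenvalues are returned descending with each
  eigenvector's largest-magnitude component positive. When eigenvalues
  tie (perfect cube or sphere) the eigenbasis is arbitrary — documented
  rather than resolved, since any frame is equally valid.
* Phantom generation, the pipeline and the benchmark restore the
  caller's RNG state; all randomness flows from explicit seeds.
* TIFF I/O is uncompressed 16-bit multi-page; write∘read is
  bit-identical on grey values and metadata.

## Known limitations

* The reconstruction is parallel-beam and monochromatic; no scatter,
  beam hardening, or detector defect models.
* Segmentation assumes the two-class density contrast (grain > chaff)
  that wheat ears provide; crops without it would need the explicit
  `grain_threshold`.
* Phantom seeds are binary-rasterized, so threshold placement between
  air and grain levels barely affects recovered volumes; on real,
  blurred data volume accuracy degrades with edge width.
* The virtual weight is linear in absorption; moisture or compositional
  effects on attenuation are not modelled.
* Traits are computed per seed independently; rachis architecture
  beyond the axis line is out of scope.
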