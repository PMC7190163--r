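---
title: "Methods: cell type-specific smFISH transcript quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-specific smFISH transcript quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcount)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic experiments used in the test suite do and do not
demonstrate about real microscopy data.

## The measurement model

A single-molecule FISH experiment images one field of view as one 3D stack
per channel. A transcript channel contains diffraction-limited spots: each
RNA molecule (or nascent transcription site, when intronic probes are used)
appears as the microscope's point-spread function (PSF), well approximated
by an anisotropic 3D Gaussian a few voxels wide. At typical confocal
sampling (0.285 µm pixels, 0.4 µm z-steps) the in-plane PSF sigma is about
1.5 voxels and the axial sigma about 1 voxel. The nuclei channel (DAPI) is
a dense stain; marker channels (immunofluorescence) are bright over cells
of one type. The quantity of interest is the number of transcript spots per
nucleus (nascent mode) or per cell (mature mode), broken down by cell type.

All coordinates in the package are 1-based `(z, y, x)` voxel indices with
integer values at voxel centres, the native convention of R's array
ecosystem. Voxel sizes are carried as metadata only; every distance
parameter is expressed in voxels so that the same settings behave
identically regardless of calibration metadata.

### Intensity normalization

Raw stacks are min–max normalized per channel to $[0, 1]$:
$x \mapsto (x - \min) / (\max - \min)$. The published working ranges for
the two scale-dependent thresholds — detection gates around 0.06–0.24 and
basin depths around $10^{-7}$–$5\times10^{-5}$ — are only meaningful on a
fixed intensity scale, and min–max to the unit interval is the simplest
rescaling that provides one. It is a visible, documented choice rather than
an implicit preprocessing step: percentile-based variants would change what
those magnitudes mean. A constant channel maps to all zeros, and
normalization is idempotent (the test suite checks this numerically).

## Filtering

Each transcript channel is band-passed: a Gaussian **high pass**
(`sigma_high`, default 10 voxels) subtracts a heavily blurred copy of the
volume and clips negatives at zero, removing background that varies at cell
scale; a Gaussian **low pass** (`sigma_low`, default 1 voxel) then smooths
at spot scale. The defaults follow from the optics: spot FWHM is 2–3
pixels, background varies over tens of pixels, so any `sigma_high` well
above the spot scale and `sigma_low` at or below it behaves equivalently.
The order (high pass, then low pass) is fixed; both filters are separable
1D convolutions with reflect boundary handling, implemented as exact dense
banded-matrix products per axis (the test suite pins them against a
brute-force dense 3D convolution and against the analytic kernel).
Negatives are clipped after the high pass so that downstream integrated
intensities are non-negative; for voxels away from the border this makes
the filter exactly invariant to additive offsets.

Filtering uses an isotropic sigma in voxel units by default even though the
voxel is anisotropic in micrometres; a per-axis override
(`per_axis_sigma`) is available. This keeps the spot-scale smoothing
matched to the PSF's voxel-space footprint, which is closer to isotropic
than the physical-space one.

## Spot detection

Detection runs on the filtered volume:

1. **Candidates** are 26-neighbourhood local maxima above the
   `percentile_floor` intensity quantile (default 0.99).
2. **Subpixel refinement** fits a 3D Gaussian
   $A\,e^{-\frac{1}{2}\left(\frac{(z-z_0)^2}{\sigma_z^2}+\frac{(y-y_0)^2}{\sigma_y^2}+\frac{(x-x_0)^2}{\sigma_x^2}\right)}+b$
   to the $(2r+1)^3$ window around each candidate
   (Levenberg–Marquardt, 100 iterations). If the fit fails to converge or
   any fitted sigma falls outside $[0.5, 2r]$ voxels — physically
   implausible for a diffraction-limited spot — the centre falls back to
   the intensity-weighted centroid and the row is flagged in the
   `fallback` column. On a single-slice volume the fit is 2D.
3. **Mass** is the sum of filtered intensities over the window. Integrated
   intensity is preferred over the peak because it is robust to where the
   sampling grid lands relative to the true centre.
4. The **`min_mass` gate** discards spots below threshold. Because the
   gate acts on a fixed candidate set ordered by mass, the retained set at
   any threshold is exactly the zero-threshold set filtered by mass:
   counts are non-increasing in `min_mass` and every thresholded result is
   a subset of the permissive one (both properties are tested).
5. **Separation** enforcement greedily keeps the higher-mass spot whenever
   two centres are closer than `separation` voxels, with deterministic
   ties (mass, then $z, y, x$).

Choosing `min_mass` is the step that most affects the biology, so
`categorize_spots()` plus `render_detection_overlay()` implement the
interval QC view: spots are binned below/within/above a user-chosen bound
pair and drawn in red/yellow/green over the filtered projection. Inspecting
bounds near the working gate (the default report bounds are
$0.8\times$–$1.2\times$ `min_mass`) shows directly whether borderline
detections look like transcripts. Whether a published bound refers to peak
or integrated intensity is ambiguous in general; here both the gate and the
report bounds act on the same quantity, the window mass, so the comparison
is internally consistent.

## Nuclei segmentation

Segmentation is 2D: the normalized nuclei channel is max-projected, not
sliced, because nuclei overlap little in well-plated preparations and a 3D
treatment would require resolving overlaps along z that this pipeline
explicitly does not attempt (a known limitation; see below).

The stages of `segment_nuclei()`:

1. **Smooth** the projection (Gaussian, `smoothing_sigma`, default 2 px).
   This smoothed image is *the* watershed surface: `min_depth` values are
   defined on its intensity scale.
2. **Threshold** foreground by Otsu's method (default) or a fixed value.
3. **Watershed** the surface restricted to foreground. The package uses
   its own deterministic descending priority flood (in C++): basins grow
   from every regional maximum, pixels attach to the basin of their
   steepest strictly-higher neighbour, plateaus flood breadth-first, ties
   go to the smaller label, and every foreground pixel receives exactly
   one label. Determinism at double precision matters here because the
   depths being resolved are as small as $10^{-6}$; the implementation is
   cross-checked against an independent watershed on basin counts.
4. **Merge shallow basins** (`merge_shallow_basins()`): on the basin
   adjacency graph, the depth of an adjacent pair is
   $\min(\mathrm{peak}_A, \mathrm{peak}_B) - \mathrm{saddle}(A,B)$, the
   saddle being the highest contact level along the shared boundary. The
   pair with the smallest depth is merged and affected edges recomputed,
   repeatedly, while that depth is below `min_depth`. This depth is the
   classical *dynamics* criterion, so the procedure is equivalent to
   running the watershed on the h-maxima-suppressed surface — an
   equivalence the test suite verifies exactly, partition against
   partition, on randomized surfaces whose saddle depths are calibrated to
   span the tested thresholds (see the h-maxima note below).
5. **Remove small regions** (`min_size`, pixels): pyknotic nuclei and
   debris are smaller than live nuclei, so an area floor removes them
   automatically.
6. **Compact labels** to consecutive IDs and compute region properties.

`min_depth` is the over/under-segmentation control. Around
$10^{-6}$–$10^{-7}$ on the normalized scale it suppresses spurious splits
from minor intensity texture; raised deliberately to the
$5\times10^{-6}$–$5\times10^{-5}$ range it splits touching mammalian nuclei,
whose shared border produces a shallow saddle — the resulting
over-segmentation is then cheap to fix by ID-based merging, whereas
under-segmentation cannot be fixed downstream at all.

**h-maxima equivalence and its limits.** Union-merging basins on the graph
and re-flooding the suppressed surface agree exactly when a suppressed
basin borders one surviving neighbour — the generic touching-nuclei
situation, and the configuration the equivalence test generates. When a
suppressed basin borders several survivors, discrete re-flooding may split
single boundary pixels of that basin between survivors while graph merging
keeps the basin whole; the package follows the merging semantics
("sequential combination" of regions) because corrections and audits then
operate on whole regions. Region counts agree between the two routes in
either case.

**Corrections.** `correct_segmentation()` takes declarative edits — merge
sets and deletion lists of region IDs — validates them (unknown IDs are
reported with the valid set; an ID cannot be merged and deleted at once),
applies them (lowest ID wins a merge), and records the audit in the run
metadata. Batch-friendly declarative edits were chosen over interactive
editing so that a corrected analysis remains reproducible from its
metadata file alone.

## Cell-type assignment and counting

Marker channels are max-projected, smoothed, and thresholded
(`marker_threshold`, per channel); components smaller than
`min_region_size` are discarded. For each nucleus and marker the **overlap
fraction** is $|\mathrm{nucleus} \cap \mathrm{mask}| / |\mathrm{nucleus}|$,
and the nucleus is called positive at `min_overlap_fraction` (default 0.5
— majority overlap, the least surprising decision rule given that only a
brightness threshold is specified by the underlying approach). Nuclei
positive for multiple markers are reported with a `multi` flag rather than
resolved: marker panels are usually designed to be mutually exclusive, and
inventing a tie-break would hide a staining or thresholding problem.
Marker-negative nuclei are retained as `"unassigned"`.

Counting looks up each spot's rounded $(y, x)$ in the label map — z is
collapsed because segmentation is 2D — and reports per-region counts plus
a background count, never dropping spots: the identity
$\sum_k \mathrm{count}_k + \mathrm{background} = \mathrm{total}$ holds
exactly and is asserted in the tests.

In **nascent** mode the label map is the nuclei themselves (nascent
transcripts are nuclear). In **mature** mode each nucleus is first grown
into a cell territory: a multi-source breadth-first propagation inside the
marker mask assigns every reachable mask pixel to its geodesically nearest
nucleus (4-connected, ties to the smaller ID — verified against a
brute-force geodesic-distance oracle). Mask pixels unreachable from any
nucleus stay unowned; a nucleus outside every mask component keeps its own
pixels as its territory, so it still receives its nuclear spots rather
than vanishing from the output. Whether cytoplasm segmentation should
derive from the marker morphology itself or from nucleus-seeded growth is
genuinely underdetermined in the method this package implements;
nucleus-seeded territories were chosen because they need no additional
parameters and degrade gracefully to nascent-mode behaviour when markers
are absent.

## Reporting and reproducibility

Each run writes per-sample CSVs (spots, regions, assignments), a 16-bit
label-map TIFF, one QC PNG per stage (filtering, detection, segmentation,
assignment, quantification) plus a pseudocolour composite with per-nucleus
counts, and a YAML metadata file containing every parameter of every
module, the correction audit, package version and seed. Batch results
accumulate in a single CSV across samples; appending validates the schema,
refuses duplicate `(sample_id, nucleus_id)` keys, and never rewrites
existing rows. The CSV is the canonical interchange format and loads
directly into spreadsheet tools.

QC images are composed as raw RGB rasters (rings, boundaries, and a small
bitmap digit font) and written with `png::writePNG`, deliberately avoiding
any graphics device: identical inputs produce byte-identical files, which
makes image-level regression testing and the metadata re-run guarantee
possible. `run_from_metadata()` re-executes a pipeline from a saved
metadata file — optionally overriding individual dotted-path parameters —
and reproduces the original tables bit-for-bit on the same input, which
the acceptance checks assert literally on file bytes.

Stage artifacts (filtering, detection, segmentation, marker masks) are
cached on disk keyed by their exact upstream parameters, so changing a
downstream parameter re-runs only downstream stages — the modularity that
makes iterative threshold tuning affordable.

## The synthetic experiment generator

`simulate_experiment()` renders the study conditions the test suite runs
under, with complete ground truth. The default field of view is a
16×176×176 stack: six isolated nuclei of half-maximum radius 13–15 px
(≈ 3.7–4.3 µm at 0.285 µm/px), two cell types at a 3/3 split with marker
channels covering their nuclei, and one transcript channel with
Poisson-distributed spot counts per nucleus (means 8 vs 2 — strong
cell type-specific expression), spot peak 0.5 over a 0.05 background
gradient with Gaussian noise 0.01 (the detection-only fixture uses noise
0.02, i.e. peak SNR 25).

Choices a reader should know about:

- **Nucleus profile.** Isolated nuclei are super-Gaussian blobs
  $e^{-\ln 2\,(d^2/r^2)^2}$: half-maximum exactly at $r$, but only
  $1.5\times10^{-5}$ of the peak at $2r$. A plain Gaussian of the same
  half-maximum radius has such heavy tails that a neighbour 40 px away
  would tilt a $10^{-5}$ saddle by orders of magnitude more than the
  saddle itself.
- **Touching pairs.** Pair members are rendered as plain Gaussians
  ($\sigma = r/2$) because log-concavity guarantees a single well-defined
  saddle between the two peaks (the flat-topped super-Gaussian sum can be
  trimodal near critical separation). The centre separation is calibrated
  by root-finding on the *discrete rendered grid*, against the same
  smoothed, normalized surface the segmentation floods, so the achieved
  saddle depth matches the requested one essentially exactly (the tests
  require 10%; the calibration residual is ~$10^{-11}$ relative). Pair
  placement guarantees that render windows of different objects never
  overlap, so the calibration is exact in the full image, and all pairs
  share one integer-aligned geometry so one calibration serves all.
- **Noise on the nuclei channel defaults to zero.** A saddle of depth
  $10^{-5}$ on the unit scale is only a testable quantity when residual
  intensity fluctuations after smoothing are well below that; with noise,
  depth thresholds this small would measure the noise, not the geometry.
  Real DAPI stacks are high-SNR but not noise-free — on real data the
  effective minimum usable `min_depth` is set by the residual noise after
  smoothing.
- **Spot placement.** Spots are placed inside nuclei (within $0.7r$, the
  nascent scenario) with a minimum pairwise separation of 3.5 units of
  the *effective* blurred spot width $\sqrt{\sigma_\mathrm{psf}^2 + 1}$
  (the detection low pass included). This keeps every rendered pair of
  spots clearly bimodal — resolvable by construction — which is the
  regime in which per-nucleus counts can meaningfully be required to be
  exact. Nascent transcription sites are few and well separated in real
  nuclei, so this is the realistic regime, but it is a real limitation of
  the fixtures: dense mature-mRNA fields with unresolvable spot pairs are
  *not* represented, and detection recall there would be bounded by
  optics, not by this implementation.
- **Basin-surface fixtures.** The watershed-oracle surfaces are 32×32
  images of isolated two-bump components whose saddle depths are drawn
  log-uniformly over $10^{-6.5}$–$10^{-3.5}$ and grid-calibrated, so the
  tested `min_depth` values ($10^{-6}, 10^{-5}, 10^{-4}$) fall inside the
  realized depth spectrum and real merges occur in most comparisons.

Analysis parameters used with the fixtures are derived from the
generator's own settings, fixed by formula rather than tuned: the
fixture-run `min_mass` is a quarter of the nominal integrated spot
intensity, $0.25\,A\,(2\pi)^{3/2}\sigma_z\sigma_y\sigma_x \approx 4.4$ —
far above the integrated noise in a window and far below a true spot's
mass.

What passing these tests shows: the implementation recovers exactly what
it is told is there, under optics-faithful rendering, across the full
pipeline, deterministically. What it does not show: robustness to optical
aberrations, uneven illumination, autofluorescence, overlapping nuclei in
z, or spot densities beyond the resolvable regime — the generator does not
emulate those.

## Numerical choices and degenerate inputs

- Convolution boundary mode is reflect everywhere; kernels truncate at
  `truncate` (default 4) sigmas.
- The watershed flood, the basin merge order (globally smallest depth
  first, ties to smaller label pairs), the separation filter's tie-break,
  and the BFS territory tie-break are all fully specified, so every stage
  is a pure function of its inputs — re-running with identical parameters
  is bit-identical, and the merged partition does not depend on input
  label numbering.
- Degenerate inputs are contracts, not accidents: an empty or all-zero
  volume yields an empty spot table; an empty foreground yields an empty
  label map with a warning; `min_depth = 0` merges nothing and
  `min_depth = ∞` merges each connected component to one region;
  `min_size = 0` filters nothing; a z = 1 stack runs through the whole
  pipeline as a 2D analysis (checked against an independent 2D reference
  detector).
- Poisson draws and all other randomness in the generator come from one
  seed; fixtures are reproducible by construction.

## Known limitations

Segmentation is 2D: nuclei that overlap along z cannot be separated, and
their transcripts cannot be attributed correctly — such regions should be
removed during QC (deletion by ID). Mature-mode territories are a
geodesic partition of the marker mask, not a morphology segmentation; in
dense tissue with interleaved processes the territory boundary is a
proxy. The batch output is CSV (a documented, spreadsheet-importable
schema); no native spreadsheet file is written. Marker positivity is a
threshold decision — no probabilistic cell typing.

## Problem sizes in the test suite

The suite simulates its data at the sizes above (176² × 16 stacks, 32²
oracle surfaces, 256² pair images, 50 oracle surfaces × 3 depths, 40-seed
statistical checks), which keeps a full run of unit plus acceptance tests
around a minute and a half on one core while still exercising every stage
at realistic spot and nucleus scales.
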