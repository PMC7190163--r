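# fishcount

Cell type-specific quantification of single-molecule RNA FISH
(smFISH/RNAscope) transcripts from multi-channel 3D fluorescence stacks.

## The problem

An smFISH experiment images a field of view as one z-stack per channel: a
DNA stain (DAPI) marking nuclei, one or more transcript channels in which
every RNA molecule (or nascent transcription site) appears as a
diffraction-limited spot, and immunostain channels whose bright regions
identify cell types (e.g. GFP⁺ vs mCherry⁺, or GFAP⁺ radial glia vs SATB2⁺
neurons). Turning those images into *per-cell-type transcript counts*
requires four coupled analyses — spot detection, nuclei segmentation,
cell-type assignment, and counting — and each has a failure mode that
silently corrupts the biology: a wrong intensity gate miscounts
transcripts, an over- or under-segmented nucleus merges or splits cells,
and a mis-assigned nucleus attributes expression to the wrong population.

`fishcount` implements the full pipeline with the controls that make these
failure modes visible and fixable:

- **Band-pass filtering** — Gaussian high pass (background removal) then
  Gaussian low pass (spot-scale smoothing) on each transcript channel.
- **3D spot detection** — candidate local maxima refined to subpixel
  centres by least-squares 3D Gaussian fitting; each spot's **mass**
  (integrated intensity over the fit window) is gated by `min_mass`, the
  single most influential parameter. An interval QC overlay colours spots
  below/within/above a bound pair (e.g. 0.06–0.07 vs 0.23–0.24 on
  normalized data) so the gate can be chosen by inspection.
- **Watershed nuclei segmentation with minimum depth** — the 2D nuclei
  projection is flooded from its intensity maxima; adjacent basins are
  merged while their *depth* — `min(peak_A, peak_B) − saddle(A,B)` — is
  below `min_depth`. Small values (1e-6 to 1e-7) suppress
  over-segmentation; deliberately larger values (5e-6 to 5e-5) split
  touching nuclei whose shared border is shallow. A `min_size` filter
  removes debris, and ID-based corrections (`merge: [[3,4]]`,
  `delete: [2]`) fix anything that remains.
- **Cell-type assignment** — each marker channel is thresholded into a
  positive-region mask; a nucleus is marker-positive when at least
  `min_overlap_fraction` (default 0.5) of its area lies inside the mask.
  Nascent mode counts spots inside nucleus masks; mature mode first grows
  each nucleus into a cell territory within the marker mask.
- **Reporting** — per-sample CSVs, deterministic QC PNGs for every stage,
  a cumulative batch CSV across samples, and a YAML metadata file holding
  every parameter, from which a run can be re-established bit-for-bit.

A synthetic-experiment generator (`simulate_experiment()`) renders
multi-channel stacks with complete ground truth — nucleus masks, cell
types, spot positions, even touching nucleus pairs with an intensity
saddle calibrated to a requested depth — so every stage is testable
without any external data.

## Worked example

```r
library(fishcount)

sim <- simulate_experiment(fixture_params(seed = 1))
sim$experiment
#> <fish_experiment> sim_seed1: 4 channels
#>   DAPI         nuclei      16 x 176 x 176
#>   HES1         transcript  16 x 176 x 176
#>   GFP          cell_marker 16 x 176 x 176
#>   mCherry      cell_marker 16 x 176 x 176

run <- run_pipeline(
  sim$experiment,
  run_config(detect = detection_params(min_mass = 4.4))
)
glance(run)
#> # A tibble: 1 × 5
#>   sample_id n_nuclei n_spots n_background_spots n_unassigned
#>   <chr>        <int>   <int>              <int>        <int>
#> 1 sim_seed1        6      18                  0            0
tidy(run)
#> # A tibble: 6 × 4
#>   sample_id nucleus_id cell_type count_HES1
#>   <chr>          <int> <chr>          <int>
#> 1 sim_seed1          1 mCherry            2
#> 2 sim_seed1          2 GFP                5
#> 3 sim_seed1          3 mCherry            0
#> 4 sim_seed1          4 GFP                4
#> 5 sim_seed1          5 GFP                5
#> 6 sim_seed1          6 mCherry            2
```

`glance()` summarises the run: 6 nuclei, 18 detected transcripts, none in
the background, every nucleus assigned a type. `tidy()` gives the
per-nucleus table that also lands in the batch CSV — here the GFP⁺ cells
carry 4–5 HES1 transcripts and the mCherry⁺ cells 0–2, reflecting the
simulated cell type-specific expression (Poisson means 8 vs 2). Against
the generator's ground truth:

```r
score_against_truth(run, sim$truth)
#> <fish_score>
#>   spots HES1: recall 1.000, precision 1.000, rmse 0.137 vox
#>   segmentation: 6/6 regions, mean IoU 0.852
#>   assignment: 6/6 correct (100.0%)
#>   counts: MAE 0.000
```

Passing `out_dir =` to `run_config()` additionally writes the spot,
region and assignment CSVs, a 16-bit label-map TIFF, five per-stage QC
PNGs plus a pseudocolour composite with counts, and the metadata YAML;
`run_from_metadata()` re-executes a run from that file, reproducing the
tables byte-for-byte. A thin command-line wrapper is installed as
`exec/fishcount` (`fishcount run|simulate|correct`).

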