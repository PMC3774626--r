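---
title: "Quantifying smFISH images: spot calling, threshold sensitivity and allele classification"
author: "spotsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying smFISH images: spot calling, threshold sensitivity and allele classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotsense)
```

## The measurement problem

In single-molecule RNA FISH (smFISH), dozens of short fluorescently
labeled oligonucleotides hybridize along one transcript, so each RNA
molecule appears in a 3D fluorescence stack as a bright,
diffraction-limited spot. Counting those spots per cell gives absolute
transcript numbers without amplification. The practical difficulty is
not finding bright spots — it is deciding *where signal ends and
background begins*, and knowing how much that decision matters for the
reported counts. spotsense implements a complete quantification
pipeline around that question:

1. **enhance** — a spot-size-matched linear filter,
2. **regional_maxima** — candidate spots as 3D regional maxima of the
   filtered stack,
3. **threshold_curve / select_threshold** — the spot count `N(T)` as a
   function of the intensity threshold `T`, and the automatic choice of
   the plateau threshold,
4. **sensitivity** — the signal-quality score: how fast `log N(T)`
   changes at the chosen threshold,
5. per-cell counting and condition statistics (means, SD/SEM, empirical
   CDFs, two-tailed Welch tests),
6. **classify_spots** — SNP FISH: colocalization of allele-specific
   detection-probe spots with guide-probe spots to call each RNA
   wild-type or mutant.

Everything is validated against a built-in scene simulator
(`make_scene()`) that renders ground-truth spots with a realistic
camera noise model.

## The two-population model and the sensitivity score

Candidate spots extracted from a filtered smFISH image fall into two
intensity populations: dim *background spots* (autofluorescent
particles and nonspecific probe binding, which are genuinely spot-like,
not pixel noise) and bright *RNA spots*. In a good image the two
populations are well separated, so `N(T)` — the number of candidates
with filtered intensity at least `T` — has a wide plateau between the
populations: any threshold on the plateau yields the same count, and
two analysts will agree. In a poor image the populations blend; every
threshold choice is arbitrary and materially changes the count.

The sensitivity score makes this quantitative. With `g(T) = log N(T)`,
the score at the working threshold `T*` (grid index `i*`) is

    S = | smoothed dg/dT at i* | * dT_grid

i.e. the relative change in spot count per threshold-grid step. The
derivative is a central difference over the positive-count part of the
grid; it is smoothed with a centred moving average (default window 7
grid points, shrunk symmetrically near the ends) because raw
log-derivatives of a counting curve are noisy. Multiplying by the grid
step makes the score scale-free: rescaling all intensities by any
constant leaves it unchanged, so scores are comparable across images
with different brightness. `S = 0` means the count is locally
indifferent to the threshold; larger values mean less trustworthy
counts. On an exactly geometric curve `N(T_i) = C r^i` the score equals
`|log r|` at every interior index, independent of smoothing — a useful
closed-form check that the tests exercise.

The score is an image-level quantity (one threshold curve per image);
condition-level summaries average it over images, never over cells.

## Filter and candidate extraction

The enhancement filter is the negated, scale-normalised Laplacian of
Gaussian (LoG), with sigmas in micrometres converted to voxels through
the stack calibration (defaults 0.17 µm lateral, 0.45 µm axial,
matching a ~1.4-NA objective's PSF). The LoG is the standard linear
band-pass matched to blob-like structure at a chosen scale: bright
spots of roughly PSF size become positive peaks, flat background maps
to zero, and linearity (`enhance(aI) = a enhance(I)`) preserves
relative intensities. The filter is separable and computed in compiled
code; borders use symmetric reflection. Single-plane stacks are
filtered in 2D.

Candidates are 26-connected regional maxima of the filtered stack
(8-connected for single-plane images): a voxel above all neighbours, or
a connected plateau of equal value whose in-image neighbours are all
strictly lower. Plateau handling matters on saturated or symmetric
spots: each plateau contributes exactly one candidate. The
representative is the plateau voxel nearest the plateau's floored
centroid with a lexicographic `(z, y, x)` tie-break — for non-convex
plateaus the floored centroid itself may lie outside the plateau, and
placing the representative off the plateau would break the invariant
that a candidate's value equals the filtered image at its position.
Plateaus with no strictly lower in-image neighbour (a constant image,
or a plateau filling the stack) are not maxima. Maxima on the outermost
voxel shell are kept but flagged `border`, so callers can exclude them.
A `min_value` floor (default: the 1st percentile of the filtered image)
merely bounds the candidate list; it never touches real structure.

## Automatic plateau selection

The working threshold is chosen where the spot count is least sensitive
to moving the threshold — the flattest point of `log N(T)`. Two
eligibility rules make the literal minimisation robust on real curves,
both visible in `select_threshold()`:

* **Search right of the dominant descent.** The candidate list is
  dominated by filtered-noise maxima. Left of that population's
  descent, `|d log N / dT|` is nearly zero for the trivial reason that
  `N` is still enormous, which would place the "plateau" below the
  noise floor (and overcount spots more than tenfold). Selection
  therefore starts at the first grid point where the smoothed descent
  rate reaches half its maximum, placing the search between candidate
  populations, where the manual procedure also looks.
* **Require an estimable derivative (`min_count`, default 20).** Where
  only a handful of candidates survive, counts change by 0 or 1 per
  grid step, and runs of exact zeros in the derivative appear purely
  from count discreteness. Grid points with fewer than `min_count`
  survivors are excluded; in the plateau region of any realistic image
  hundreds of spots survive, so the floor never binds there.

Trailing grid points where the count has flattened onto its final
positive value are excluded too (the stretch where only the single
brightest candidate survives is always exactly flat), ties break toward
the lower threshold, and degenerate curves (a single cliff) fall back
to any interior point with a defined derivative. A manual threshold can
always be supplied instead; smoothing affects the score, never the
count at a fixed threshold.

## The scene simulator

`make_scene()` renders multi-channel synthetic scenes with full ground
truth — the package's test bench and demo substrate. Design choices:

* **Geometry.** Cells are non-overlapping disks (default radius 5.8 µm)
  on a jittered grid spanning a 512 × 512 px field at 0.13 µm/px, with
  20 optical sections at 0.3 µm spacing; nuclei are concentric ellipses
  in a DAPI-like channel. This is the simplest geometry supporting
  per-cell counting at adherent-cell densities.
* **Spots.** Per-cell RNA counts are Poisson (mean 50; a dispersion
  parameter switches to negative binomial). Each spot is an anisotropic
  3D Gaussian (σ 0.17/0.45 µm) rendered by integrating the Gaussian
  mass over each voxel, so a spot's total intensity equals its
  amplitude up to the ±4σ window truncation (< 0.1%). Amplitudes are
  log-normal around the population mean (CV 0.25) — real spot
  intensities vary with probe count and local environment.
* **Two populations.** Background spots (default 30 per cell, placed
  uniformly inside cells) are rendered with the same PSF at mean
  amplitude `signal_amplitude / contrast_ratio`. The contrast ratio is
  the synthetic stand-in for hybridization quality. Defaults: signal
  5000 photons, contrast 8 — i.e. clearly separated populations.
* **Noise.** Poisson shot noise on signal plus a uniform background
  (default 100 photons/voxel), then additive Gaussian read noise
  (sd 3), the standard CCD model; negative camera values clip at zero.
* **Condition series.** `make_condition_series()` emulates degrading
  hybridization: the background-spot amplitude stays fixed and the
  *signal* amplitude falls with the contrast ratio. (Holding the signal
  fixed and brightening the background instead would, near contrast 1,
  lift the merged population cleanly away from the noise floor and make
  the quality score improve again — the opposite of what degraded
  hybridization does to real images, where fewer bound probes dim the
  RNA spots against an unchanged background.)
* **SNP scenes.** With `allele_fraction_mut` set, each RNA is assigned
  the mutant allele with that probability; a detection-channel spot is
  rendered at the same position with the matching allele's labeling
  efficiency (default 0.9), and in the wrong channel with probability
  `cross_channel_prob` (default 0). Detection channels carry their own
  background spots.

Scenes are bit-reproducible from their seed. What the simulator does
*not* model: optical aberrations and axial PSF asymmetry,
photobleaching, cell-to-cell autofluorescence differences, nuclear
transcription-site clusters, densely packed or overlapping cells, and
segmentation errors (the label map is exact). Tests passing on
simulated scenes therefore demonstrate the pipeline's correctness and
its behaviour under controlled degradation — not performance on
arbitrary real tissue, where segmentation and optics add failure modes
of their own.

## Colocalization SNP calling

Guide probes label every target RNA; a single allele-specific detection
oligonucleotide (stabilised by toehold strand displacement in the wet
protocol) marks the allele. `match_channels()` pairs guide spots with
detection spots by physical distance (anisotropic calibration, in µm),
greedily by ascending distance with each spot used at most once —
every accepted pair is mutually nearest among the spots still
unmatched, and exact ties break lexicographically so results are
deterministic. The default radius, 0.4 µm (≈ 3 lateral pixels), exceeds
the localisation scatter of a diffraction-limited spot but stays below
typical inter-spot spacing; it is configurable and should grow if
chromatic registration between channels is poor.

Each guide spot then receives exactly one call: `wt` or `mut` (matched
in one detection channel), `ambiguous` (matched in both within the
radius — reported as its own class by default rather than tie-broken,
with `resolve_by_distance = TRUE` available), or `unlabeled` (no
match; with 90% detection efficiency ~10% of RNAs are expected here).
`summarize_cells()` tallies calls per cell with the partition invariant
`n_guide = n_wt + n_mut + n_unlabeled + n_ambiguous`; guide spots
outside any cell are kept in bucket 0. Chance colocalization with an
unrelated detection spot is bounded by the Poisson estimate
`1 - exp(-rho * V)` with `rho` the detection-spot density inside cells
and `V` the matching ellipsoid volume; at defaults this is a few
percent, which the homozygous-control simulation reproduces.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma_xy`, `sigma_z` | 0.17, 0.45 | µm | filter scale; set to the PSF sigma of the optics |
| `n_thresholds` | 100 | – | threshold-grid resolution ("a variety of thresholds") |
| `smoothing_window` | 7 | grid points | derivative smoothing; odd, ≥ 3 |
| `min_count` | 20 | spots | derivative estimability floor in auto selection |
| `radius_um` | 0.4 | µm | colocalization radius |
| `pixel_size_xy`, `z_spacing` | 0.13, 0.3 | µm | calibration; all physical distances derive from these |

## Numerical and degenerate-input choices

* Threshold grids are uniform over the candidate range; an all-equal
  candidate set gets a degenerate two-point range so the drop from
  total to zero is still representable.
* `log N` is computed only where `N > 0`; the derivative needs both
  neighbours, so the grid end points are never selectable.
* Welch's unequal-variance t-test is the default two-tailed comparison
  (`student = TRUE` restores the pooled test); two zero-variance
  samples with equal means return `t = 0, p = 1` by convention.
* SD uses the unbiased `n − 1` denominator; SEM = SD/√n over cells.
* Integer-valued stacks are written as 16-bit TIFF (bit-exact round
  trip); other stacks as 32-bit float with a power-of-two intensity
  scale recorded in a JSON sidecar, preserving values to single
  precision.

## Problem sizes used in the test bench

The validation suite runs the full pipeline at the package's reference
conditions: 20 cells × ~50 spots in a 20 × 512 × 512 stack for
detection recovery (5 seeds), the contrast series {8, 4, 2, 1.25} × 5
seeds for the quality-score ordering, and two ~1000-RNA SNP scenes
(heterozygous and homozygous control). Unit tests use smaller scenes
chosen per property. These sizes give binomial error bars comfortably
inside the asserted bounds while keeping the whole suite quick on one
CPU.

## Worked example

```{r example, eval = FALSE}
library(spotsense)

# a clean scene at the reference conditions
sc <- make_scene(scene_params(seed = 1))
ss <- call_spots(sc$channels$guide, labels = sc$cell_label_map)
ss
sensitivity(ss$curve, ss$threshold_index)
score_detection(ss, sc$true_spots)

# condition comparison against a high-contrast reference
demo_turbo_vs_overnight(out_dir = "report")
```

## Known limitations

* Sub-voxel localisation (Gaussian fitting) and declumping of merged
  spots are out of scope; two RNAs closer than ~2σ merge into one
  candidate, which bounds recall at very high local densities.
* The sensitivity score's absolute scale depends on the grid
  resolution; comparisons should use a fixed `n_thresholds` (the
  default keeps this consistent), and only orderings across conditions
  are meaningful.
* Automatic selection assumes the dominant descent belongs to the
  lowest-intensity (noise/background) population; images containing
  almost nothing but real spots fall back to the global interior
  minimiser, which is the right answer there.
* The simulator's cells are convex and never touch; real segmentation
  errors and cell contact are not represented.
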