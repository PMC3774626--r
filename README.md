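# spotsense

Spot detection and signal-quality metrics for single-molecule RNA FISH
(smFISH) images, in R.

## The problem

In smFISH, dozens of short fluorescently labeled oligonucleotides
hybridize along a single transcript, so every RNA molecule shows up in
a 3D fluorescence stack as a bright, diffraction-limited spot. Counting
spots per cell yields absolute transcript numbers — *if* you can draw
the line between real RNA spots and the dimmer population of
spot-like background. spotsense is for microscopists and image
analysts who need (a) reproducible spot counts from 3D stacks, (b) an
objective score of how trustworthy those counts are, and (c) per-RNA
allele calls from two-colour SNP FISH experiments.

## What it computes

**Spot calling.** A stack `I` is filtered with the negated,
scale-normalised Laplacian of Gaussian matched to the PSF
(σ<sub>xy</sub> = 0.17 µm, σ<sub>z</sub> = 0.45 µm by default);
candidate spots are the 26-connected regional maxima of the filtered
stack. For a threshold `T`, the spot count is
`N(T) = #{candidates with filtered intensity ≥ T}`.

**Plateau threshold and sensitivity score.** A good image shows two
separated candidate populations (background spots vs RNA spots), so
`log N(T)` has a flat plateau between them. spotsense selects the
threshold `T*` minimising the smoothed `|d log N / dT|` and reports

&nbsp;&nbsp;&nbsp;&nbsp;`S = |smoothed d log N/dT|(T*) × ΔT`,

the relative change in spot count per threshold step — `S ≈ 0` means
anyone would count the same spots; large `S` means the populations
blend and counts are threshold-dependent. Condition comparisons use
per-cell counts (mean ± SD/SEM, empirical CDFs, two-tailed Welch
t-tests) and per-image sensitivity scores.

**SNP classification.** Guide-probe spots (every RNA) are matched to
allele-specific detection-probe spots within 0.4 µm (greedy by
ascending physical distance, each spot used once); each RNA is called
`wt`, `mut`, `ambiguous` or `unlabeled`, with per-cell tallies.

**Synthetic scenes.** `make_scene()` renders multi-channel scenes
(DAPI, guide, optional allele detection channels) with ground truth:
Gaussian-PSF spots of log-normal amplitude, a dimmer background-spot
population controlled by a contrast ratio, Poisson shot noise and
Gaussian read noise. Every stage of the pipeline is validated against
these scenes.

## Worked example

```r
library(spotsense)

sc <- make_scene(scene_params(seed = 1))        # 20 cells, ~50 RNA each
ss <- call_spots(sc$channels$guide, labels = sc$cell_label_map)
ss
#> <spot_set> channel 'guide': 965 spot(s) at threshold 22.5 (auto-selected)

sensitivity(ss$curve, ss$threshold_index)
#> <sensitivity_score> 0.0001481 at threshold 22.5 (window 7)

score_detection(ss, sc$true_spots)$f1           # against ground truth
#> [1] 0.9836901
```

The scene contains 997 true RNA spots; auto-thresholding recovers 965
of them with no false positives (F1 = 0.98), and the sensitivity score
~1.5×10⁻⁴ says the count changes by ~0.015% per threshold step — a
clean, quantifiable image. Degrading the contrast ratio from 8 to 1.25
(`make_condition_series()`) raises the score by three orders of
magnitude as the two candidate populations merge.

A command-line interface wrapping the same functions is installed at
`exec/spotsense` (`simulate`, `detect`, `snpcall`, `run`, `demo`
subcommands); `vignettes/spotsense-methods.Rmd` describes the model,
parameters and design choices in full.

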