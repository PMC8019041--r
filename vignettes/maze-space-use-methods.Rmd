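---
title: "Measuring space use in a patch–channel maze: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring space use in a patch–channel maze: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mazetrack` turns overhead video of a single small aquatic invertebrate in a
multi-patch maze into space-use and locomotion metrics, and ships a
ground-truthed simulator for validating every step of that chain. This
vignette documents the measurement model, the parameter choices, and the
design decisions that are not forced by the problem itself.

## 1. The arena model

The arena is a trapezoidal tank containing circular **patches** (13 cm
diameter by default, area `patch_area(0.13)` ≈ 0.013 m²) connected by
narrow straight **channels** (2.5 cm wide). Some patches are provisioned
with conditioned leaf material (**resource patches**); the rest are empty.

A maze is a `maze_geometry` built from a YAML configuration
(`read_maze_config()`, `build_maze()`); `default_maze()` ships a six-patch,
eight-channel trapezoid layout. Geometric conventions:

* Channel rectangles are **trimmed at the chord** where the channel meets
  each patch circle, not at the channel axis. Together with the documented
  label precedence (patch > channel subzone > outside) this makes
  patch + channel + outside an *exact partition* of the plane: no unlabeled
  slivers at channel mouths, which is what lets simulator ground truth and
  the measurement chain agree exactly.
* Each channel is divided along its axis into three ordered **subzones**
  `a`, `b`, `c` (equal thirds by default, configurable via
  `subzone_breaks`). Subzone membership uses half-open intervals, so a
  point on a break belongs to the downstream subzone and labels are stable
  under perturbations far smaller than any physical scale.

## 2. Tracking

`track_stack()` implements classical single-animal backlit tracking:

1. **Background**: per-pixel temporal median of the stack
   (`estimate_background()`). This assumes the animal moves during the
   clip; an animal that is nearly static for most of a short clip is
   partially absorbed into the median and detection suffers. That is a
   known property of median backgrounding, not something the package tries
   to hide — the QC report (`detection_rate`, `gap_histogram`) surfaces it.
2. **Detection**: one-sided difference (background − frame) thresholded
   *strictly* above `detection_threshold` (default 20 of 255); connected
   components labeled with `EBImage::bwlabel()`; blobs outside
   `blob_size_limits` (default 4–5000 px²) discarded; the centroid is
   intensity-weighted.
3. **Linking**: nearest-neighbour association frame to frame, with
   candidate jumps beyond `max_link_jump` (default 2 cm) rejected as
   spurious.
4. **Gap filling**: undetected runs of at most `max_gap` frames (default 5,
   i.e. 0.2 s at 25 Hz) are linearly interpolated and flagged
   `interpolated`; longer runs stay missing.

Pixel coordinates use the image convention (row 1 at the top);
`px_to_m()` converts pixel centres to arena metres with the y-axis pointing
up, using a scalar calibration (m/px, default 0.70 m across a 1280-px
frame).

## 3. Space-use metrics

`label_zones()` assigns each trajectory sample a zone label, carrying the
last known position across undetected runs, and collapses the result into a
contiguous `zone_sequence` whose segment durations sum exactly to the
trajectory time span.

**Transitions.** A directional patch-to-patch transition is registered only
when the animal traverses all three subzones of one channel in order
(`a→b→c` counts +1, `c→b→a` counts −1). `count_transitions()` implements
this as a five-state machine that resets whenever the animal leaves the
channel or re-enters a patch; partial entries (e.g. `a, b, a`) register
nothing. The test suite checks the machine against an independent
brute-force scan oracle (repeatedly take the earliest-ending `abc`/`cba`
occurrence) on thousands of random subzone strings. One subtlety frozen in
the tests: for overlapping strings such as `a,b,c,b,a` the shared `c` can
complete only one crossing, so reversing a sequence does *not* in general
negate the event list; it does for patch-separated complete traversals.

**Visits.** `detect_visits()` turns patch segments into visits. A channel
excursion that returns to the same patch *without a completed transition*
merges into one visit, with the excursion time excluded from the visit
duration (so merged visits have duration ≤ `t_exit − t_enter`). Visits of
at least `min_residence` (default 30 s) **qualify**.

**Descriptors.** `summarize_space_use()` reports: number of qualifying
visits (and the subset to resource patches), giving-up time (GUT: mean
qualifying resource-visit duration, minutes), total and percentage time in
patches, and **cumulative space used** = qualifying resource visits ×
`per_visit_area`. The default `per_visit_area` is 0.01 m², the operational
per-visit constant of the protocol the package supports; the geometric
patch area (0.013 m² for a 13-cm patch) is reported alongside, because the
two conventions are both defensible and users should see both.
`occupancy_bins()` adds a 30-s occupancy profile (resource/empty/channel/
outside fractions per bin).

**Kinematics.** `summarize_kinematics()` first applies `wall_filter()`,
which drops samples within `wall_margin` (default 1 cm) of a patch wall —
for a 13-cm patch that retains an 11-cm central arena — then resamples to a
regular grid (default `resample_dt` = 1 s, nearest native sample, gaps
excluded), and reports step length (cm), speed (cm/s), maximum absolute
acceleration (cm/s²) and a 30-s binned speed profile. The 1-s resampling
default matches the convention of reporting step metrics on 1-s intervals
rather than raw 25-Hz jitter.

## 4. Statistics

* `kruskal_wallis()` wraps the standard test (an independent hand-formula
  oracle lives in the tests).
* `scheirer_ray_hare()` is implemented from its rank-ANOVA definition
  (type-II sums of squares on mid-ranks, H = SS_effect / (SS_total/(N−1))),
  since no installed package provides it. Using mid-ranks makes the usual
  tie correction exact. Its null type-I error is calibrated in the
  acceptance suite; under a strong main effect the off-factor statistics
  are conservative, which is a property of the test, not the code.
* `fit_scaling()` fits log10(response) ~ log10(mass) (+ optional
  covariates) by OLS and reports the allometric exponent with a profile CI.
* `fit_occupancy()` fits a binomial GLM of patch occupancy on
  time × resource; under (quasi-)separation it falls back to a Firth-type
  penalized Newton fit (written in-package; no `logistf`/`brglm2`
  available) and flags `separation = TRUE`. Rank-deficient designs are
  handled by QR pivoting with `NA` for aliased terms.
* `coefficient_of_variation()` is 100·sd/mean (sample SD).

## 5. The simulator and what it does (not) emulate

`simulate_individual()` generates a 25-Hz trajectory as a correlated random
walk confined to the current patch (specular wall reflection, or tangent
alignment with probability `thigmotaxis` to mimic wall-following), an
exponential patch-leaving hazard (`mean_residence`), channel choice
weighted toward resource-leading channels (`resource_attraction`), scripted
channel traversals with AR(1) lateral jitter, and occasional aborted
entries (`channel_abort_prob`) that turn back before subzone `c`.

Defaults are the study conditions the package targets: mean speed 2.45 cm/s
(SD 1.03), 25 frames/s, 30-s qualification threshold, body masses
0.6–12.41 mg, visit-count allometric exponent 0.77 anchored at 6.9 mg.
Tests and the acceptance suite run the 6-h field protocol at a scaled
30-min problem size; that scaling is a package choice for desk-scale
runtimes, not a claim about the biology.

The simulator logs per-frame ground-truth zone labels from its own state
(with patch-precedence applied via in-circle checks), plus visit and
transition lists derived from those labels by oracles written independently
of the measurement chain. The acceptance suite demands *exact* agreement
between pipeline metrics and this ground truth over 50 individuals.

What it does **not** emulate: hydrodynamics, interactions between animals,
diel activity rhythms, resource depletion feedback on residence, or any
learning; residence is memoryless by construction. One numerical
consequence worth knowing: with an exponential residence of mean 600 s, the
mean of visits *conditioned on qualifying* (≥ 30 s) is 630 s by
memorylessness — measured qualifying means should be compared against the
conditional expectation, not the raw parameter.

`cohort_spec()`/`simulate_cohort()` scale this to cohorts. Two modes:
`"trajectory"` runs full walks (used for full-chain validation);
`"events"` draws qualifying visit schedules directly from the
Poisson/allometric model (used for 200-replicate parameter-recovery
studies, where trajectory-level qualification thinning would otherwise
distort the very exponent being recovered, and where speed matters).

`render_video()` produces NIR-style frames (bright field, slightly darker
wall outlines, anisotropic Gaussian dark blob oriented along the heading,
additive Gaussian noise) with ground-truth pixel centres, for tracker
validation.

## 6. Open design decisions, stated

* **0.01 m² vs 0.013 m² per visit**: both reported; `per_visit_area` is a
  parameter.
* **Two visit conventions**: merged-excursion durations (used here, per the
  excursion-exclusion rule) necessarily break the naive
  `duration = t_exit − t_enter` identity; the chosen semantics are frozen
  in tests.
* **Transitions and the 30-s rule**: a completed channel crossing counts
  regardless of whether the flanking visits qualify.
* **Layout under-determination**: published patch centre coordinates are
  not available, so `default_maze()` uses a plausible symmetric placement
  inside the 70/40/70-cm trapezoid; every geometric quantity that matters
  downstream (patch size, channel width, subzone thirds, wall margin) is
  explicit in the YAML and user-replaceable.

## 7. A minimal session

```{r, eval = FALSE}
library(mazetrack)
maze <- default_maze()
sim <- simulate_individual(forager_params(mean_residence = 300), maze,
                           duration = 1800, seed = 1)
an <- analyze_trajectory(sim$trajectory, maze)
print(an)
```
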