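---
title: "Quantifying force-modulated ABP engagement of actin bundle networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying force-modulated ABP engagement of actin bundle networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlemech)
```

## The measurement problem

Actin-binding proteins (ABPs) such as dimeric α-catenin can bind F-actin in
a force-dependent manner. In reconstituted assays, networks of actin
filament bundles assemble across the gaps of micropatterned myosin stripes
(e.g. 2.5 µm motor stripes with 17.5 µm spacing); when motors are ATP-active
they place the bundles under tension, and the ABP's engagement is read out
by two-channel TIRF imaging as the ratio of ABP to F-actin fluorescence per
bundle segment. F-actin intensity serves as the proxy for bundle size
(filament number), so the analysis reduces to: segment the network into
individual bundle segments, measure both channels per segment, and relate
the ABP : F-actin ratio to bundle size across conditions (active motors vs.
nucleotide-depleted; force-sensing protein vs. a force-blind mutant).

`bundlemech` implements this pipeline end to end, together with a synthetic
scene generator whose ground truth lets every stage be validated by
parameter recovery.

## The generative binding model

A bundle segment of `n` filaments under total tension `F` shares load
equally, so each filament bears `F / n`. The per-filament ABP occupancy is
modelled as

$$\rho(n) = k_0\,\bigl(1 + \beta\, g(F/n)\bigr),$$

with \(g(x) = x\) by default or the saturating alternative
\(g(x) = x/(x + x_0)\). Parameters:

| parameter | meaning | default |
|---|---|---|
| `k0` | baseline (mass-action) occupancy per filament | 1 |
| `beta` | force-activation amplitude; 0 = force-blind mutant | 0.5 |
| `F_seg` | total segment tension, arbitrary units | 6 |
| `x0` | saturation scale of the load response (optional) | — |

Force units are arbitrary throughout — no absolute force calibration
exists in this assay — so only the ratio `F/n` is meaningful.

Two limits motivate the linear form. With `beta = 0`, the expected ABP
signal per segment is \(n\,k_0\): strictly proportional to the F-actin
signal, the mass-action regime observed without motor activity and for the
force-blind mutant. With `beta > 0`, total segment ABP is
\(k_0 n + k_0 \beta F\): the force-coupled term is *independent of n*, so
the same amount of force-recruited ABP is spread over fewer filaments in
small bundles — per filament, small bundles are enriched. The per-segment
ratio is linear in `1/n`,

$$\frac{\rho(n)}{a_0} = \frac{k_0}{a_0} + \frac{k_0\,\beta\,F}{a_0}\cdot\frac{1}{n},$$

which is what `fit_ratio_vs_inverse_n()` exploits for parameter recovery
(`a0` is the F-actin photon density per filament).

By default every segment carries the same total tension — the premise that
motors apply a similar total force to a network segment regardless of its
size. `network_config(F_dist = "lognormal", F_sdlog = ...)` draws
per-segment tensions instead; tension heterogeneity is what populates the
"high ABP, low F-actin" quadrant in force-active conditions, since a small
bundle that happens to bear high tension collects disproportionate ABP.

## What the scene generator emulates — and what it does not

`sample_network()` places star/Y assemblies whose knots sit in
inter-stripe gaps with prong endpoints anchored on the stripes, bundle
sizes drawn from a configurable distribution (default uniform on 1–4).
`render()` converts a scene to a two-channel stack: constant per-pixel
path density (`n * a0` actin, `n * rho(n)` ABP; overlaps add), Gaussian
PSF, gain, constant background, Poisson shot noise, Gaussian read noise,
and per-frame geometric photobleaching, at a 2 s frame interval.

Deliberate simplifications: bundle intensity is strictly proportional to
`n` (no sub-resolution packing correction — matching the use of F-actin
intensity as the bundle-size proxy); paths are straight; networks do not
rearrange over time (state-resolved analysis is exercised on synthetic
jumps instead); there is no filament turnover, no unbound-fluorophore
haze gradient, and no nonspecific ABP adsorption to the stripes. Passing
recovery tests therefore demonstrates the pipeline's correctness on
idealized networks, not robustness to every pathology of real TIRF data.

Paths are rasterized as hard (supercover) pixel sets at constant density
rather than with anti-aliased splatting: this keeps the noiseless
contract exact — on-path pixels equal `density * gain + background` — at
the cost of one-pixel staircase edges, which the PSF blur smooths anyway.

Rupture lifetimes of paired filament complexes are modelled by
`rupture_model()` as a two-component exponential mixture parameterized by
medians (default 27 s main component, reproducing the observed 26–29 s
median; a small long-lived tail with a 400 s median persisting beyond six
minutes).

## The segmentation pipeline

`segment_pipeline()` composes five stages:

1. **Threshold** (`binarize()`). The default `"robust"` method takes
   `max(Li, median + 5 * MAD)`. Otsu's between-class-variance criterion
   (also provided, computed exactly over the observed values rather than a
   256-bin histogram) is the wrong tool here: these images are a dominant
   dark background plus thin bright structures spanning a several-fold
   brightness range, and Otsu frequently places its cut *between* dim and
   bright bundles, silently discarding single-filament segments. Li's
   minimum cross-entropy threshold tracks the background/signal boundary
   instead, but on noisy frames it can descend into the noise floor; the
   median + 5·MAD background floor prevents that. All methods are
   shift-equivariant, so masks are invariant to constant offsets.
2. **Thinning** (`skeletonize_mask()`): Zhang–Suen thinning to 1-pixel
   centrelines; topology-preserving, skeleton ⊆ mask.
3. **Junction detection** (`branch_points()`): a 3×3 neighbourhood filter.
   The default rule flags pixels whose ring of 8 neighbours shows ≥ 3
   off→on transitions (the Yokoi crossing number) — i.e. at least three
   distinct branches leave the pixel. A raw "≥ 3 on-neighbours" count
   (`method = "count"`) is also provided but fires on every corner of the
   4-connected staircases thinning produces along diagonals (~a third of
   skeleton pixels in practice), which would shred segments rather than
   separate them.
4. **Debranch and label** (`split_segments()`): branch points are removed
   together with a guard neighbourhood and the remainder labelled by
   8-connectivity. The guard is essential, not cosmetic: pixels flanking a
   junction touch diagonally, so removing the junction pixel alone leaves
   the arms 8-connected. The pipeline default guard radius is 4 px
   (Chebyshev) so that the eventual masks stay clear of the junction
   mixing zone (mask dilation radius 2 + ~2 px of PSF spread); with the
   minimal 3×3 removal, junction-adjacent mask pixels average the blurred
   signals of *all* bundles meeting there and bias the recovered
   ratio-vs-1/n slope by ~7–8 % even without noise. Components below
   `min_segment_px` (default 5) are dropped.
5. **Widen** (`widen()`): each labelled skeleton is dilated to a constant
   5-pixel-wide measurement mask; contested pixels go to the nearest
   skeleton (Euclidean), ties to the lower label.

## Measurement and statistics

`measure()` reports per-segment areas, background-subtracted channel
means, and the **ratio of means** — declared the canonical per-segment
statistic (more noise-robust than averaging per-pixel ratios; per-pixel
`ratio_image()` maps are diagnostic/display only). Segments whose
background-subtracted actin mean is not positive are flagged and excluded
from ratio statistics. The background estimate is the median intensity
outside all masks (`estimate_background()`).

State-resolved analysis: `state_windows()` encodes user-supplied
half-open frame windows between substantive network transitions;
`time_average()` averages frames within a window; `detect_transitions()`
offers an automatic z-score rule on the mean absolute frame difference as
a convenience, not as a claim about how states should be defined.
`match_segments()` (greedy maximum-IoU) tracks segments between states,
and `max_fold_change()` summarizes a tracked segment's ABP trajectory
relative to its first state.

Condition-level comparisons use `quadrant_fraction()` (fraction of
segments above the median ABP *and* below the median F-actin intensity,
medians computed per condition table — the operational readout of
small-bundle enrichment), `linfit()` (OLS with Pearson r), `welch_test()`
(unequal-variance t, two-sided; no multiple-testing correction is
applied), and `paired_compare()` for before/after-ATP designs. Paired
comparisons are keyed by stripe-gap region rather than by segment because
segments rearrange once motors engage. `normalize_per_trial()` divides
each channel by its per-trial median — median rather than maximum for
robustness to bright outliers — before pooling trials.

Whether condition scatter plots should use single designated frames or
state-averaged frames is left configurable; the default is a single
designated frame per condition. Thresholding is global per analyzed frame
by default, with `segment_config(region_mask = ...)` available to
restrict analysis to inter-stripe gaps.

## Stoichiometry helpers

`subunits_from_length()` converts filament length to subunit count via the
2.73 nm rise per subunit; an 8.6 µm median filament gives ≈ 3150 ≈ 3,000
subunits at one significant figure. `end_concentration()` divides the
polymerization actin concentration by subunits per filament (one barbed
end per filament, no annealing/severing correction). Note that 1 µM actin
with 8.6 µm filaments yields ≈ 0.32 nM barbed ends; a printed value of
0.6 nM would require ≈ 1.9 µM actin in the estimate. The helper implements
the stated formula and leaves the discrepancy visible rather than patching
either number.

## Numerical and design choices

* Pixel coordinates are 1-based `(row, col)`; frame windows and ROI boxes
  are half-open ranges. ROI boxes with even extents bias one pixel
  down/right of centre.
* Exact Otsu scans all boundaries between consecutive distinct values;
  the reported threshold is the midpoint between the two flanking values.
  A constant image yields an all-background mask plus a warning flag.
* Tie-breaks are deterministic everywhere: labels ordered by size then
  lexicographic smallest pixel; mask contests to the lower label; greedy
  IoU matching resolves equal IoU by first occurrence.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; identical `(params, seed)` give bit-identical output.
* Peak counting uses topographic prominence (computed from first
  principles — no installed R routine provides it), with plateaus counted
  once.
* The Gaussian PSF uses a separable kernel with circular boundaries, so
  total intensity is conserved exactly.

## Problem sizes used in validation

Validation experiments run on 160 × 192 px scenes (0.25 µm pixels) with
two stars of 3–5 prongs each: 100 noiseless scenes for segmentation
recovery; 100 noiseless / 60 noisy scenes (~280+ matched segments) for
parameter recovery; 100 paired replicates of 24 scenes per condition
(~240 segments each, versus thousands per condition in a full imaging
campaign) for the quadrant contrast; 2,000 null simulations for Welch
calibration; 10⁴ draws for the rupture-time round trip. These sizes were
chosen to give comfortable statistical margins while keeping a full
validation run in minutes on a laptop.

## Known limitations

* The simulator's networks are static and tree-like (no loops, no
  crossings between distinct stars); real networks form interlocking
  stars whose segmentation is harder.
* Bundle-size recovery relies on F-actin intensity linearity in `n`;
  sub-resolution bundle packing and polarization effects are not
  modelled.
* The automated state detector is a stand-in for expert annotation of
  "substantive transitions"; its z-threshold has no claimed optimality.
* `binarize()`'s robust default assumes the background occupies a clear
  majority of pixels; dense fields violate the median/MAD estimate.
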