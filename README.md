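# bundlemech

Quantification of force-modulated actin-binding-protein (ABP) engagement
of myosin-tensed actin bundle networks, from two-channel TIRF-style image
stacks to per-bundle-segment ratiometric statistics — plus a synthetic
scene generator with known ground truth that validates the whole pipeline
by parameter recovery.

## The problem

In reconstitution assays, actin filament bundles assemble into star-shaped
networks spanning the gaps of micropatterned myosin stripes. With ATP the
motors tense the network; a fluorescent ABP (e.g. dimeric α-catenin) binds
F-actin in a force-dependent way. The readout is ratiometric: per bundle
segment, the ABP : F-actin fluorescence ratio, with F-actin intensity as
the proxy for bundle size *n*. The package answers the practical
questions in that workflow:

* **Segmentation** — threshold the F-actin channel, skeletonize, find
  junctions with a 3×3 neighbourhood filter, debranch, and dilate to
  consistent 5-pixel-wide measurement masks (`segment_pipeline()`).
* **Quantification** — per-segment channel means and ratios, state-window
  time averaging, segment tracking across states, fold changes, per-trial
  normalization, quadrant fractions, OLS regressions, Welch tests, paired
  ±ATP comparisons, line-scan bundle counting, box-ROI measurement, and
  census/survival summaries of paired filament complex (PFC) ruptures.
* **Simulation** — ground-truth networks on stripe micropatterns rendered
  as noisy two-channel stacks under a per-filament-load binding model:

  rho(n) = k0 * (1 + beta * g(F/n)),  g(x) = x (default)

  so a segment's expected ABP signal is `k0*n + k0*beta*F`: the
  force-coupled part is independent of *n* and per-filament occupancy is
  enriched on small bundles. `beta = 0` encodes a force-blind mutant
  (pure mass action). Regressing the measured ratio on `1/n` recovers
  `k0*beta*F/a0` (slope) and `k0/a0` (intercept).

## Worked example

```r
library(bundlemech)

pattern <- make_stripe_pattern(2.5, 17.5, pixel_size = 0.25,
                               shape = c(160, 192))
net <- network_config(n_stars = 2, prongs_per_star = 3,
                      binding = binding_params(k0 = 1, beta = 0.5))
optics <- render_params(psf_sigma = 1, background = 10, gain = 2,
                        read_noise_sigma = 2)

tab <- simulate_measurements(pattern, net, optics, n_scenes = 60, seed = 8)
fit <- fit_ratio_vs_inverse_n(tab)
cat(sprintf("slope %.4f (truth %.4f), intercept %.4f (truth %.4f)\n",
            fit$slope, 1 * 0.5 * 6 / 30, fit$intercept, 1 / 30))
#> slope 0.0972 (truth 0.1000), intercept 0.0360 (truth 0.0333)
```

Each of the 60 simulated fields is rendered, segmented and measured; each
recovered mask is matched to its ground-truth prong, and the regression of
the per-segment ABP : F-actin ratio against reciprocal bundle size
recovers the binding-law amplitude within a few percent despite shot and
read noise.

The stoichiometry helpers reproduce the familiar back-of-envelope numbers:

```r
subunits_from_length(8.6, 2.73, rounding = "signif1")
#> [1] 3000
end_concentration(1e-6, subunits_from_length(8.6, 2.73)) * 1e9  # nM
#> [1] 0.3174419
```

A configurable end-to-end run (simulate → segment → quantify → compare,
with CSV/JSON/TIFF outputs) is available as `run_pipeline()`, and a thin
command-line wrapper with verbs `simulate`, `segment`, `quantify`,
`states`, `compare`, `census`, `stoich` and `run` ships in
`inst/cli/bundlemech.R`.

## Layout

```
R/                  implementation (simulation, segmentation,
                    quantification, statistics, stoichiometry, IO)
tests/testthat/     unit, property and validation suites
scripts/acceptance.R   from-scratch validation report
vignettes/          methods vignette: models, assumptions, design choices
inst/cli/           command-line wrapper
```
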