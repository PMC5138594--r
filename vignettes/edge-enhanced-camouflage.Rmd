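---
title: "Edge-enhanced disruptive camouflage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-enhanced disruptive camouflage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgecamo)
```

Many disruptively coloured animals accentuate the borders between their
pattern elements: light patches fade towards white at their edges, dark
patches towards black, or only one of the two. This package provides a
complete, synthetic test bench for asking how such **edge enhancement**
affects crypsis: stimulus generation, factorial experiment designs,
simulated observers, and the Bayesian analysis chain, all seeded and
reproducible. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the underlying
methods left genuine freedom.

## 1. The colour population

Leaves and camouflage patches draw from one CIE-LAB colour population, so
the target is chromatically background-matching by construction. Real
paradigms of this kind start from a calibrated photograph of leaf litter;
`synth_forest_population()` substitutes a parametric stand-in: a
two-component LAB mixture of a dominant warm-brown litter cluster (80%,
L ~ N(45, 14), A ~ N(10, 4), B ~ N(22, 6)) and a darker, greener
shadow/moss component (20%, L ~ N(30, 15), A ~ N(−5, 12), B ~ N(10, 14)),
with L clipped to [0, 100]. The minority component supplies the chroma
outliers a real photograph contains; `filter_population()` then excludes
every colour beyond one sample SD of the population mean on the A or B
axis, exactly as the paradigm prescribes, and with this mixture about
two-thirds of colours survive. The filter computes its statistics once on
the input (a single exclusion pass, boundary values retained); whether the
original procedure used sample or population SD is not recorded anywhere,
so we fixed the conventional sample SD.

Patch colours come from disjoint lightness-percentile bands — dark from
the 35th–45th, light from the 55th–65th — giving internal contrast while
keeping both colours typical of the background. Percentile ranks use the
midpoint convention with average ranks for ties, inclusive at band
endpoints, which makes band membership deterministic. A population of
identical colours collapses both bands and is reported as degenerate
rather than silently producing a zero-contrast pattern.

`lab_to_display()` implements the textbook CIE-LAB → XYZ → linear sRGB
conversion (D65). Out-of-gamut results — which edge enhancement can
legitimately produce when an offset pushes L near 0 or 100 — are clipped
channel-wise and *flagged*, never raised as errors, because clipping at
the gamut boundary is what a real display would do.

## 2. Backgrounds

`render_background()` stamps leaf masks sequentially at uniform random
positions; later leaves occlude earlier ones. Leaf lengths follow a
shifted gamma: the 20 px hard minimum is the shift, the mode constraint
pins (shape − 1) · scale = 1 px, and the 95th-percentile constraint
(46 px) is solved numerically, giving shape 1.124 and scale 8.04. A gamma
is the simplest positively skewed family able to satisfy all three printed
constraints simultaneously. Widths are 20% of an independent draw from the
same distribution. The mask itself is a parabolic lens — pointed tips,
widest at the centre — because only "leaf-shaped" is constrained; any
convex elongated mask preserves the statistics that matter downstream
(edge density and spatial scale).

Shadows model a light source over the viewer's right shoulder: each leaf's
silhouette, translated left by a width drawn from |N(2.4, 3)| px and minus
the leaf itself, is darkened by 70% in *linear* intensity immediately
before the leaf is stamped, so a leaf can occlude its neighbour's shadow
but never its own. The shadow is flat and multiplicative; there is no
penumbra. At the large-screen scale of 20 px = 0.62°, the 95th percentile
of these widths converts to 0.23°.

The default canvas is 3500 × 1170 px: the 350-px target then spans a tenth
of the long axis, reproducing the very-large-display search regime in
which a camouflaged object does not automatically receive foveal scrutiny.
One point deserves honesty: at the stated leaf sizes, 15,000 stamps cover
only about a third of that canvas (the Boolean-model expectation
exp(−n·Ā/A) ≈ 0.65 of pixels are never painted), so scenes have visible
base-canvas interstices. The test suite checks coverage *against the
Boolean-model prediction* at an area-scaled size — that is the meaningful
guard against mis-sized masks — rather than asserting near-total coverage,
which the stated geometry cannot produce.

## 3. Camouflage texture and edge enhancement

The pattern is white Gaussian noise filtered in the Fourier domain by a
radial Gaussian amplitude A(d) = exp(−(d − μ)²/2w²), d in cycles/px. The
spectral centre μ = 0.048 cycles/px sets the pass-band wavelength
1/μ ≈ 21 px, matching the modal leaf length, which is what makes the
texture a spatial-scale match to the background. The original filter's
width parameter is recorded as σ = 120 with its unit convention
unrecoverable; we store it verbatim and map it to the working bandwidth by
the documented rule w = 3/(2σ) = 0.0125 cycles/px, fixed once so that
(a) the amplitude at DC is far below 10% of the pass-band peak and (b) the
posterised pattern's breadth sits at the pass-band wavelength. Both
properties are asserted in the tests; the rule is overridable via
`filter_spec(bandwidth = )`.

**Patch breadth** is measured by `patch_breadth()` as twice the median
chord (run) length over rows and columns of the label image: one dark plus
one light chord make up a full period, so for a narrow-band pattern the
statistic estimates the dominant wavelength (≈ 21 px at the defaults). We
deliberately use a chord-based scale measure rather than a mean
boundary-distance statistic: mean distance to the boundary saturates near
3–4 px for any labyrinthine median-split pattern regardless of bandwidth,
and therefore cannot measure the pattern scale it is meant to check.

`posterise()` thresholds at the median with ties going to the dark class —
an arbitrary but fixed convention that makes the split deterministic; on
even grids with continuous noise each class holds exactly half the pixels.
A constant texture cannot be split and is reported as degenerate.

**Boundary distance.** The luminance ramp needs a per-pixel distance to
the patch boundary. We define it as the Euclidean distance to the nearest
opposite-label pixel minus one (floored at zero), so that pixels
*immediately adjacent* to the other patch sit at distance 0 and receive
the full offset. This convention is forced by the model's endpoint
behaviour — the boundary pixel of a light patch with L = 55 and offset 40
must show L = 95 — and is validated pixel-for-pixel against a brute-force
all-pairs oracle on small images. The transform itself is EBImage's exact
Euclidean distance map.

**The ramp.** For ramp variants, L(d) = L_patch ± offset · max(0, 1 −
d/width): the full offset at the boundary, the untouched patch value at
d ≥ width, linear and continuous in between, computed from the shared
distance map so the light and dark ramps abut exactly at the boundary —
the point of highest contrast. `no_low` ramps only light patches, `no_high`
only dark ones, and `square` replaces the gradient with a constant
±offset band over the same width on both sides of the boundary (the
same-width-both-sides reading is an assumption; the alternative — a
single-sided band — would halve the manipulated area and was rejected to
keep the square variant's contrast energy comparable to `both`). A and B
channels always keep the patch colour: the model manipulates luminance
only.

The snake target is a sinusoidal tube (two undulation periods, body width
12% of length, elliptically tapered ends). Only the length (350 px ≈ 10.9°
at the screen scale) and a snake-like silhouette are constrained; the tube
is the simplest connected shape meeting both.

## 4. Designs

* **Experiment 1** (edge strength): control plus the `both` variant at
  widths {8, 16} px × offsets {20, 40}, × 2 shadow levels × 8 target
  cells = 80 trials, each combination exactly once. The source description
  "twice within each location" is realised as the shadow factor — once per
  shadow level per location — which is the only reading consistent with
  the printed total of 80.
* **Experiment 2** (edge structure): control plus
  {`no_high`, `no_low`, `square`} × offsets {20, 40} at width 16 px,
  × 2 shadow levels × 8 cells = 112 trials. No total is printed for this
  design; the balanced factorial is adopted.
* **Experiment 3** (depth judgement): {control, `both`, `no_high`,
  `no_low`} × 2 backgrounds × 25 repetitions = 200 trials, target central
  and vertical, with a leaf-free 4.49° × 13.80° band around it so
  occlusion cannot act as a depth cue. The monitor scale is not printed in
  pixels; we adopt 350 px/13.30° (≈ 26.3 px/°), making the fixed 0.53°
  edge width 14 px. The edge offset for this experiment is unstated; the
  default is 40, the value used in the illustration figures, and it is
  configurable.

Per-trial seeds derive from the master seed by the documented rule
`(seed + 7919·i) mod (2³¹ − 1)`, so any single trial's stimulus and
behaviour are reproducible in isolation.

## 5. Synthetic observers

`simulate_rt_dataset()` draws log RT = intercept_p + effect_c + N(0, s):
participant intercepts N(1.0, 0.25) log-seconds (median ≈ 2.7 s,
plausible for a large-display search), within-participant spread s = 0.4.
This makes the analysis's assumptions *literally true under the null*,
which is the point: the generator exists to calibrate and validate the
analysis chain, not to imitate human data. Errors occur with probability
clamp(0.06 + 0.08·(log rt − intercept_p)), coupling errors positively to
slow trials as observed in real search data; error trials are generated
and then discarded by the analysis, exercising the exclusion path.
Depth responses use an ordinal probit: latent N(shift_c, 1) cut at ±0.5.

What the generator does **not** emulate: fatigue and learning across
trials, spatial effects of target location, lapses, non-log-normal RT
tails, and any actual perceptual mechanism linking edge parameters to
detectability — condition effects are injected, not emergent. Passing
tests therefore demonstrate that the pipeline recovers what was injected
at realistic noise levels, not that edge enhancement helps camouflage.

## 6. The analysis chain and its numerics

Preprocessing follows the published order strictly: exclude errors first,
then log transform, then z-score each participant using their own mean and
sample SD over all their correct trials (both shadow levels pooled —
whether z-scoring preceded or followed the shadow split is not recorded;
pooling matches "all times for each participant"). Control-relative scores
subtract the participant's same-shadow-level control mean, so control rows
are identically zero and any participant-level shift or RT rescaling
cancels exactly.

The JZS Bayes factor integrates the effect-variance mixing parameter g
(inverse-gamma(1/2, r²/2), the Cauchy(0, r) scale mixture) with adaptive
quadrature at relative tolerance 1e-9, with the H0/H1 likelihood ratio
folded inside the integrand for numerical stability at large t. The
reported `num_error` is the integrator's error estimate relative to the
Bayes factor. Tests require agreement to 1e-3 relative with an
*independent* oracle that instead integrates the effect size itself
against a noncentral-t likelihood on a 40,001-point tangent-substitution
grid. Degenerate inputs (zero variance, n < 2) are errors, not NaNs.
Evidence labels bucket |log BF| at 0, ln 3, ln 10, ln 30, ln 100; a Bayes
factor of exactly 1 is labelled anecdotal on the H0 side by convention.

Bootstrap CIs are percentile intervals of the mean (default 10,000
resamples, seeded). At n = 10 participants the percentile bootstrap is
known to undercover slightly — our own calibration simulation puts
coverage near 90% against the nominal 95% — and the test suite asserts
that measured behaviour rather than the nominal level. Shapiro–Wilk is
delegated to `stats::shapiro.test` with the standard 3 ≤ n ≤ 5000 domain
guard.

Problem sizes in the test suite were chosen for a desk-scale run: 100,000
draws for the length/width percentile checks, 128² textures over 20 seeds
for the breadth calibration, 100 simulations each for the null-calibration
and effect-recovery suites, and area-scaled canvases for the rendering
checks. The full suite completes in about a minute on one core.

## 7. Transects

`linearize()` inverts a 2.2 display gamma, and `transect_profile()`
averages all three channels over a 7-px-diameter disc (pixel centres
within Euclidean radius 3.5, no interpolation) at 1-px steps along a
segment. Intensities are reported on the image's own [0, 1] scale with no
per-transect renormalisation. On an edge-enhanced boundary the profile
shows the diagnostic overshoot/undershoot pair flanking the step — the
same signature seen in photographs of edge-enhanced animals. Discs
reaching past the border are truncated and flagged rather than dropped.

## 8. Known limitations

* The band-pass filter's original functional form and σ-unit are not
  recoverable; our radial Gaussian preserves the one verifiable property
  (the pass-band spatial scale) but is not guaranteed to be the original
  filter.
* The renderer is photometrically exact but geometrically simple: flat
  shadows, hard occlusion, no anti-aliasing of mask edges.
* Human headline results (Bayes factors on real search times) are out of
  reach by design — they require the original participant data; the
  package's claims are about generator statistics and pipeline
  correctness.
* Bayesian ANOVA model comparison across factorial structures is not
  implemented; the per-condition control-relative t-tests are.
* No animal-vision (cone-catch) modelling: stimuli are defined in CIE-LAB
  and standard sRGB, i.e. for human observers on calibrated displays.
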