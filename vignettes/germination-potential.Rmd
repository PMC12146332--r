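---
title: "Measuring germination potential from time-lapse seed imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring germination potential from time-lapse seed imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtrack)
```

## The model

A germinating seed changes shape in one dominant way: the radicle
elongates. On a dark background with controlled lighting, that change is
visible as growth of the bright foreground region. `germtrack` turns this
into a one-dimensional signal per seed: the white-pixel count `Y` of the
binarized seed crop as a function of hours `x` since the experiment
started, sampled hourly from hour 24 (most seeds only begin germinating
about a day in) to hour 48.

The signal model is a smooth monotone growth curve observed with
quantization and segmentation noise. Five candidate mean functions are
fitted — exponential `a·e^(bx)`, linear, logarithmic `a·ln x + b`, power
`a·x^b`, and a polynomial (cubic by default) — and ranked by the
coefficient of determination in explained-over-total form,

    R² = Σ(ŷᵢ − ȳ)² / Σ(yᵢ − ȳ)².

The first derivative of the selected polynomial is the **germination
potential**: the instantaneous rate of morphological change in px/h. Its
maximum over the observation window locates the hour of fastest growth.
This redefines the classical notion (a count of germinations inside a
fixed early window) as a rate curve, which distinguishes seeds that
germinate early-and-slowly from ones that surge late even when their
final counts agree.

### Assumptions

* Foreground/background separation is achievable with one global
  threshold (120 on the 0–255 scale): dark cloth, no specular highlights,
  seed and sprout both bright. No adaptive thresholding is attempted.
* The annotated bounding box of a tracked seed contains that seed's whole
  body + sprout and (approximately) nothing else; overlapping neighbours
  contaminate the count.
* The seed body's own area is constant, so area growth is sprout growth.
  Real seeds can *shrink* as they dry, producing non-monotone series and
  negative fitted rates; the synthetic generator reproduces this confound
  via `shrink_rate` precisely so the analysis stages can be tested on it,
  but the measurement model does not correct for it (separating body from
  sprout is out of scope).

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| binarization threshold | 120 | intensity (0–255) | reference operating point for dark-cloth imagery; ties (exactly 120) map to black, keeping "below threshold = background" closed |
| sampling grid | 24–48 step 1 | hours | germination onset clusters after ~24 h; hourly sampling matches the published analysis grid |
| polynomial order | 3 | — | lowest order that captures onset–acceleration–saturation; order ≥ 4 tails turn downward and are rejected by the monotone rule |
| monotone rule | derivative ≥ 0 at `t_max` | — | concrete encoding of "growth curves must not end decreasing" |
| tie-break | fewer parameters at ΔR² < 1e−12 | — | prevents a nested cubic from displacing an exactly-linear truth |
| noise factor | 0.2 | probability | reference augmentation strength |
| salt share | 0.5 | fraction | impulse polarity split, white vs black |
| split ratios | 7:2:1 | — | train = ⌊0.7N⌋, remainder split exactly 2:1, leftover → test (8148 → 5703/1630/815) |
| mAP IoU grid | 0.50–0.95 step 0.05 | IoU | the conventional mAP50–95 grid; configurable, since reports in the wild disagree on the upper bound (0.90 vs 0.95) |
| visibility threshold | 2 | px | radicle length above which the generator labels a seed "germinated" |

## Numerical choices

* **R² form.** The explained/total form is primary, because that is the
  published definition; the residual form `1 − SSR/SST` is co-reported on
  every fit. For linear-in-parameters least squares with intercept the two
  are identical (property-tested to 1e−10). For log-linearized
  exponential/power fits the explained form is *not* bounded by 1; both
  numbers are kept so a reader can see when the forms diverge. Selection
  uses the explained form as specified; on all tested growth series the
  cubic's advantage is large enough that the ranking is unaffected.
* **Log-linearization.** Exponential and power families are fitted by
  ordinary least squares on the log scale rather than iterative nonlinear
  least squares: deterministic, closed-form, reproducible. R² is still
  scored on the original y scale.
* **Threshold tie.** `binarize` uses a strict `> threshold` rule; a pixel
  exactly at 120 is background.
* **Grayscale.** BT.601 luma (0.299R + 0.587G + 0.114B), rounded half up.
* **Peak location.** The derivative's maximum over the closed domain is
  found exactly (endpoints + real critical points; for a concave quadratic
  this is the vertex −b/2a clipped to the domain). Because published peak
  hours are typically read off hourly-sampled curves, the hourly-grid
  argmax is reported alongside the exact peak.
* **Rounding.** Germination rates round half up to one decimal
  (`round()`'s banker's rounding would turn 0.25 % into 0.2 %).
  Exported equation strings round coefficients to 4 decimals; internal
  precision is full.
* **Degenerate inputs.** Constant series make R² undefined → error, not
  NaN. Empty detection/ground-truth sets yield explicit `NA` sentinels for
  precision/recall, never a silent 0. A box that misses the image, a gap
  in the sampling grid, or an ambiguous seed track each raise a named
  error rather than guessing.

## The synthetic generator: what a green test establishes

`scene_spec`/`render_stack` emulate the acquisition setup: dark background
(intensity 15), optional dish ring (60), elliptical seed bodies (200) with
straight constant-width radicle strokes whose length follows a planted
cubic or logistic law, 97 frames over 48 h at 30-min intervals, optional
impulse noise applied only *after* the exact foreground mask is recorded.
Intensities are chosen so binarization at 120 recovers the generator's
mask exactly — on noise-free scenes the measured white count equals the
planted area on every frame, which is the end-to-end oracle for the
cropping/thresholding/counting chain.

Deliberate simplifications, and their consequences for what the tests can
claim:

* Radicles are straight rays; real radicles curve. Straightness is what
  makes the sprout area analytically ≈ width × length (the rounded tip is
  included in the stated length; at lattice-aligned angles such as π/4 the
  rasterized stroke over-covers by ~20 %, so fixtures use incommensurate
  angles). A green area test validates the measurement chain, not
  robustness to curved morphology.
* No texture, lighting gradients, condensation, or seed-to-seed
  occlusion. Threshold choice is therefore untested against the realistic
  failure mode of poor contrast.
* Shrinkage is linear in the ellipse axes after onset — a caricature of
  drying, sufficient to produce the non-monotone series that exercise the
  monotone-rejection rule.

## Design decisions taken here

* Internal boxes are 0-based half-open; VOC files are read/written in the
  1-based inclusive dialect. Widths are then always `xmax − xmin` with no
  ±1 bookkeeping.
* The dataset split is an unstratified seeded shuffle; the floor/2:1
  remainder rule is fixed by requiring 8148 → 5703/1630/815 exactly.
* `sp_noise` semantics: the noise factor is the *replacement probability*
  per pixel (not a per-polarity probability), and replaced pixels split
  50/50 white/black; for color images the whole pixel is replaced across
  channels. These are the most common salt-and-pepper conventions
  consistent with "some pixels become white or black".
* Seed tracking across frames is nearest-center matching from an initial
  box, with an explicit override hook, since manual selection is the
  realistic workflow for dish-level analysis; ties raise an error.
* Detection matching is the greedy-by-confidence one-to-one protocol with
  all-points AP interpolation — the YOLO-ecosystem convention, verified
  against a brute-force maximum-matching oracle on small instances (greedy
  is provably optimal when each detection overlaps at most one truth; on
  adversarial layouts it is only a lower bound, which the tests assert).
* The published derivative tables for dishes 6–8 disagree slightly with
  exact differentiation of their own cubics (consistent with transcription
  error); exact differentiation is treated as authoritative and the exact
  reproduction check covers dishes 1–5.

## Known limitations

* Germination potential inherits every bias of the white-pixel proxy:
  shrinkage, binarization halo, and box contamination all flow into the
  fitted rate, and the method reports them honestly (up to and including
  negative rates) rather than correcting them.
* Log-linearized fits weight multiplicative error; series with counts
  near zero would distort the exponential/power candidates (guarded: those
  families refuse non-positive y).
* The explained/total R² used for ranking can exceed 1 for non-LS fits;
  it is reported as defined, with the residual form alongside as the
  diagnostic.
* mAP values from a trained detector are not reproducible without the
  detector and full dataset; the metrics module is validated against
  hand-computable cases and independent oracles instead.
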