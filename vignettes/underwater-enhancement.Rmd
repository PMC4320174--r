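---
title: "Dual-intensity Rayleigh stretching for underwater images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-intensity Rayleigh stretching for underwater images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwie)
```

## The problem

Water absorbs long wavelengths first: red light is largely gone within a few
meters of depth, while green and blue penetrate much further. Underwater
photographs therefore carry a strong blue-green cast, a compressed intensity
range, and — because scenes typically contain both brightly lit sand and
shadowed structure — coexisting regions that naive global stretching drives
into over- or under-enhancement, destroying detail at both ends.

`uwie` implements a histogram-modification pipeline that addresses the cast
and the contrast loss jointly, without any physical image-formation model or
per-image tuning.

## The pipeline

Given an 8-bit RGB image, `enhance()` applies, in order:

1. **Median-referenced Von Kries balancing** (`apply_color_balance()`).
   With channel means $R_{avg}, G_{avg}, B_{avg}$, the channel whose mean is
   the *median* of the three is the reference; the minimum-mean channel is
   multiplied by $A = \mathrm{median}/\mathrm{min} \ge 1$ and the
   maximum-mean channel by $B = \mathrm{median}/\mathrm{max} \le 1$.
   Using the median rather than the dominant (blue/green) channel keeps the
   multipliers moderate: scaling a nearly-extinct red channel all the way up
   to the blue mean would amplify it so strongly that object colors become
   untrustworthy. After this step all three channel means equal the median
   of the original means — a property the test suite checks to $10^{-9}$
   relative, which is why no clipping happens here (clipping would destroy
   it; the next stage renormalizes anyway).
2. **Global min–max stretch** (`global_stretch()`): each channel's observed
   $[i_{min}, i_{max}]$ is mapped affinely onto $[0, 255]$, so the mean
   computed next is meaningful on the full dynamic range.
3. **Mean split and dual Rayleigh stretch** (`dual_stretch_channel()`).
   Each channel is split at its *post-stretch* mean into a lower region
   $[\min, \mu]$ and an upper region $[\mu, \max]$, and each region is
   independently mapped onto the full range following a Rayleigh
   distribution. Both maps are applied to *all* pixels, saturating outside
   their region: the lower-region map sends everything at or above the mean
   to 255 (a bright rendition that lifts shadow detail), the upper-region
   map sends everything at or below the mean to 0 (a dark rendition that
   preserves highlight detail). Membership of the exact mean value is
   therefore immaterial — it maps to 255 under one and 0 under the other,
   and the next stage averages them.
4. **Composition** (`compose_average()`): the three bright channels form one
   image, the three dark channels another, and the output is their
   per-pixel mean, computed in real arithmetic before any quantization.
5. **HSV color correction** (`correct_color()`): the composed image is
   clipped to $[0,255]$, converted to HSV (hexcone model), saturation and
   value are independently stretched between their 1st and 99th
   percentiles onto $[0,1]$, hue is left untouched, and the image is
   converted back.
6. **Quantization** (`quantize()`): clip to $[0,255]$ and round half away
   from zero. Everything upstream runs in doubles; quantization happens
   only here and before metric computation, so rounding error never
   compounds across stages.

## The Rayleigh region map and its two interpretations

The Rayleigh distribution, with CDF $F(x) = 1 - e^{-x^2/2\sigma^2}$, is the
commonly assumed target shape for well-exposed underwater histograms: a
skewed bell that concentrates mass mid-range. Two readings of "stretch the
region to follow the Rayleigh distribution" exist, and the package
implements both (`rayleigh_params(mode = ...)`):

* **`"quantile"` (default)** — histogram specification. The region value is
  normalized to $u \in [0,1]$ and mapped through the inverse CDF of a
  Rayleigh distribution *truncated* to $[0,255]$:
  $y = F^{-1}\!\left(u \, F(255)\right)$. This map is strictly monotonic,
  hits both endpoints exactly, and provably sends a uniform input onto the
  truncated Rayleigh law — the acceptance checks verify a
  Kolmogorov–Smirnov distance below 0.02 on $10^5$ seeded samples
  (observed: ≈ 0.003).
* **`"literal"`** — direct evaluation of the Rayleigh-stretched transfer
  expression (the stretched value fed through the Rayleigh *density*),
  followed by a linear rescale onto $[0,255]$. The density is not a
  distribution map: it peaks at $x = \sigma$ and decreases beyond, so the
  transfer is non-monotonic and cannot hit both endpoints on its own. It is
  retained purely for fidelity experiments; the quantile mode is what
  realizes the stated intent and is the default.

The scale parameter is expressed as a fraction of the dynamic range,
$\sigma = \alpha \cdot 255$, with default $\alpha = 0.4$ ($\sigma = 102$).
No canonical value exists for this parameter; $0.4$ places the mode of the
truncated distribution near mid-range, matching the bell-shaped target
description, and is exposed on both the function and CLI surfaces. The
$\alpha$ appearing in the transfer denominator and the $\sigma$ in its
exponent are treated as the same quantity — the literal expression is a
simplification chain in which the two symbols must coincide.

One directional note: after this construction the *lower*-region map
produces the *brighter* image (region $[\min,\mu]$ occupies the full range,
everything above saturates high). Descriptions of this family of methods
sometimes label the lower-stretched result "under-enhanced"; the package
names the two outputs by their measured brightness (`lower` = bright,
`upper` = dark). The composition averages both, so the final output does
not depend on the labeling.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `alpha` | 0.4 | fraction of range | Rayleigh scale $\sigma/255$ |
| `mode` | `"quantile"` | — | region-map interpretation (above) |
| `sv_lo`, `sv_hi` | 1, 99 | percent | HSV S/V stretch limits |
| `skip_color_balance`, `skip_hsv` | `FALSE` | — | ablation switches |

The 1%/99% limits are read as *percentiles of the data* (linear
interpolation between order statistics, `stats::quantile` type 7), not as
fixed cuts at 1% of the intensity range; the percentile reading is the
common convention for limited stretching and makes the clip fraction
scene-independent. By construction about 1% of pixels saturate at each end
of S and V.

## Quality metrics

`img_entropy()` computes the discrete entropy
$H = -\sum_{x} p(x)\log_2 p(x)$ over 256 gray levels on quantized data
(bounded by 8 bits). How color is collapsed for entropy is genuinely
underdetermined in the comparison literature, so both conventions are
available: the default averages the three per-channel entropies; a
grayscale mode first applies the luma weights $(0.299, 0.587, 0.114)$.
`img_mse()` is the mean squared difference over all pixels and channels,
and `img_psnr()` uses the standard squared-peak form
$10\log_{10}\!\left((2^B-1)^2/\mathrm{MSE}\right)$ — the frequently
mis-typeset $20\log_{10}((2^B-1)/\mathrm{MSE})$ form reproduces no
published 8-bit reference value, while the form used here matches
published MSE/PSNR tables to the printed 0.01 dB. Identical images yield
`Inf` rather than an error.

## Synthetic scenes: what they emulate and what they do not

Real reference photographs from tropical reef surveys are not
redistributable, so `make_scene()` / `degrade_scene()` generate paired
clean/degraded scenes that reproduce the *statistical* signature the method
targets: a smooth illumination gradient, textured elliptical "coral/fish"
blobs with distinct hues, and a bright rippled sand band (guaranteeing
bright and dark areas in one frame); degradation applies per-channel
attenuation (default 0.25/0.70/0.85 — red weakest), additive blue-green
veiling light (default RGB 35/140/165 at weight 0.25), contrast
compression about the channel mean (default 0.6), and Gaussian sensor noise
(default SD 2 levels). These defaults represent a few meters of clear
tropical water and give degraded scenes whose red mean is below 0.6 of the
blue mean and whose entropy is below the clean scene's — the two
signature properties the tests assert.

The generator is seeded and bitwise deterministic (layout and noise use
separate derived streams; the caller's RNG state is untouched). It does
**not** model forward/back scatter, depth-dependent attenuation, turbidity
or optics, so passing tests demonstrate that the pipeline removes the
cast/contrast signature it was designed for — not that it is optimal on
arbitrary field imagery.

## Numerical and degenerate-input choices

* Rounding is half-away-from-zero, stated explicitly because R's default
  differs (half-to-even).
* Constant channels (or near-constant S/V planes) cannot be stretched;
  every stage passes them through unchanged with a warning instead of
  erroring, so flat frames never abort a batch.
* Channel-mean ties in the Von Kries step are broken by ranking on
  (mean, then fixed order R < G < B); equal means give identity gains, so
  gray images are fixed points.
* The quantile map's endpoints are pinned algebraically ($u=0 \to 0$,
  $u=1 \to 255$) so floating-point rounding cannot leak outside the range.
* Gains are computed once from the pre-balance image; the correction is
  one-shot, not iterated.

## Problem sizes used in the checks

The packaged checks run on 96×128 scenes (a 20-scene seeded suite for the
behavioral properties), $10^5$ samples for the distributional check, and
≤ 10×10 inputs for the brute-force oracle comparisons. These sizes keep the
whole suite under a few seconds while leaving every property
scale-independent; the pipeline itself is vectorized and handles
full-resolution photographs directly.

## Worked example

```{r example}
spec <- scene_spec(seed = 3)
clean <- make_scene(spec)
degraded <- quantize(degrade_scene(clean, spec))
enhanced <- enhance(degraded)

evaluate_quality(degraded, enhanced)
evaluate_quality(degraded, histogram_equalization(degraded))

c(red_blue_before = mean(degraded[, , 1]) / mean(degraded[, , 3]),
  red_blue_after = mean(enhanced[, , 1]) / mean(enhanced[, , 3]))
```

The enhanced image gains roughly two bits of entropy over its degraded
input while the histogram-equalization baseline loses information on these
scenes, and the red/blue mean ratio moves back toward balance — the
behavior the pipeline exists to produce.

## Known limitations

* The method is global: scenes needing spatially varying correction
  (artificial lighting vignettes, strong backscatter) are out of scope.
* Hue is never corrected; a cast that survives channel-mean balancing
  (e.g. colored artificial light) will survive the pipeline.
* Metrics operate on 8-bit data only; higher bit depths are not supported.
* MSE/PSNR are computed against the *degraded* input (no ground-truth
  alignment is attempted), so they measure departure, not restoration
  accuracy.
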