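# uwie — underwater image enhancement by dual-intensity Rayleigh stretching

Underwater photographs lose red light within the first few meters of depth,
leaving a blue-green cast, a compressed intensity range and washed-out
detail. `uwie` is an R package (with a small command-line wrapper) for
marine-imaging practitioners who need a fast, parameter-light,
histogram-based enhancement of such photographs — no physical
image-formation model, no per-image tuning.

## Method

For an 8-bit RGB image, `enhance()` runs:

1. **Median-referenced Von Kries balancing** — with channel means
   $R_{avg}, G_{avg}, B_{avg}$, the median-mean channel is the reference;
   the weakest channel is multiplied by
   $A = \mathrm{median}/\mathrm{min}$ and the strongest by
   $B = \mathrm{median}/\mathrm{max}$, equalizing all three means without
   the extreme gains a blue-referenced balance would need.
2. **Global min–max stretch** of each channel onto $[0, 255]$:
   $P_{out} = (P_{in} - i_{min})\,(o_{max}-o_{min})/(i_{max}-i_{min}) + o_{min}$.
3. **Mean-split dual Rayleigh stretch** — each channel is split at its
   mean; the lower region $[\min,\mu]$ and upper region $[\mu,\max]$ are
   each mapped onto the full range by the inverse CDF of a Rayleigh
   distribution ($F(x) = 1 - e^{-x^2/2\sigma^2}$, $\sigma = 0.4\cdot255$)
   truncated to $[0,255]$, producing a bright and a dark rendition of the
   scene.
4. **Composition** — the per-pixel average of the bright and dark images.
5. **HSV correction** — saturation and value stretched between their 1st
   and 99th percentiles; hue untouched.

Quality metrics (discrete entropy over 256 gray levels, MSE, and
$\mathrm{PSNR} = 10\log_{10}\!\left(255^2/\mathrm{MSE}\right)$ dB), a
per-channel histogram-equalization baseline, and a seeded synthetic
underwater-scene generator are included, so the whole pipeline is testable
without external data.

## Worked example

```r
library(uwie)

spec     <- scene_spec(seed = 3)                  # synthetic reef scene
clean    <- make_scene(spec)
degraded <- quantize(degrade_scene(clean, spec))  # blue-green, low contrast
enhanced <- enhance(degraded)

evaluate_quality(degraded, enhanced)
#> <quality_report> entropy 7.286 bits | MSE 5381.1 | PSNR 10.82 dB
evaluate_quality(degraded, histogram_equalization(degraded))
#> <quality_report> entropy 5.457 bits | MSE 7066.6 | PSNR 9.64 dB

c(red_blue_before = mean(degraded[,,1]) / mean(degraded[,,3]),
  red_blue_after  = mean(enhanced[,,1]) / mean(enhanced[,,3]))
#> red_blue_before  red_blue_after
#>           0.261           0.885
```

The degraded scene has entropy 5.484 bits; enhancement raises it to 7.286
bits (more recovered detail) while the histogram-equalization baseline
*loses* information (5.457 bits) and leaves a larger departure from the
input (higher MSE, lower PSNR). The red/blue channel-mean ratio moves from
0.26 toward balance at 0.89 — the blue-green cast is largely removed.

## Command line

```sh
UIE=$(Rscript -e 'cat(system.file("cli", "uie.R", package = "uwie"))')
Rscript $UIE enhance reef.png -o reef_enhanced.png --alpha 0.4
Rscript $UIE he reef.png -o reef_he.png
Rscript $UIE metrics reef.png reef_enhanced.png --csv report.csv
Rscript $UIE synth -o scenes/ --n 20 --seed 7
Rscript $UIE batch -o report.csv --n 20 --seed 7 --methods proposed,he
```

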