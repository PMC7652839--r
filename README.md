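# crackseg

Mechanical image segmentation by simulated crack propagation.

`crackseg` segments a target region in a 2-D grayscale image by turning the
segmentation problem into a fracture-mechanics problem — the way a scored
pane of glass breaks along the scribe line. It is aimed at biomedical image
analysts who need to trace boundaries that are blurred or locally invisible
(soft-tissue MR, ultrasound, low-contrast CT), where intensity-driven
methods such as level sets tend to leak through weak edges.

## The method

1. **Image → plate.** The Gaussian-gradient field
   `I_G = |∇G_σ * I|²` is large at intensity boundaries. A negative rescale
   `Î = 1 − (I_G − min)/(max − min)` followed by a power-law (gamma)
   transform `I_M = Î^γ` makes boundaries the *low* values, and the linear
   thickness map `h = (I_M − min)(H − 1)/(max − min) + 1 ∈ [1, H]` turns the
   image into a variable-thickness elastic plate with a **groove** carved
   along the target boundary.
2. **Fracture.** A plane-stress finite-element model (one bilinear quad per
   pixel, element thickness `h`) is loaded by a pair of equal-and-opposite
   force patches near the crack tip, normal to the crack (Mode-I opening),
   ramped linearly from zero. Thin elements concentrate stress, so the
   maximum principal stress `σ₁` first reaches the material strength
   `σ_max` in the groove; the crack then extends one mesh edge, its faces
   are split open (node duplication), the ramp resets, and the cycle
   repeats. Because the tip concentration can drive `σ₁` over the threshold
   even across a few groove-free pixels, the crack bridges short boundary
   gaps; wider blanks stall the front and a second front is started beyond
   the blank, the two being merged afterwards.
3. **Local windows (LCPM).** Rather than fracturing the whole image, the
   simulation runs in small overlapping `(2L+1)²` windows that follow the
   boundary: each window re-enhances contrast locally, inherits the end of
   the previous crack as its initial crack, and the next window centre
   advances a distance `α` along the fitted boundary direction
   `θ = atan(k)` of the current crack. The per-window cracks are merged,
   smoothed and rasterised into the final contour and mask.

Quality is quantified against reference masks with the Dice similarity
coefficient `DSC = 2|A∩B|/(|A|+|B|)`, the symmetric Hausdorff distance, and
the true-negative / false-positive rates (`TNR + FPR = 1`), which measure
boundary overflow.

## Worked example

```r
library(crackseg)

# a 128x128 disk phantom on a textured background, with ground truth
ph  <- gen_phantom(phantom_preset("textured", seed = 3))
ps  <- phantom_seed(ph)          # first window centre + short manual seed

res <- run_lcpm(ph$image, lcpm_config(), center = ps$center, seed = ps$seed)
glance(res)
#> # A tibble: 1 × 7
#>   closed n_points n_windows fronts stalls perimeter  area
#>   <lgl>     <int>     <int>  <int>  <int>     <dbl> <int>
#> 1 TRUE        250        13      1      0      193.  2970

seg_metrics(res$mask, ph$mask)
#> # A tibble: 1 × 4
#>     dsc hausdorff   tnr     fpr
#>   <dbl>     <dbl> <dbl>   <dbl>
#> 1 0.973      2.24 0.989  0.0110
```

The contour closed after 13 local windows with a single front and no
stalls; the segmented mask overlaps the ground truth with Dice 0.973 and a
worst-case boundary error of 2.2 px, and only 1.1 % of the true background
is mislabelled (FPR). `autoplot(res, image = ph$image)` draws the contour
and the window centres over the image; `tidy(res)` returns the contour
points as a tibble.

A command-line interface with `run`, `run-stack`, `synth`, `eval` and
`bench` subcommands is installed under `inst/cli/crackseg.R`.

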