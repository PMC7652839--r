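---
title: "Segmenting images by cracking plates: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting images by cracking plates: model, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crackseg)
```

## The mechanical analogy

A scored glass pane breaks along the scribe line because the groove
concentrates stress. `crackseg` exploits the same physics for image
segmentation: the image gradient is turned into the thickness field of an
elastic plate, so that the target boundary becomes a groove, and a
quasi-static brittle fracture simulation grows a crack along that groove.
The crack polyline, mapped back to pixel coordinates, is the segmentation
contour. The decisive advantage over intensity-evolution methods (e.g.
level sets) is behaviour at weak or interrupted boundaries: a crack tip
concentrates stress, so it can jump a short groove-free stretch and
continue on the far side instead of leaking into the background.

## From intensity to plate thickness

Four deterministic steps build the plate:

* **Gradient.** `gaussian_gradient()` computes `|∇(G_σ * I)|²` using
  derivative-of-Gaussian kernels (the derivative taken as the central
  difference of the sampled Gaussian, so the smooth-then-differentiate
  ordering agrees to round-off; truncation at 4σ, reflect padding).
  `σ` trades noise suppression against edge localisation; default 1.5 px.
* **Negative rescale.** `negative_rescale()` maps the window's gradient
  range affinely onto [0, 1] and inverts it, so the strongest edge becomes
  the global minimum. A constant window has no information; it is flagged
  `degenerate` and the driver treats it as a boundary gap rather than an
  error.
* **Gamma.** `power_transform()` raises the field to `γ` (default 2):
  values near 1 spread apart, values near 0 compress, deepening the groove
  relative to its surroundings. `γ` is the contrast knob for faint
  boundaries; 1.5–3 is the useful range.
* **Thickness.** `thickness_map()` sends the window extremes to exactly 1
  and `H` (default 10). `H` sets the mechanical contrast between groove
  and plate; the crack-onset analysis below explains why ~10 is enough and
  why enormous values buy nothing.

By default the rescale and gamma steps run **per local window**
(`transform_scope = "window"`): a window sees only its own grayscale range,
so a faint local edge is amplified to a full-depth groove no matter how
strong edges elsewhere in the image are. This is the main reason the
windowed method survives inhomogeneous illumination.

## The plate model

Each pixel becomes one bilinear quadrilateral plane-stress element whose
out-of-plane thickness is the mapped height (`build_mesh()`). Under
in-plane load the stress in a membrane scales as force/(width × thickness),
so thin elements concentrate stress exactly as a grooved 3-D plate does at
a fraction of the cost. A plane-stress element carries no through-thickness
bending degrees of freedom, so the model is inherently symmetric — it
behaves like a plate grooved equally on both faces, which removes the
asymmetry a one-sided groove would introduce between the two surfaces.
All four window borders are fully fixed: this removes rigid-body modes for
any crack orientation and approximates the far-field anchoring of the
surrounding image.

The material defaults (Young's modulus 210 GPa, Poisson ratio 0.49,
strength 220 MPa, fracture energy 42 200 J/m²) describe a stiff, nearly
incompressible brittle solid. Only the *ratio* of applied load to strength
matters for crack onset — the load ramp is auto-calibrated — so these
values are conventions, not tuning knobs. The fracture-energy parameter is
accepted for completeness but unused: crack extension here is
instantaneous-brittle rather than governed by a softening law, because the
contour is quantised to pixels anyway and a softening zone below one pixel
cannot change it.

## Crack growth

`propagate_crack()` implements a discrete-crack loop:

1. Split the mesh nodes along the current crack polyline
   (`split_nodes()`): interior vertices are duplicated so the faces can
   separate; the mouth and tip stay shared.
2. Apply a unit pair of equal-and-opposite nodal force patches (radius
   3 px) straddling the crack just behind the tip, normal to the crack
   direction at the tip — Mode-I opening. At pixel resolution "the
   direction at the tip" is the direction of the last few edges, not of the
   final one-pixel segment, so staircase micro-steps do not misalign the
   load.
3. Solve the linear system once. Because the response is exactly linear in
   the load, the whole linear ramp collapses into one number: the onset
   force is `σ_max / σ₁(unit load)` at the critical near-tip element, and
   the discrete ramp answers with the first increment at or above it.
4. If the onset lies within the ramp cap, extend the crack one mesh edge
   and repeat from 1.

**Steering.** Each of the three forward edges is scored by the largest
`σ₁` among the elements it would expose (the elements beside the edge and
around its far node — the far-node ring keeps a groove that crosses the tip
neighbourhood diagonally visible). Three guards make the greedy pixel walk
robust, all consequences of the same observation — stress beside the open
crack faces is bending of the detached strips, not tip concentration, and
must not steer:

* elements *behind* the tip's recent direction of travel are not consulted;
* a move turning more than ~120° against the direction accumulated over
  the last ~10 edges is ruled out (within one window the boundary is
  locally straight, so such a turn is always the parallel-track artefact of
  unzipping a strip beside the crack);
* only groove-adjacent edges (at least one thin neighbour) are extension
  candidates at all — groove-free plate can be crossed only by the explicit
  gap mechanism below.

Exact score ties (a shared critical element) are resolved towards the
valley floor (deepest element beside the new edge), then along the groove
wall rather than through a two-pixel groove band, then towards the
direction perpendicular to the principal stress direction, then straight
ahead. When a move dead-ends, the last extension is retracted and banned
(bounded backtracking); the longest route found is reported.

**Ramp cap and gaps.** The cap is calibrated once per propagation as
`ramp_safety` (default 3) times the seed-configuration onset: large enough
to break the groove anywhere along the window, far below what
full-thickness plate needs (about `H`× more). When the cap is reached
without extension the tip has run out of groove; the tip is then pushed
straight for up to `gap_max` (default 3) pixels — the numerical analogue of
the tip concentration carrying the crack over a scratch-free stretch — and
if the groove does not resume the probe is retracted and the front reports
a stall.

## The windowed driver

`run_lcpm()` iterates `(2L+1)²` windows (default `L = 15`) along the
boundary. Each window inherits the last ~10 crack edges as its initial
crack, and the next centre moves `α` (default `L`, the midpoint of the
admissible `(0, 2L)` overlap range) along the boundary direction obtained
by *orthogonal* (total-least-squares) regression of the window's crack
points — ordinary least squares would blow up on vertical boundaries. The
sign ambiguity of the step is resolved by continuing the previous step
direction. The contour closes when the tip returns within `closure_eps`
(default `α`) of the starting seed after at least three windows; it ends
open at the image border.

A stalled front triggers the wide-gap strategy (`handle_stall()`): the
global gradient is probed along the stalled direction (with a narrow
lateral fan to absorb boundary curvature) for the edge resuming, a second
front is seeded on the strongest gradient ridge there, oriented to continue
the same circulation, and the junction is recorded as a straight bridge.
`merge_and_smooth()` integrates all fragments: near-duplicate points from
window overlaps are dropped, bridges are interpolated at unit spacing, a
moving average (window 5, circular when closed, endpoints pinned when open)
smooths pixel quantisation, and closed contours are oriented
counter-clockwise. Rasterisation uses even-odd scanline fill at pixel
centres with the contour pixels themselves counted as interior, which
biases areas high by about half a pixel times the perimeter — visible in
the area checks, irrelevant at the 1-px contour tolerance.

Seeding the first window is either manual (`manual_initial_crack()`, a
few-pixel polyline on a clear stretch of boundary — the user also supplies
the first window centre) or automatic (`auto_initial_crack()`): a fan of
`m + 1` rays from an apex `N` window-sides away (fan angle
`2·atan(1/(2N))`) collects first hits on a Canny edge map, and the seed is
a short total-least-squares segment through the central hits. All four apex
placements are tried; the one with the most hits wins.

## What the phantoms emulate — and what they do not

`gen_phantom()` builds disks, ellipses and Fourier-perturbed blobs
(harmonics ≤ 5, total radial perturbation ≤ 12 %) with controlled
degradations: linear background ramps, radially inhomogeneous objects,
sinusoidal/checker texture, additive Gaussian noise, and boundary gaps.
Gaps blend the object into the background across an angular arc (with an
8° raised-cosine taper on each side so the nominal arc is fully erased —
the ground-truth mask is untouched, only visibility is). Default contrasts
(object 0.30 vs background 0.70, texture amplitude 0.06, noise σ 0.03–0.04)
are in the range of reasonably-windowed clinical images.

Passing on these phantoms demonstrates boundary tracking under intensity
inhomogeneity, texture, noise and interrupted edges. It does *not*
demonstrate robustness to modality-specific physics (ultrasound speckle,
bias fields, partial-volume effects), to neighbouring structures with
stronger edges a window-width away, or to concave shapes with deep
invaginations — the convexity-ish assumption enters through the local
straightness of windows and the closure rule.

## Numerical choices and problem sizes

* Windows are `2L+1` pixels (the Chebyshev ball of radius `L`), clamped —
  not mirrored — at image borders, since mirrored intensities would
  fabricate grooves.
* Degenerate (information-free) windows are flagged and handled as gaps,
  not errors.
* The closure bridge and gap bridges are straight segments; with `α = 15`
  the worst closure chord subtends a sagitta under 1.5 px on the shapes
  used here.
* Determinism: there is no hidden randomness anywhere in the pipeline;
  phantoms and spline grooves are seeded explicitly, and reruns are
  bit-identical.
* The bundled tests exercise 31×31-element windows (≈ 2 000 degrees of
  freedom per solve, a few hundred solves per full segmentation) and
  128×128 images; a full phantom segmentation takes a few seconds. The
  acceptance script uses 12 segmentation runs and 8 groove-plate
  propagations, chosen to give stable means while keeping a full
  reproduction under a few minutes.

## Known limitations

* Per-pixel cracking limits accuracy to about one pixel; sub-pixel
  boundary localisation is out of scope.
* The ramp-cap window between "breaks the groove" and "cuts virgin plate"
  narrows for very shallow grooves (`H` close to 1) or extremely jagged
  boundaries; the defaults hold a comfortable margin on the regimes
  tested.
* Only one region is segmented per run; multi-object images need one run
  per object.
* The one-sided versus two-sided plate comparison that motivates the
  symmetric model cannot be reproduced in a plane-stress reduction — the
  reduction simply has no through-thickness dimension; this is a feature
  (the asymmetry problem cannot occur) but also means that particular
  3-D effect is not simulated.
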