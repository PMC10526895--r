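---
title: "High-density perimetry: models, estimation and the adaptive boundary search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-density perimetry: models, estimation and the adaptive boundary search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdperim)
library(dplyr)
```

## The problem

Static automated perimetry estimates contrast thresholds at a sparse grid
of visual-field locations. Small defects — angioscotomas, the roughly
half-degree-wide and ~0.3 log-unit-deep sensitivity depressions in the
shadows of retinal vessels — slip between grid points, and even dense
grids blur them because fixational eye movements of similar magnitude
scatter the retinal landing positions of nominally identical stimuli.
This package implements a complete computational pipeline for studying
that problem on a 13° × 19° patch of a right eye's field around the optic
nerve head (11–17° temporal, −3 to +6° vertical; temporal = +x,
superior = +y, all positions in one field-space frame): dense ZEST
thresholding, eye-position-based trial filtering, three displays of the
results, and an adaptive search that looks for scotoma *boundaries*
instead of thresholds. A synthetic observer with known ground truth makes
every step testable.

## The psychometric model

All detection behaviour runs through Quick's form of the Weibull
frequency-of-seeing curve with guess and lapse rates:

$$\Psi(c) = \gamma + (1-\gamma-\lambda)\left(1 - 2^{-(C/A)^\beta}\right),
\qquad C = 10^{c},\; A = 10^{\alpha},$$

where $c$ is stimulus contrast in log10 Weber units, $\alpha$ the
threshold, $\beta$ the slope, $\gamma$ the false-positive rate and
$\lambda$ the false-negative rate. With $\gamma = \lambda$ the curve
passes through exactly 0.5 at $c = \alpha$: threshold is the contrast seen
half the time. Both rates default to 0.02 wherever curves are fitted. An
absolute scotoma is represented by $\alpha = +\infty$, which collapses
$\Psi$ to $\gamma$ at any contrast the device can produce.

```{r psi}
p <- psychometric_params(alpha = -0.35, beta = 3.5)
detection_probability(p, -0.35)
```

## Geometry and the contrast ladder

The test grid is the full Cartesian product of two inclusive ranges
(13 columns × 19 rows = 247 locations at 0.5° spacing), ordered row-major
for reproducible sequencing. The contrast ladder holds 74 levels from
−0.9 to +0.6 log units; its linear maximum, $10^{0.6} \approx 3.98$,
respects the device ceiling of 400% Weber contrast (an 80 cd/m² increment
on a 20 cd/m² background). The exact level placement of the original
testing device is not published; the default places levels uniformly on
the *linear* contrast scale between the endpoints, which reproduces a
non-uniform log spacing with a median step near 0.02 log units, and a
uniform-log option is available. Real sessions were run in blocks of
coarser (2°) grids interleaved to the 0.5° grid; since the exact
partition into 8 blocks cannot be reconstructed, block assignment here is
a deterministic offset labelling and nothing downstream depends on it.

```{r grid}
nrow(build_grid(11, 17, -3, 6, 0.5))
range(10^as.numeric(build_ladder()))
```

## ZEST

Each location runs an independent ZEST track: a probability mass function
over the ladder levels as candidate thresholds, multiplied after each
response by the likelihood of that response under $\Psi$ with the
candidate as threshold, then renormalised. Choices that the original
procedure leaves open are fixed as follows, each configurable:

- **Prior**: uniform over the ladder (a broad Gaussian option exists).
  With six presentations the posterior mean is dominated by the data well
  before the prior shape matters.
- **Update likelihood slope**: $\beta = 3.5$, a mid-range perimetric
  slope; $\gamma = \lambda = 0.02$.
- **Stimulus placement**: the posterior mean snapped to the nearest
  ladder level, exact ties broken toward the lower contrast, making the
  procedure fully deterministic given the responses (posterior mode is
  available as an option).
- **Termination**: exactly six presentations per location, so the default
  grid yields 1,482 threshold trials; the estimate is the posterior mean.
- **Catch trials**: blank (false-positive) and maximum-contrast
  (false-negative) probes can be interleaved at configurable per-trial
  rates, reported separately; they default to off because the published
  assessment procedure is not specified.
- Timing (60 ms stimulus, 1200 ms mean inter-stimulus interval) is
  carried as metadata for the eye-movement simulator, not enforced.

Under the default settings, 500 simulated six-presentation runs per true
threshold across the working range recover thresholds with mean absolute
error around 0.08–0.11 log units and bias below 0.04 (see
`test-acceptance.R`); the sequential update is verified against a
brute-force Bayes product on small domains.

## Eye-position filtering

Three fundus frames register eye position per presentation (two during
the 60 ms stimulus, one after; one frame per 40 ms). Displacements arrive
in camera pixels and convert at 1.64 arc min (0.027°) per pixel. The
trial displacement is the per-axis median over the three frames; the
stimulus is inferred to land at nominal + displacement (the sign
convention is a package choice — the original work does not state one —
and is pinned by a round-trip test). A trial is excluded when

1. any frame is missing (blink, or optic disc out of image);
2. displacement varies by more than 0.5° among the three frames
   (interpreted per axis as max − min; a Euclidean-diameter option
   exists, since the original rule's metric is not stated); or
3. any frame is shifted more than 1° from the reference (also per axis).

The excluded *set* is order-independent; only the reported reason label
follows the order above. At the fixational statistics used here
(microsaccades at 0.8/s make one land in ~9.6% ≈ 10% of 120 ms windows)
simulated sessions lose roughly 6–16% of trials, the range observed in
practice.

## The three displays

**Conventional map.** Sensitivity in log units is the reciprocal of
threshold contrast, $-\hat\alpha$, plotted at nominal locations with no
interpolation; missing locations are flagged, never dropped. Rendering
clamps to the −0.5…1.0 log-unit relative range with a diverging palette.

**Local maximum-likelihood map.** At every point of a fine lattice
(0.05° spacing over the same extents: 21,901 points), all valid trials
whose *inferred* location falls within 0.5° contribute to a weighted ML
fit of $(\alpha, \beta)$ with $\gamma = \lambda = 0.02$ fixed, each trial
weighted by a Gaussian kernel of its distance (SD 0.5°, so weight
$e^{-1/2} \approx 0.61$ at the cutoff — the kernel is truncated at the
inclusion radius exactly as specified, discontinuity and all).
Numerically the fit is a bounded L-BFGS-B search ($\alpha$ within the
ladder extent ±0.3, $\beta \in [0.5, 20]$) from four deterministic
starting points with a coarse grid fallback; fewer than 4 trials in
radius, non-convergence, or an $\alpha$ pinned at its bounds yield an
undefined or flagged fit rather than an error. One-sided data (e.g. an
all-seen neighbourhood) has no crossing information, and the flagged
boundary fit makes that explicit. Because of the 0.5° pooling radius,
recovered depressions are wider and shallower than the truth — a known
property of the display, not a defect of the fit.

**Slice display.** At display threshold $C_0$, a trial is *crossover*
when contrast $< C_0$ yet seen, or contrast $\geq C_0$ yet not seen
(strict and inclusive exactly so); everything else is *concordant*. The
three subsets partition the valid trials. The sweep runs $C_0$ from 0.5
down to −0.5 log units in −0.01 steps (101 frames); as $C_0$ falls the
crossover-seen count is non-increasing and the crossover-not-seen count
non-decreasing, by set containment. The two-contrast principle follows:
for a 0.3 log-unit step scotoma with steep slopes, seen trials at the
normal threshold mark normal regions and not-seen trials at a contrast
0.3 higher mark the scotoma, each with high spatial precision. In the
test suite the seen-side slice is taken one sweep step (0.01 log units)
above the normal threshold, since the strict inequality makes the slice
*at* the threshold empty on that side. Selecting $C_0$ was a visual
judgement in the original work; `suggest_display_threshold()` offers an
optional, unvalidated clustering heuristic and nothing in the package
depends on it.

## The wave search

The adaptive simulator assumes the regional sensitivity is already known
(it drives a simulated observer from a fitted map or ground-truth
surface), fixes one stimulus contrast, and searches outward from the
blind-spot centre — the algorithm is deliberately blind-spot-specific.
Locations lie on circles in 0.5° radius steps with approximately 1°
along-circle spacing, concretely $n = \max(4, \mathrm{round}(2\pi
r/1°))$ points starting at angle 0 with no stagger, a determinism
choice. Wave 1 tests the whole innermost circle (two presentations per
location). Each later wave adds the next circle and repeatedly opens any
untested generated location that is a Voronoi neighbour of a tested
location with at least one miss — which covers both the next circle
beyond misses and same-circle gaps next to fresh misses — until nothing
opens; a location adjacent to both a missing and a fully-seen location is
opened (any miss suffices). The run ends `edges_closed` when a wave tests
nothing new (every boundary location was seen twice), or `out_of_range`
if it reached the test-area boundary. An opened location outside the
area cannot be tested: it is flagged and skipped while the search
continues elsewhere, so a blind spot that crosses the area edge (as the
default synthetic subject's does) is still traced along its in-area
boundary; halting at the first out-of-area opening would abandon the
search after a few dozen locations, inconsistent with the low-hundreds
location counts this procedure is meant to achieve.

Voronoi adjacency is computed directly: each point's cell is the
intersection of bisector half-planes clipped to a bounding box
(Sutherland–Hodgman clipping with a nearest-first scan and an exact
pruning bound), and two points are neighbours iff their cells share an
edge of positive length — cells meeting only at a vertex, as in the
cocircular square tie, are not neighbours. The implementation is checked
in the tests against a frozen adjacency computed by an independent
computational-geometry library. For the search, the bounding box is the
generated points' padded extent rather than the test area itself, since
candidate circles legitimately extend past the area edge before the
out-of-range bookkeeping sees them; within the area the two choices
agree except for cells touching the box edge, which the opening rule
never reaches before termination.

On the default synthetic subject at a contrast midway between the normal
and vessel-elevated thresholds (−0.2 for a −0.35 baseline), runs test
roughly 80–110 locations — far below the 247-location exhaustive grid
and in line with practice — and every location missed on both
presentations lies where the true threshold exceeds the stimulus
contrast.

## The synthetic observer

`sensitivity_surface()` is baseline threshold (default −0.35 log units,
chosen to sit inside the range of display thresholds used in practice,
−0.50…−0.15) plus vessel depressions plus a blind-spot mask. Vessels are
polylines with a Gaussian cross-section of scale width/2 (default width
0.5°, depth 0.3 log units, so the full width matches the approximate
vessel width; a rectangular profile is an option). The blind spot is an
ellipse (default centre (15°, 1.5°), semi-axes 2.5° × 3.5°) inside which
nothing is seen. The slope field is a uniform $\beta = 3.5$.

The eye-movement model draws one drift per trial (Gaussian, SD 0.15°
per axis, constant across the three frames), microsaccades at 0.8/s
(linear rate × window probability per 120 ms window, the same
approximation used for the 10% figure) that shift the later frames by a
Gaussian amplitude (SD 0.4° per axis), and blinks that blank one frame
(default 5% of trials). Responses are drawn at the *displaced* retinal
location from the surface's local curve; frames are encoded back to
pixels with 0.5 px registration noise. Tying the microsaccade event to
inter-frame disagreement is what makes the generator exercise the 0.5°
jitter rule; the model has no main-sequence dynamics, no within-trial
drift, no optics, and a uniform slope field, so passing tests show the
pipeline's statistical machinery is correct, not that real eyes behave
this way. Identical seeds give byte-identical session CSVs.

## Problem sizes and numerical choices

The full-resolution published analysis (21,901 lattice fits) is
supported but the test suite and examples run reduced versions chosen as
sensible working sizes: flat-field recovery uses a 7 × 7-location grid
with a 0.25° lattice; vessel localisation fits 0.1°-spaced
cross-sections of the full 247-location session; ZEST recovery uses 500
runs per condition. Tolerances follow from the design: grid divisibility
uses a 1e-9 relative tolerance, pdf normalisation 1e-9, Voronoi edge
lengths 1e-9 with a both-cells confirmation guard, and ties in ZEST
stimulus snapping resolve to the lower contrast. Degenerate inputs
(empty domains, collinear or duplicate points, empty neighbourhoods,
all-seen neighbourhoods) return flagged values or named errors, never
crashes.

## Limitations

- The gaze filter consumes displacement tables; optic-disc localisation
  and image registration are upstream and out of scope.
- The ML map inherits the 0.5° smoothing of its definition: depressions
  are spatially exaggerated and depth-attenuated.
- The wave search is specific to a single deep scotoma with a known
  centre; it is not a general scotoma finder.
- The per-axis reading of the 0.5°/1° exclusion rules and the
  displacement sign convention are package choices among readings the
  original description leaves open; both are configurable or pinned by
  tests.
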