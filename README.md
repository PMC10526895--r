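# hdperim

Simulation and analysis of **high-density static perimetry** over a small
region of the visual field — the optic-nerve-head neighbourhood of a right
eye — aimed at a question that conventional perimetry handles poorly: how do
you locate *small, shallow* scotomas (such as angioscotomas, the shadows of
retinal blood vessels) without measuring a full threshold map at hundreds of
closely spaced locations?

The package is written for visual psychophysicists and perimetry-algorithm
developers. It provides, as composable tidyverse-style functions over trial
tables:

- **Test geometry** — a 0.5°-spaced rectangular grid of 247 locations
  spanning 11–17° temporally and −3 to +6° vertically, a 74-level contrast
  ladder from −0.9 to +0.6 log₁₀ Weber contrast, and fine estimation
  lattices (0.05° spacing).
- **ZEST adaptive thresholding** — Bayesian threshold estimation with a
  probability mass over the ladder, six presentations per location, and the
  Quick–Weibull frequency-of-seeing likelihood
  Ψ(c) = γ + (1 − γ − λ)(1 − 2^(−(C/A)^β)), with C = 10^c, A = 10^α, so
  that Ψ(α) = 0.5 when γ = λ (threshold is the contrast seen half the
  time).
- **Eye-position trial filtering** — per-trial eye displacement from three
  fundus-image frames (1.64 arc min/pixel, frames every 40 ms), median
  displacement per axis, and the exclusion rules: any frame obscured by a
  blink, displacement varying by more than 0.5° among the three frames, or
  any frame shifted more than 1° from the reference.
- **Three result displays** — the conventional sensitivity map
  (sensitivity = −threshold in log units), a locally weighted
  maximum-likelihood threshold map (all presentations within 0.5° of each
  estimation point, Gaussian distance weights with SD 0.5°, γ = λ = 0.02),
  and the **slice display**: at a display threshold C₀, show only the
  *crossover* trials — seen below C₀, or not seen at or above C₀ — and
  sweep C₀ from 0.5 to −0.5 log units in 0.01 steps.
- **Wave-based scotoma-boundary search** — an adaptive simulator that tests
  locations on circles of increasing radius (0.5° steps, ~1° along-circle
  spacing) from the blind-spot centre, two presentations per location,
  expanding only toward Voronoi neighbours of locations with at least one
  miss, until the boundary closes or the test-area edge is reached.
- **A synthetic observer** — ground-truth sensitivity surfaces with a deep
  elliptical blind spot and narrow (0.5°) shallow (0.3 log-unit) vessel
  shadows, plus full session simulation with fixational drift,
  microsaccades (0.8/s, so ~10% of 120 ms frame windows) and blinks — so
  every analysis above can be validated against known truth.

## Worked example

```r
library(hdperim)
library(dplyr)

subject  <- make_paper_like_subject(seed = 1)   # blind spot + 2 vessels
session  <- simulate_session(subject, seed = 7) # 247 locations x 6 trials
filtered <- filter_session(session$trials, session$gaze)
glance(filtered)
#>   n_trials n_excluded excluded_fraction
#> 1     1482        120            0.0810

# local weighted ML fit on a vessel shadow (true centreline passes nearby)
valid <- filter(tidy(filtered), valid)
weighted_ml_fit(valid, x_deg = 12, y_deg = -1)
#>   x_deg y_deg alpha_log  beta sensitivity_log n_trials_in_radius fit_status
#> 1    12    -1   -0.0182  14.9          0.0182                 14 ok

# slice display at the baseline threshold
sel <- slice_select(valid, display_threshold = -0.35)
table(sel$subset)
#>    crossover_seen crossover_notseen        concordant
#>                52               670               640

# adaptive boundary search from the blind-spot centre
search <- run_wave_search(
  wave_search_config(center_x = 15, center_y = 1.5, contrast = -0.2),
  simulated_observer_from_map(subject), seed = 7)
glance(search)
#>   status       n_locations_tested n_presentations n_waves
#> 1 out_of_range                 95             190      11
```

Reading the numbers: 8.1% of trials are excluded by the eye-position rules
(blinks, frame jitter over 0.5°, shifts over 1°). The local fit at (12°,
−1°) — on a simulated vessel shadow — returns a threshold of −0.02 log
units against a background of −0.35, i.e. a ~0.33 log-unit local
depression, recovering the generated 0.3 log-unit angioscotoma. The wave
search covers the blind-spot boundary with 95 tested locations (190
presentations) instead of the 247 × 6 = 1,482 trials of exhaustive
thresholding; it ends `out_of_range` because this subject's blind spot
extends past the temporal edge of the 13° × 19° test area.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
display; `run_pipeline(config, out_dir)` runs the whole chain (fixture →
ZEST → gaze filter → maps → sweep → wave search) from one config and seed,
and `inst/cli/hdperim.R` exposes the same steps as shell subcommands.

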