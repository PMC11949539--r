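---
title: "Deciding when a presence/absence sampling effort is sufficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding when a presence/absence sampling effort is sufficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevstab)
```

## The problem

Occurrence and prevalence rates — the proportion of sampled units in which
a species is present — underpin much of community ecology, parasitology and
disease ecology. Collecting the presence/absence records is often the
expensive part: field time, funds, diving hours and elusive species all
limit how many host colonies, quadrats or habitats can be scored. The
question this package answers is not *what is the prevalence* but *have I
sampled enough for my prevalence estimate to be trustworthy* — and if so,
what was the minimum sufficient effort.

The input is a wide table with one row per sampled unit: a grouping label
(host species, site, habitat) in one column and a binary presence (1) /
absence (0) entry per target species in the rest. Cells may be empty where
a unit was not scored for a species; each group/species pair therefore has
its own number of scored units, `k_max`.

## The prevalence accumulation curve

For a single group/species pair with `k_max` scored units, the package
draws, for every sample size `k = 1 .. k_max`, a uniform random subset of
`k` units *without replacement* and records its prevalence (in percent).
Averaging over `n_replicates` replicates (default 50) yields the mean
curve `m(k)`. Under simple random sampling without replacement the
subsample proportion is hypergeometric, so `m(k)` is an unbiased estimate
of the full-sample prevalence at every `k`, and at `k = k_max` the
subsample *is* the sample: `m(k_max)` equals the observed prevalence
exactly (the package sets this value directly rather than trusting
floating-point summation).

Replicates are generated by **nested accumulation**: each replicate is a
random permutation of the scored units and the size-`k` subsample is its
first `k` elements, exactly as effort accumulates in the field — a new
sample extends the previous ones. Every `m(k)` therefore still averages
`n_replicates` exact SRSWOR draws, but successive curve values within a
replicate are strongly and positively correlated: adding one unit to a
size-`k` sample changes its proportion by at most `1/k`, so the successive
differences of the mean curve shrink like `1/k`. This geometry is what the
detector's default thresholds are calibrated for, and it is also what
makes the analysis fast (one permutation yields the whole curve). An
`mode = "independent"` alternative draws a fresh subsample at every `k`;
the marginal distribution of each `m(k)` is identical, but successive
differences then shrink only like `1/sqrt(k)` — the same rate at which the
corrected threshold shrinks — so the windowed criterion essentially never
triggers at the default settings. Independent mode is provided for
methodological comparison, not routine use.

## The stability point

The curve is scanned for the first window of `x = successive_points`
consecutive means (default 10) that is flat in two senses, both strict:

1. every successive difference inside the window satisfies
   `|m(k) − m(k−1)| < y / sqrt(k)`, with `y = mean_diff_threshold`
   (default 2 percentage points). The `sqrt(k)` correction compensates for
   the systematic shrinking of the differences with sample size; `k` is
   the later member of each pair (an `correction_index = "earlier"` switch
   implements the other reading — the two differ negligibly);
2. the range of the window means, `Δ = max − min`, satisfies
   `Δ < z` with `z = delta_threshold` (default 1 percentage point),
   uncorrected.

Ties at either threshold fail; the comparisons are deliberately strict so
that tightening a threshold can never advance the stability point — the
detector is provably monotone in `x`, `y` and `z` (tested as properties).

**Reporting convention.** The package reports the stability point as the
*last* sample size of the first qualifying window (`point =
"window_end"`): the effort by which the curve has demonstrably been stable
for `x` successive sizes. We regard this as the natural operational answer
to "how many samples do I need" — one cannot certify a flat window of 10
means with fewer than 10 samples past its start — and it is the convention
under which our simulation benchmarks below reproduce. A constant curve
therefore stabilises at `x`, not at 1. `point = "window_start"` reports
the first window mean instead; a `window_unit = "differences"` switch
makes the window span `x` successive differences (`x + 1` means) for users
who read the window length as counting differences. The estimated
prevalence reported is the curve value at the stability point, with the
full-sample (tail) prevalence always given alongside; displayed values are
rounded to one decimal half-away-from-zero, internal values never.

If the curve is shorter than the window, or no window qualifies, the
verdict is `na`: the effort conducted does not yet support a stable
estimate. This is a result, not an error — it is precisely the "sample
more" signal the tool exists to give.

All prevalence quantities are on the percent scale; the defaults `y = 2`
and `z = 1` are percentage points and are only meaningful on that scale.

## Reproducibility

Every analysis accepts a seed. A table-wide scan derives an independent
sub-stream per group/species pair by hashing the pair's labels together
with the seed, so adding or dropping a species column never changes the
other pairs' results; simulation grids derive one child stream per cell.
RNG state of the calling session is saved and restored around every seeded
computation.

## The simulation harness

Because the detector is a heuristic, the package ships the validation
study it was assessed with, as first-class seeded functions:

* `run_default_grid()` crosses population sizes 100 / 1000 / 10000 with
  true prevalences 10–90 % (step 10 %) and replicate counts 10–100 (step
  10) plus 200 and 500 — 324 cells, each a full estimator run on a
  synthetic population containing exactly `round(N·p)` presences
  (`k_max = N`: the validation hands the estimator the whole population).
* `run_parameter_sweep()` crosses `x ∈ {2, 10, 50}`,
  `y ∈ {1, 2, 5, 10}` and `z ∈ {0.5, 1, 2}` on the focal population
  (N = 1000, p = 50 %, n = 50), quantifying how stringency drives the
  required effort.
* `repeat_runs()` re-runs one configuration many times to expose the
  run-to-run spread of the stability point; `expected_se()` gives the
  closed-form SRSWOR standard error
  `100·sqrt(p(1−p)/k · (N−k)/(N−1))` used as the variance oracle.

At the defaults the grid's grand mean stability point is ≈ 30 samples,
falling to ≈ 21 at extreme prevalences (10 or 90 %) and rising to ≈ 35–38
at mid prevalences (40–60 %) — mid-range prevalences are intrinsically
hardest because the binomial-type variance `p(1−p)` peaks at 50 %. The
focal repeat-run experiment (N = 1000, p = 50 %, 10 runs) gives a mean of
roughly 35–39 with an sd near 9: a single run can easily land 10 samples
from the long-run mean. **Run the analysis at least five times** (the
`cmd_estimate()` driver defaults to `runs = 5`) and use the aggregate;
its recommended sample size is the across-run mean rounded *up*, a
deliberately conservative choice against under-sampling. The estimated
prevalence at the stability point sits within about one percentage point
of the truth for the median grid cell. A handful of grid cells
(small population, 10 replicates, mid prevalence) occasionally return
`na` — the curve honestly fails to flatten within 100 units — so grid
summaries average over determined cells.

These simulation sizes (324 cells, 10–100 repeat runs, a few thousand
Monte-Carlo draws for the oracles) are the package's chosen desk-scale
study conditions: large enough for the stochastic tolerances quoted above,
small enough to run in seconds on one core thanks to the nested
(permutation-prefix) resampling.

## The packaged example, and what the tests do not show

`coral_example_path()` points to a **synthetic** coral-symbiont survey
(six host groups including one coral split across two depths, six
symbiont columns, nine scored pairs) whose group sizes and observed
prevalences emulate a real Caribbean survey: a well-sampled hydrocoral
(104 colonies, three symbionts around 19–24 % prevalence, all stabilising
comfortably below the available effort) and an under-sampled host
(35 colonies whose fanworm column, scored on 18 colonies at mid
prevalence, structurally cannot complete a stability window — the `na`
verdict). It exercises every front-end path: per-symbiont `k_max`,
missing cells, the panel figure with its dotted stability lines, shared
lines for coincident stability points and `na` annotations.

The synthetic generators sample units independently with a fixed true
prevalence. Real surveys violate this in ways the tests therefore cannot
vouch for: spatial and temporal autocorrelation between neighbouring
colonies, observer-dependent detection (a present symbiont scored absent),
and prevalences that drift across the sampling window. The stability
point certifies internal convergence of the estimate under exchangeable
resampling of *your* data — it cannot repair a biased or non-stationary
sampling design, and it determines sufficiency for the sampled group at
the sampled place and time only.

## Known limitations

* Presence/absence only; no abundance, no occupancy-style detection
  model, no confidence intervals on the prevalence itself.
* The verdict is stochastic near the boundary: a pair whose true
  stabilisation effort is close to `k_max` can return a number in one run
  and `na` in the next — which is exactly why the multi-run protocol and
  the majority-`na` "insufficient" verdict exist.
* Thresholds are absolute (percentage points); for very rare species a
  2-point mean-difference tolerance may be loose relative to the
  prevalence being estimated.
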