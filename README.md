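# prevstab

**Is your presence/absence sampling effort sufficient to estimate a
species' occurrence or prevalence rate — and what was the minimum effort
that would have sufficed?**

Field surveys of species occurrence (hosts scored for symbionts, habitats
scored for a focal species) are routinely cut short by time, funding,
weather or elusive taxa. `prevstab` answers the question a field ecologist
actually faces at the end of a campaign: whether the `k_max` units scored
so far already pin down the prevalence rate, or whether a particular
taxon is still under-sampled.

## Method in brief

For each group/species pair the package builds a *prevalence accumulation
curve*: for every sample size `k = 1..k_max` it draws a uniform subsample
of `k` units without replacement (SRSWOR, so subsample proportions are
hypergeometric and unbiased), and averages the subsample prevalence over
`n` replicates (default 50). Replicates are nested permutations — each
replicate grows the way real sampling effort grows — so the mean curve
`m(k)` flattens as `1/k`.

The *stability point* is detected from the first window of `x` successive
means (default 10) that is flat in two strict senses:

* every successive difference obeys `|m(k) − m(k−1)| < y / √k`
  (default `y = 2` percentage points; the `√k` factor corrects for the
  shrinking scale of the differences), and
* the window range obeys `Δ = max − min < z` (default `z = 1`).

The reported stability point is the last sample size of that window — the
effort by which the curve has demonstrably been stable for `x` successive
sizes — together with the prevalence estimated there. If no window
qualifies within the data, the verdict is `na`: sample more. Because the
procedure is stochastic, the driver repeats it (default 5 runs) and
recommends the across-run mean rounded up.

## Worked example

The package ships a synthetic coral–symbiont survey
(`coral_example_path()`): six host groups, six symbiont species, nine
scored host–symbiont pairs.

```r
library(prevstab)

tab <- read_occurrence_csv(coral_example_path())
scan <- estimate_all(tab, stability_params(seed = 1))
scan
#> Stability scan: 9 group/species pair(s), nested resampling
#>                    group                    species k_max stability_point
#>         Acropora palmata       Domecia acanthophora    35              35
#>         Acropora palmata    Spirobranchus polycerus    18              na
#>      Agaricia agaricites     Opecarcinus hypostegus    60              32
#>        Agaricia lamarcki     Opecarcinus hypostegus    44              31
#>     Millepora complanata       Domecia acanthophora   104              37
#>     Millepora complanata        Megabalanus stultus   104              17
#>     Millepora complanata   Acanthemblemaria spinosa   104              32
#>   Orbicella faveolata 6m Troglocarcinus corallicola    50              na
#>  Orbicella faveolata 15m Troglocarcinus corallicola    52              27
#>  estimated_prevalence tail_prevalence
#>                  34.3            34.3
#>                  <NA>            44.4
#>                  44.0            45.0
#>                  70.6            70.5
#>                  19.1            19.2
#>                  24.0            24.0
#>                  22.3            21.2
#>                  <NA>            36.0
#>                  21.8            21.2
```

Reading this: the 104 *Millepora complanata* colonies were ample — its
three symbionts stabilise after 17–37 samples at prevalences of
19.1–24.0 %. The fanworm *Spirobranchus polycerus* on *Acropora palmata*
returns `na`: 18 scored colonies cannot complete a 10-point stability
window, so that prevalence (44.4 % in hand) is not yet trustworthy.
`plot_panels(scan, "panels.png")` renders one panel per host with the
curves, dotted stability lines, per-curve prevalence labels and `na`
marks. Because single runs wobble, use the multi-run driver for real
decisions:

```r
cmd_estimate(coral_example_path(), "results/", runs = 5, seed = 1)
```

which writes five per-run CSVs, an aggregate with a recommended sample
size per pair (mean stability point rounded up, `"insufficient"` verdict
when most runs return `na`), the panel figure and a log.

The simulation harness that validates the detector is exported too:

```r
repeat_runs(1000, 0.5, runs = 10, seed = 1)
#> Repeat-run summary (N = 1000, true prevalence = 50%, 10 runs)
#>   stability point: mean 37.1 ± sd 9.9
```

so a population of 1000 with 50 % prevalence needs about 37 samples on
average — but individual runs ranged widely, which is exactly why the
≥ 5-run protocol exists. `run_default_grid()` sweeps 324
size × prevalence × replicate combinations (seconds on one core) and
shows mid-range prevalences are hardest: ~35–38 samples at 40–60 %
prevalence versus ~21 at 10 or 90 %.

## Command line

```sh
Rscript inst/scripts/prevstab.R estimate --input survey.csv --out results \
        --runs 5 --seed 1
Rscript inst/scripts/prevstab.R simulate --config sim.yaml --out results
```

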