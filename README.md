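# swidcarbon

Carbon stocks and REDD+ management scenarios in shifting-cultivation
landscapes.

Shifting cultivation (swidden) rotates forest clearing, brief cropping and
fallow regeneration across a landscape mosaic. Whether carbon-payment
schemes such as REDD+ should shorten rotations, spare old fallows, or
protect old-growth forest depends on two quantities this package
estimates: how much aboveground carbon a plot holds, and how fast
secondary forest recovers it. swidcarbon is aimed at landscape ecologists
and forest-carbon analysts who have (or want to simulate) stem/liana/
deadwood/litter inventories from 10 × 30 m plots.

The package provides, end to end:

1. **Allometry** — plot-level carbon pools from inventory records: tree
   biomass as the ensemble mean over height-free allometric equations
   `B = a(ρD²)^b` or `ln B = c0 + c1 ln D + c2 (ln D)² + c3 ln ρ`, liana
   equations, frustum/cone deadwood volumes times decay-class densities,
   litter subsample scaling; composite-plot area factors; carbon fraction
   0.474; Mg/plot (0.03 ha) and Mg/ha scales.
2. **Recovery model** — linear mixed models of log₁₀ carbon with
   square-in-landscape random intercepts (ML), AICc all-subset ranking
   (`AICc = AIC + 2k(k+1)/(n−k−1)`), Nakagawa marginal/conditional R²,
   growth-curve prediction with parameter-uncertainty draws truncated to
   the joint 95% confidence ellipse, and a Moran's I diagnostic.
3. **Scenario engine** — a 30-parcel (1 ha each) landscape Monte Carlo:
   equal-area cultivation cycles of 5/10/15/30 yr, fallow sparing,
   old-growth sparing, 1,000 draws per scenario, totals in Mg/30 ha, plus
   analytic helpers (`sparing_mixture()`, `relative_change()`) and
   sensitivity samplers (median / literature old-growth values).
4. **Synthetic data** — a generator calibrated to published summaries
   (old-growth 441.4 ± 60 Mg/ha; log₁₀-linear recovery slope 0.04/yr
   anchored at 248 Mg/ha at age 29) plus an inventory inverter, so the
   whole pipeline is testable without field data.

## Worked example

```r
library(swidcarbon)

inv  <- generate_inventory(default_params(), seed = 1)  # synthetic inventory
ptab <- plot_carbon_table(inv$dataset, read_equation_registry(),
                          read_decay_density())
fit  <- fit_model(ptab, "total", fixed = "fallow_age")
fit
#> log10-carbon model (total carbon), n = 55, AICc = 31.87 [singular random effects]
#> (Intercept)  fallow_age
#>      1.2850      0.0339
#> residual SD 0.2811; random-intercept variances: square:landscape 0.006452, landscape 0
```

The fitted fallow-age slope 0.0339 log₁₀(Mg/ha)/yr is this synthetic
draw's estimate of the generating slope 0.04: secondary-forest carbon
rises about 8% per fallow year. Simulating management scenarios from the
fitted curve and the observed farmland/old-growth plot pools:

```r
samplers <- list(
  farmland   = make_empirical_sampler(ptab$total_carbon[ptab$habitat == "farmland"]),
  old_growth = make_empirical_sampler(ptab$total_carbon[ptab$habitat == "old_growth"]),
  fallow     = make_model_sampler(fit))
simulate_scenarios(c("baseline", "OF", "1.3", "2.3", "3.3"),
                   samplers, n_sims = 1000, seed = 2)
#>         id    mean    sd
#> 1 baseline  2244.1  61.8   # 30-yr cycle
#> 2       OF 13500.0 353.7   # all old-growth
#> 3      1.3   650.5  24.3   # cycle shortened to 5 yr
#> 4      2.3  5167.6 167.5   # 83% spared as permanent secondary forest
#> 5      3.3 11351.3 323.9   # 83% spared as old-growth
```

Means are Mg per 30-ha landscape over 1,000 Monte Carlo draws. Shortening
the cycle to 5 yr (1.3) loses ~71% of the baseline stock; sparing 83% of
old-growth (3.3) retains ~84% of the all-old-growth landscape — the
ordering 3.x > 2.x > baseline > 1.x that makes old-growth sparing the
most carbon-effective intervention.

```r
relative_change(2244.1, 13500.0, 13500.0)
#> $change_pct  -83.4    $retained_pct  16.6
```

## Layout

- `R/` — synthetic data, inventory I/O, allometry, recovery model,
  scenario engine, pipeline/CLI (`swidcarbon_cli()`, wrapper in
  `inst/scripts/swidcarbon`).
- `inst/extdata/` — editable equation registry and decay-density table
  (the registry's `provenance` column labels synthetic stand-in
  coefficients).
- `vignettes/carbon-recovery-and-scenarios.Rmd` — the methods vignette:
  model assumptions, calibration choices, numerical details, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
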