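---
title: "Methods: plot carbon, recovery curves, and landscape scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot carbon, recovery curves, and landscape scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swidcarbon)
```

swidcarbon models aboveground carbon in shifting-cultivation (swidden)
landscapes: mosaics of farmland, regenerating secondary-forest fallows, and
old-growth forest. It answers two questions. First, how much carbon does a
10 × 30 m inventory plot hold, given its stems, lianas, deadwood and leaf
litter? Second, how does landscape-level carbon respond to management —
shortening fallow cycles, sparing old fallows for permanent regeneration, or
protecting old-growth forest — the intervention families relevant to
carbon-payment schemes such as REDD+?

## 1. From inventory records to plot carbon

Each plot uses a composite design: large stems (DBH ≥ 5 cm) and deadwood
are censused on the full 300 m²; small stems (1–5 cm) on three 2 × 2 m
subplots; lianas (DBH ≥ 2 cm) on two 1 × 30 m strips; leaf litter on three
1 m² quadrats. Pool biomasses are scaled to the full plot by the inverse
sampled-area fractions (×1, ×25, ×5, ×100 respectively), summed, converted
to carbon with the wood carbon fraction 0.474, and expressed per plot
(0.03 ha) and per hectare.

**Trees.** Dry biomass per stem is the arithmetic mean of all registry
equations applicable to the plot's habitat, evaluated at DBH $D$ (cm) and
wood specific gravity $\rho$ (g/cm³, dry mass over green volume of an
increment core). Two functional forms are supported,
$B = a(\rho D^2)^b$ and
$\ln B = c_0 + c_1\ln D + c_2(\ln D)^2 + c_3\ln\rho$, both height-free:
height-based equations are excluded by design because height is
unmeasurable in closed-canopy steep terrain. Small stems cannot be cored,
so they inherit the mean $\rho$ of the large stems in their own plot (a
configurable global fallback exists for plots without large stems and is
always logged). The shipped registry mixes transcribed public coefficients
(Chave-style pan-tropical height-free form; Ketterings-style power form;
Schnitzer-style liana form) with clearly labelled synthetic stand-ins for
cited sources whose coefficients are not public; the `provenance` column
says which is which. Coefficients are inputs, not code: the ensemble
mechanism, not any coefficient value, is what the package's correctness
guarantees cover.

**Lianas.** Per liana, the mean over the liana equations (DBH only); per
strip, the sum; per plot, the mean of the two strips.

**Deadwood.** Volume uses the frustum of a cone,
$V = \tfrac{\pi h}{3}(R^2 + r^2 + Rr)$, when both end diameters were
measured, else the cone $V = \tfrac{\pi R^2 h}{3}$. The field schema
records *diameters*; the implementation halves them to radii before these
radius-based formulas — applying diameters directly would overstate volume
fourfold. Biomass is volume × density: a measured core density for
decay class 1 (recently dead), otherwise a five-class literature-style
density table (defaults 0.54/0.45/0.36/0.26/0.17 g/cm³, config-overridable,
required to be positive and non-increasing).

**Litter.** Each quadrat's compressed volume (L) is scaled by the dry-mass
concentration of a 1 L subsample; the plot value is the mean over quadrats.
The mean (not the sum) matches the per-area scaling convention used for
every other pool; the choice is flagged here because field protocols vary.

## 2. The recovery model

Plot carbon is strongly right-skewed, so models are fitted to
$\log_{10}$(Mg/ha) by linear mixed models with square-nested-in-landscape
random intercepts (`lme4`), estimated by maximum likelihood throughout —
REML AICc values are not comparable across fixed-effect structures. The
model scale is per-hectare $\log_{10}$; per-plot and per-ha versions differ
only by the additive constant $\log_{10}(0.03)$.

Candidate fixed effects are the habitat contrast (cell-means coding, one
level per habitat) or the fallow-age slope, plus standardized elevation and
its interaction with the main term. `rank_all_subsets()` fits every
admissible subset (interaction only with both mains) and ranks by
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$, where $k$ counts fixed
effects plus variance components. Ties keep the smaller model first.
Marginal and conditional $R^2$ follow Nakagawa's variance-component
decomposition, computed directly from the fit (fixed-prediction variance,
random-intercept variances, residual variance).

When the random variances or the residual variance collapse to zero — as
on noiseless synthetic data — `lme4` cannot do better than the
fixed-effects model, so `fit_model()` degrades to `lm()` and flags the fit
`degenerate` rather than failing; convergence warnings are captured into
the `converged` flag.

`predict_secondary_carbon()` back-transforms the linear predictor exactly
in `mean` mode. In `draw` mode it samples intercept/slope vectors from the
fit's Gaussian sampling distribution *truncated to the joint 95%
confidence ellipse*, reflecting parameter (not prediction) uncertainty:
the scenario engine's remit is uncertainty in the recovery curve, not
plot-level scatter. R's random-number state is ambient, so draw mode uses
the session RNG rather than taking an explicit generator handle; seed
control happens at the simulation call. Ages above 30 yr (the oldest
sampled fallow) are evaluated at 30: an uncapped exponential extrapolation
would overtake old-growth carbon within two decades, which the observed
system does not do.

A Moran's I diagnostic with inverse-distance weights (`ape::Moran.I`, zero
diagonal, randomization normal approximation) is provided to check that
plot carbon is not strongly spatially autocorrelated.

## 3. The landscape simulator

A landscape is 30 uniform 1-ha parcels. A cultivation cycle of length $L$
keeps an equal area in each state age $0$ (farmland) to $L-1$ (oldest
fallow); advancing one year ages every fallow, clears fallows reaching $L$
back to farmland, ages permanently abandoned parcels without clearing, and
leaves old-growth untouched. Scenario ids encode the published designs:
cycle shortening without sparing (1.1–1.3), sparing 50/67/83% of the
landscape as permanently abandoned old fallows (2.1–2.3; the spared parcels
take the *oldest* ages of the initial 30-yr landscape, which leaves the
remaining parcels exactly one cycle's worth of young ages), old-growth
sparing at the same fractions (3.1–3.3), the 30-yr baseline, complete
conversion of old-growth (4), and the all-old-growth reference (OF).

Each Monte Carlo draw allocates every parcel an independent per-ha carbon
value — resampled with replacement from observed plot values for farmland
and old-growth, drawn from the growth curve (with parameter uncertainty)
for fallows and abandoned parcels — and sums the 30 parcels. Totals are in
Mg per 30 ha; 1,000 simulations per scenario by default. Independence
across parcels is an explicit assumption (no within-landscape spatial
correlation is modelled). Sensitivity samplers replace the old-growth draw
with the empirical median or a constant literature value; scenario
rankings within a cycle length (3.x > 2.x > baseline > 1.x) are invariant
to this replacement, which the acceptance suite checks for 321.29, 355.09
and 376.6 Mg/ha.

The 5-yr horizon starts from the baseline age structure and applies the
new regime for 5 years; the source convention is not fully stated, and
this choice is the package's own.

## 4. The synthetic world

The generator emulates the study design: 3 landscapes × 12 squares × 3
plots = 108 plots split 17/55/36 between farmland, secondary forest and
old-growth (exact largest-remainder allocation, then shuffled); elevation
uniform on 1,487–2,652 m. Secondary plots follow
$\log_{10} C = \beta_0 + 0.04\,\mathrm{age} + u_{\mathrm{landscape}} +
u_{\mathrm{square}} + \varepsilon$; old-growth and farmland are iid
lognormal. Calibration uses only published summaries: old-growth
arithmetic mean 441.4 and SD 60 Mg/ha (moment-matched on the log scale);
the secondary curve anchored so its *arithmetic* mean at age 29 equals
7.44/0.03 = 248 Mg/ha, which requires subtracting the lognormal mean
correction $\sigma^2_{\mathrm{tot}}\ln 10/2$ from the intercept.

Values the source does not state were fixed once, before any acceptance
measurement, and not revisited: residual SD 0.25 log₁₀ units (a typical
chronosequence scatter), square and landscape random-intercept SDs 0.10
and 0.05 (squares differ more than landscapes), farmland geometric mean
10 Mg/ha (dead pools only, since farmland plots hold no stems), dead-pool
fractions 0.25 (secondary) and 0.125 (old-growth) back-derived from the
published dead-vs-total habitat contrasts, farmland entirely dead.

`generate_inventory()` inverts the allometry module: stems are drawn from
a truncated power-law DBH distribution ($\alpha = 2$, 5–80 cm in secondary,
5–200 cm in old-growth) until the live-biomass target is bracketed, then
the crossing stem's DBH is root-solved; deadwood pieces likewise with the
last piece's length rescaled (volume is linear in length); litter subsample
masses are set analytically. Closure is verified at generation time
(default 5%; in practice the inversion is exact to ~1e-11). What a green
closure test establishes is that the estimator and generator agree *through
the same equation registry* — it does not validate any allometric
coefficient against real harvest data, and the synthetic world has no
spatial structure, measurement error, or taxonomic composition.

## 5. Numerical choices and limitations

* Determinism: every generator and simulator takes a seed, runs in a
  local RNG scope (the session stream is restored), and identical inputs
  give byte-identical outputs. Pipeline stages derive child seeds from one
  master seed by a fixed affine rule below $2^{31}$.
* Degenerate inputs: constant elevation, constant Moran values, empty
  carbon tables, zero subsample volumes and non-positive dimensions all
  raise errors naming the offending quantity; validation reports list every
  breach with table, row and field.
* The truncated-ellipse parameter draw slightly under-disperses relative
  to the unconstrained Gaussian (by design: published procedure samples
  within 95% confidence limits).
* Published "enhancement" percentages for moving from a 5-yr cycle to
  longer cycles are not arithmetically recoverable from the rounded printed
  reductions and are therefore not asserted by the tests.
* Not modelled: soil organic carbon, belowground biomass, crop yield and
  opportunity costs, spatial placement of parcels, remote-sensing age
  verification.
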