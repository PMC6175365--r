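#' Scenario specification for the 30-parcel landscape simulator
#'
#' A landscape is 30 uniform 1-ha parcels, each farmland, an active fallow
#' (cleared again at the end of its cultivation cycle), a permanently
#' abandoned fallow, or old-growth forest. Named scenario ids fill in the
#' published configurations:
#'
#' * `"baseline"` — 30-yr cultivation cycle, no sparing.
#' * `"1.1"`, `"1.2"`, `"1.3"` — cycle shortened to 15/10/5 yr, no sparing.
#' * `"2.1"`, `"2.2"`, `"2.3"` — 50%/67%/83% of the landscape removed from
#'   cultivation as permanently abandoned secondary forest (the oldest
#'   fallows of the initial 30-yr landscape), remainder on 15/10/5-yr
#'   cycles.
#' * `"3.1"`, `"3.2"`, `"3.3"` — 50%/67%/83% spared as old-growth forest,
#'   remainder on 15/10/5-yr cycles.
#' * `"4"` — old-growth entirely cleared to a 30-yr cycle.
#' * `"OF"` — reference landscape of 30 old-growth parcels.
#'
#' @param id scenario id (free-form when the cycle/sparing fields are given
#'   explicitly).
#' @param cycle_length cultivation cycle, years (5, 10, 15 or 30).
#' @param spare_fraction fraction of parcels spared (x 30 must be integer).
#' @param spare_kind `"none"`, `"abandoned_secondary"` or `"old_growth"`.
#' @param horizon years simulated forward (5 or 30).
#' @param n_parcels parcels per landscape (30).
#' @param n_sims Monte Carlo draws (default 1000).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, cycle_length = NULL, spare_fraction = NULL,
                          spare_kind = NULL, horizon = 30, n_parcels = 30,
                          n_sims = 1000) {
  known <- list(
    baseline = list(30, 0, "none"),
    `1.1` = list(15, 0, "none"), `1.2` = list(10, 0, "none"),
    `1.3` = list(5, 0, "none"),
    `2.1` = list(15, 1 / 2, "abandoned_secondary"),
    `2.2` = list(10, 2 / 3, "abandoned_secondary"),
    `2.3` = list(5, 5 / 6, "abandoned_secondary"),
    `3.1` = list(15, 1 / 2, "old_growth"),
    `3.2` = list(10, 2 / 3, "old_growth"),
    `3.3` = list(5, 5 / 6, "old_growth"),
    `4` = list(30, 0, "none"),
    OF = list(30, 1, "old_growth"))
  if (id %in% names(known)) {
    k <- known[[id]]
    cycle_length <- cycle_length %||% k[[1]]
    spare_fraction <- spare_fraction %||% k[[2]]
    spare_kind <- spare_kind %||% k[[3]]
  }
  if (is.null(cycle_length) || is.null(spare_fraction) || is.null(spare_kind))
    stop("unknown scenario id '", id,
         "': give cycle_length, spare_fraction and spare_kind explicitly",
         call. = FALSE)
  spare_kind <- match.arg(spare_kind,
                          c("none", "abandoned_secondary", "old_growth"))
  if (!cycle_length %in% c(5, 10, 15, 30))
    stop("cycle_length must be one of 5, 10, 15, 30", call. = FALSE)
  if (spare_fraction < 0 || spare_fraction > 1)
    stop("spare_fraction must lie in [0, 1]", call. = FALSE)
  n_spared <- spare_fraction * n_parcels
  if (abs(n_spared - round(n_spared)) > 1e-9)
    stop("spare_fraction x n_parcels must be an integer number of parcels",
         call. = FALSE)
  n_spared <- as.integer(round(n_spared))
  if (spare_fraction > 0 && spare_kind == "none")
    stop("spare_fraction > 0 requires a spare_kind", call. = FALSE)
  n_cycle <- n_parcels - n_spared
  if (n_cycle > 0 && n_cycle %% cycle_length != 0)
    stop(sprintf("%d cultivated parcels are not divisible by a %d-yr cycle",
                 n_cycle, cycle_length), call. = FALSE)
  if (!horizon %in% c(5, 30))
    stop("horizon must be 5 or 30 years", call. = FALSE)
  structure(list(id = id, cycle_length = cycle_length,
                 spare_fraction = spare_fraction, spare_kind = spare_kind,
                 n_spared = n_spared, horizon = horizon,
                 n_parcels = n_parcels, n_sims = n_sims),
            class = "scenario_spec")
}

#' Equal-area cultivation-cycle age distribution
#'
#' A cycle of length `L` run over `n` parcels at steady state keeps an
#' equal area in every state age 0 (farmland) to `L - 1` (oldest fallow).
#'
#' @param cycle_length cycle length, years.
#' @param n_parcels number of parcels; must be divisible by `cycle_length`.
#' @return Integer vector of parcel state ages (length `n_parcels`).
#' @export
#' @examples
#' cycle_age_distribution(5, 30)  # ages 0..4, six parcels each
cycle_age_distribution <- function(cycle_length, n_parcels = 30) {
  if (n_parcels %% cycle_length != 0)
    stop(sprintf("%d parcels are not divisible by a %d-yr cycle",
                 n_parcels, cycle_length), call. = FALSE)
  rep(0:(cycle_length - 1), each = n_parcels / cycle_length)
}

#' Build the initial landscape of a scenario
#'
#' Spared parcels become old-growth (Scenario 3/OF) or permanently
#' abandoned fallows carrying the *oldest* ages of the initial 30-yr
#' landscape (Scenario 2); the remaining parcels hold the equal-area cycle
#' age distribution (age 0 = farmland).
#'
#' @param spec a [scenario_spec()].
#' @return A `landscape_state`: data frame with columns `kind`
#'   (`farmland`/`fallow`/`abandoned`/`old_growth`) and `age` (years; `NA`
#'   for old-growth), with the cycle length kept as an attribute.
#' @export
build_landscape <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  kind <- character(0); age <- numeric(0)
  if (spec$n_spared > 0) {
    if (spec$spare_kind == "old_growth") {
      kind <- rep("old_growth", spec$n_spared)
      age <- rep(NA_real_, spec$n_spared)
    } else {
      # oldest n_spared states of the initial 30-state landscape
      init_ages <- sort(cycle_age_distribution(30, spec$n_parcels),
                        decreasing = TRUE)[seq_len(spec$n_spared)]
      kind <- rep("abandoned", spec$n_spared)
      age <- as.numeric(init_ages)
    }
  }
  n_cycle <- spec$n_parcels - spec$n_spared
  if (n_cycle > 0) {
    a <- cycle_age_distribution(spec$cycle_length, n_cycle)
    kind <- c(kind, ifelse(a == 0, "farmland", "fallow"))
    age <- c(age, as.numeric(a))
  }
  st <- data.frame(kind = kind, age = age, stringsAsFactors = FALSE)
  attr(st, "cycle_length") <- spec$cycle_length
  class(st) <- c("landscape_state", "data.frame")
  st
}

#' Advance a landscape through time
#'
#' Per year: farmland becomes a 1-yr fallow; a fallow of age `a` becomes
#' `a + 1`, or is cleared back to farmland when `a + 1` reaches the cycle
#' length; abandoned fallows keep ageing (never cleared); old-growth is
#' unchanged. Advancing a pure cycle by a full cycle length returns the
#' same age multiset.
#'
#' @param state a `landscape_state`.
#' @param years non-negative integer.
#' @return The advanced `landscape_state`.
#' @export
advance <- function(state, years) {
  stopifnot(inherits(state, "landscape_state"), years >= 0)
  cycle <- attr(state, "cycle_length")
  for (i in seq_len(years)) {
    fallow <- state$kind == "fallow"
    farm <- state$kind == "farmland"
    aband <- state$kind == "abandoned"
    state$age[fallow] <- state$age[fallow] + 1
    cleared <- fallow & state$age >= cycle
    state$kind[cleared] <- "farmland"
    state$age[cleared] <- 0
    state$kind[farm] <- "fallow"
    state$age[farm] <- 1
    state$age[aband] <- state$age[aband] + 1
  }
  state
}

#' Carbon samplers for parcel kinds
#'
#' A sampler is `function(age, n)` returning `n` finite positive Mg/ha
#' draws from the session RNG. `make_empirical_sampler()` resamples
#' observed per-ha plot values with replacement; `make_constant_sampler()`
#' always returns one value; `make_model_sampler()` routes through
#' [predict_secondary_carbon()] (mode `"draw"` takes parameter uncertainty
#' into account, `"mean"` is deterministic); `sensitivity_of_sampler()`
#' builds the constant old-growth samplers used in sensitivity re-runs
#' (the empirical median, or a literature per-ha value).
#'
#' @param values observed per-ha carbon values (Mg/ha).
#' @param value a single per-ha carbon value (Mg/ha).
#' @param fit a growth-model fit for [predict_secondary_carbon()].
#' @param mode `"draw"` or `"mean"`.
#' @param age_cap extrapolation cap, years.
#' @param variant `"median"` (requires `values`) or `"literature"`
#'   (requires `value`).
#' @return A sampler function.
#' @name carbon_samplers
NULL

#' @rdname carbon_samplers
#' @export
make_empirical_sampler <- function(values) {
  stopifnot(length(values) > 0, all(is.finite(values)), all(values > 0))
  function(age, n) sample(values, n, replace = TRUE)
}

#' @rdname carbon_samplers
#' @export
make_constant_sampler <- function(value) {
  stopifnot(length(value) == 1, is.finite(value), value > 0)
  function(age, n) rep(value, n)
}

#' @rdname carbon_samplers
#' @export
make_model_sampler <- function(fit, mode = c("draw", "mean"), age_cap = 30) {
  mode <- match.arg(mode)
  function(age, n) {
    if (mode == "mean")
      rep(predict_secondary_carbon(fit, age, mode = "mean",
                                   age_cap = age_cap), n)
    else predict_secondary_carbon(fit, age, mode = "draw", n_draws = n,
                                  age_cap = age_cap)
  }
}

#' @rdname carbon_samplers
#' @export
sensitivity_of_sampler <- function(variant = c("median", "literature"),
                                   values = NULL, value = NULL) {
  variant <- match.arg(variant)
  if (variant == "median") {
    stopifnot(!is.null(values))
    make_constant_sampler(median(values))
  } else {
    stopifnot(!is.null(value), value > 0)
    make_constant_sampler(value)
  }
}

sampler_for <- function(samplers, kind) {
  s <- samplers[[kind]]
  if (is.null(s) && kind == "abandoned") s <- samplers[["fallow"]]
  if (is.null(s))
    stop("no carbon sampler configured for parcel kind '", kind, "'",
         call. = FALSE)
  s
}

#' Draw landscape-level carbon once
#'
#' Each parcel (1 ha) draws an independent per-ha carbon value from the
#' sampler of its kind; the landscape total is the exact sum over the 30
#' parcels (Mg/30 ha). Abandoned parcels use the `abandoned` sampler when
#' supplied and the `fallow` (growth-model) sampler otherwise, with ages
#' capped by that sampler.
#'
#' @param state a `landscape_state`.
#' @param samplers named list of samplers (`farmland`, `fallow`,
#'   `old_growth`, optionally `abandoned`).
#' @return A single total, Mg per 30 ha, with per-parcel draws as the
#'   `"parcels"` attribute.
#' @export
draw_landscape_carbon <- function(state, samplers) {
  draws <- vapply(seq_len(nrow(state)), function(i) {
    s <- sampler_for(samplers, state$kind[i])
    s(state$age[i], 1)
  }, numeric(1))
  structure(sum(draws), parcels = draws)
}

#' Monte Carlo simulation of one scenario
#'
#' Builds the scenario landscape, advances it to the horizon, then draws
#' `n_sims` independent landscape totals (each parcel drawn with
#' replacement from its sampler).
#'
#' @param spec a [scenario_spec()].
#' @param samplers named sampler list (see [draw_landscape_carbon()]).
#' @param seed optional seed for reproducibility.
#' @return An object of class `scenario_summary`: `id`, `horizon`,
#'   `totals` (length `n_sims`, Mg/30 ha), `mean`, `sd`, `quartiles`.
#' @export
simulate_scenario <- function(spec, samplers, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  state <- advance(build_landscape(spec), spec$horizon)
  with_seed(seed, {
    per_parcel <- vapply(seq_len(nrow(state)), function(i) {
      s <- sampler_for(samplers, state$kind[i])
      s(state$age[i], spec$n_sims)
    }, numeric(spec$n_sims))
    totals <- if (spec$n_sims == 1) sum(per_parcel) else rowSums(per_parcel)
    structure(list(id = spec$id, horizon = spec$horizon, totals = totals,
                   mean = mean(totals), sd = sd(totals),
                   quartiles = quantile(totals, c(0.25, 0.5, 0.75)),
                   state = state, n_sims = spec$n_sims),
              class = "scenario_summary")
  })
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("scenario %s (horizon %d yr): %.1f +/- %.1f Mg/30 ha (mean +/- SD, %d sims)\n",
              x$id, x$horizon, x$mean, x$sd, x$n_sims))
  invisible(x)
}

#' Analytic expectation of a spared/cultivated mixture
#'
#' `fraction * of_total + (1 - fraction) * cycle_total`: the expected total
#' of a landscape whose spared share is old-growth and whose remainder
#' follows a cultivation cycle (linearity of expectation over independent
#' parcels).
#'
#' @param fraction spared fraction in \[0, 1\].
#' @param of_total expected total of a fully old-growth landscape,
#'   Mg/30 ha.
#' @param cycle_total expected total of a fully cultivated landscape on the
#'   same cycle, Mg/30 ha.
#' @return Expected mixture total, Mg/30 ha.
#' @export
#' @examples
#' sparing_mixture(0.5, 13261.7, 1179.8)  # 7220.75
sparing_mixture <- function(fraction, of_total, cycle_total) {
  if (any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]", call. = FALSE)
  fraction * of_total + (1 - fraction) * cycle_total
}

#' Relative change and retained fraction of landscape carbon
#'
#' `change_pct = 100 * (mean - baseline mean) / baseline mean`; when a
#' `reference` (e.g. the old-growth landscape) is given,
#' `retained_pct = 100 * mean / reference mean` is added. Accepts
#' `scenario_summary` objects or plain numbers.
#'
#' @param summary,baseline,reference `scenario_summary` objects or numeric
#'   means (Mg/30 ha).
#' @return A list with `change_pct` and (optionally) `retained_pct`.
#' @export
#' @examples
#' relative_change(2699.7, 13261.7)$change_pct  # -79.6
relative_change <- function(summary, baseline, reference = NULL) {
  val <- function(x) if (inherits(x, "scenario_summary")) x$mean else
    as.numeric(x)
  m <- val(summary); b <- val(baseline)
  if (b == 0) stop("baseline mean is zero; relative change undefined",
                   call. = FALSE)
  out <- list(change_pct = 100 * (m - b) / b)
  if (!is.null(reference)) out$retained_pct <- 100 * m / val(reference)
  out
}

#' Simulate a list of scenarios into a summary table
#'
#' @param ids character vector of scenario ids.
#' @param samplers named sampler list.
#' @param horizon,n_sims passed to [scenario_spec()].
#' @param seed master seed; each scenario gets a derived child seed.
#' @return A data frame with one row per scenario (`id`, `mean`, `sd`,
#'   quartiles), with the `scenario_summary` objects as the `"summaries"`
#'   attribute.
#' @export
simulate_scenarios <- function(ids, samplers, horizon = 30, n_sims = 1000,
                               seed = NULL) {
  sums <- lapply(seq_along(ids), function(i)
    simulate_scenario(scenario_spec(ids[i], horizon = horizon,
                                    n_sims = n_sims),
                      samplers,
                      seed = if (is.null(seed)) NULL else child_seed(seed, i)))
  tab <- data.frame(
    id = ids,
    mean = vapply(sums, `[[`, numeric(1), "mean"),
    sd = vapply(sums, `[[`, numeric(1), "sd"),
    q25 = vapply(sums, function(s) unname(s$quartiles[1]), numeric(1)),
    median = vapply(sums, function(s) unname(s$quartiles[2]), numeric(1)),
    q75 = vapply(sums, function(s) unname(s$quartiles[3]), numeric(1)),
    stringsAsFactors = FALSE)
  attr(tab, "summaries") <- sums
  tab
}
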