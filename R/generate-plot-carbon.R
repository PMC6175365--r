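#' Generate a synthetic plot-carbon table
#'
#' Draws per-plot aboveground carbon (Mg/ha) for a hierarchical sampling
#' design of landscapes, squares and plots across three habitats. Secondary
#' plots follow a lognormal recovery curve: `log10 C = intercept + slope *
#' fallow_age + landscape + square + residual`, with Gaussian random
#' intercepts on the log10 scale. Farmland and old-growth plots are drawn
#' iid from their own lognormal distributions (old-growth moment-matched to
#' the arithmetic mean/SD in `params`). Elevation is uniform over the
#' configured range and carried as a covariate.
#'
#' Habitat labels are allocated to plots in exact largest-remainder counts
#' of `habitat_mix` and then shuffled, so the realized habitat split matches
#' the design rather than fluctuating binomially.
#'
#' @param params a [synthetic_params()] object.
#' @param seed integer; same `(params, seed)` reproduce the table exactly.
#' @return A `data.frame` of class `plot_table` with columns `landscape`,
#'   `square`, `plot`, `habitat`, `fallow_age` (years, `NA` unless
#'   secondary), `elevation` (m), `total_carbon`, `live_carbon`,
#'   `dead_carbon` (all Mg/ha, `total = live + dead` exactly).
#' @export
#' @examples
#' tab <- generate_plot_carbon(default_params(), seed = 1)
#' table(tab$habitat)
generate_plot_carbon <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  validate_synthetic_params(params)
  with_seed(seed, {
    meta <- build_plot_frame(params)
    n <- nrow(meta)

    ## hierarchical random intercepts, applied to secondary plots only
    ls_ids <- unique(meta$landscape)
    sq_ids <- unique(meta$square)
    ls_eff <- setNames(rnorm(length(ls_ids), 0, params$landscape_sd_log10), ls_ids)
    sq_eff <- setNames(rnorm(length(sq_ids), 0, params$square_sd_log10), sq_ids)

    meta$elevation <- runif(n, params$elevation_range[1], params$elevation_range[2])
    meta$fallow_age <- NA_real_
    sec <- meta$habitat == "secondary"
    ages <- seq(params$fallow_age_range[1], params$fallow_age_range[2])
    meta$fallow_age[sec] <- sample(ages, sum(sec), replace = TRUE)

    log10c <- numeric(n)
    log10c[sec] <- params$curve_intercept +
      params$curve_slope * meta$fallow_age[sec] +
      ls_eff[meta$landscape[sec]] + sq_eff[meta$square[sec]] +
      rnorm(sum(sec), 0, params$resid_sd_log10)

    of <- meta$habitat == "old_growth"
    if (any(of)) {
      mo <- of_log_moments(params$of_mean, params$of_sd)
      log10c[of] <- rnorm(sum(of), mo$mu, mo$sd)
    }
    fl <- meta$habitat == "farmland"
    if (any(fl)) {
      log10c[fl] <- rnorm(sum(fl), log10(params$farmland_geo_mean),
                          params$farmland_sd_log10)
    }

    meta$total_carbon <- 10^log10c
    df <- params$dead_fraction[meta$habitat]
    meta$dead_carbon <- meta$total_carbon * as.numeric(df)
    meta$live_carbon <- meta$total_carbon - meta$dead_carbon
    rownames(meta) <- NULL
    class(meta) <- c("plot_table", "data.frame")
    meta
  })
}

# log10-scale moments of a lognormal with given arithmetic mean and SD
of_log_moments <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  s_ln <- sqrt(log1p(cv2))
  m_ln <- log(mean) - s_ln^2 / 2
  list(mu = m_ln / log(10), sd = s_ln / log(10))
}

# landscape/square/plot ids plus an exact largest-remainder habitat split
build_plot_frame <- function(params) {
  nl <- params$n_landscapes
  ns <- params$squares_per_landscape
  np <- params$plots_per_square
  landscape <- rep(sprintf("L%02d", seq_len(nl)), each = ns * np)
  square <- rep(sprintf("L%02d-S%02d", rep(seq_len(nl), each = ns),
                        rep(seq_len(ns), nl)), each = np)
  n <- nl * ns * np
  plot <- sprintf("%s-P%d", square, rep(seq_len(np), nl * ns))

  counts <- largest_remainder(params$habitat_mix, n)
  habitat <- sample(rep(names(counts), counts))
  data.frame(landscape = landscape, square = square, plot = plot,
             habitat = habitat, stringsAsFactors = FALSE)
}

largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(props))
}
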