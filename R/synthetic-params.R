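#' Parameters of the synthetic landscape generator
#'
#' Bundles every knob of the synthetic-data module. The defaults reproduce
#' the published summaries of the study system the package emulates: three
#' shifting-cultivation landscapes at 1,487-2,652 m elevation sampled with
#' 400 x 400 m squares holding 10 x 30 m plots; old-growth plots with
#' arithmetic mean 441.4 and SD 60 Mg/ha; secondary-forest carbon following
#' a log10-linear recovery curve with slope 0.04 log10(Mg/ha) per year whose
#' arithmetic mean at a 29-yr fallow age is 7.44/0.03 = 248 Mg/ha.
#'
#' Carbon is generated on the per-hectare log10 scale. Because plot carbon
#' is lognormal, the curve intercept that yields a stated *arithmetic* mean
#' must subtract the lognormal mean correction
#' `sigma_tot^2 * ln(10) / 2` where `sigma_tot` is the total log10 SD
#' (residual plus square and landscape random-intercept scales). When
#' `curve_intercept = NULL` (the default) it is solved from
#' `age29_mean` this way, so zero-noise settings put the curve itself
#' through the calibration anchor.
#'
#' @param n_landscapes,squares_per_landscape,plots_per_square positive
#'   integer counts; defaults 3 x 12 x 3 = 108 plots.
#' @param habitat_mix named proportions over
#'   `c("farmland","secondary","old_growth")`, summing to 1. Default
#'   17/55/36 of 108, the study's habitat split.
#' @param fallow_age_range integer range (years) of secondary fallow ages,
#'   within \[1, 60\].
#' @param curve_intercept log10(Mg/ha) intercept of the recovery curve, or
#'   `NULL` to calibrate from `age29_mean`.
#' @param curve_slope log10(Mg/ha) per year; default 0.04.
#' @param age29_mean arithmetic-mean secondary carbon (Mg/ha) at age 29 used
#'   to calibrate the intercept; default 7.44/0.03.
#' @param resid_sd_log10 residual SD on the log10 scale (default 0.25; the
#'   source study does not print one, see the methods vignette).
#' @param square_sd_log10,landscape_sd_log10 random-intercept SDs on the
#'   log10 scale for squares and landscapes (secondary plots).
#' @param of_mean,of_sd arithmetic mean and SD (Mg/ha) of old-growth plot
#'   carbon; defaults 441.4 and 60.
#' @param farmland_geo_mean geometric-mean farmland carbon, Mg/ha (dead
#'   pools only); default 10.
#' @param farmland_sd_log10 farmland log10 SD; default `resid_sd_log10`.
#' @param dead_fraction named fractions of total carbon held in dead pools
#'   per habitat. Defaults back-derived from the published dead vs total
#'   habitat contrasts (farmland all-dead because its plots hold no stems).
#' @param elevation_range range in m asl; default c(1487, 2652).
#' @param seed default seed used when a generator is called without one.
#' @return An object of class `synthetic_params` (a validated list).
#' @seealso [generate_plot_carbon()], [generate_inventory()]
#' @export
#' @examples
#' p <- default_params()
#' p$of_mean          # 441.4
#' p$curve_slope      # 0.04
synthetic_params <- function(n_landscapes = 3,
                             squares_per_landscape = 12,
                             plots_per_square = 3,
                             habitat_mix = c(farmland = 17, secondary = 55,
                                             old_growth = 36) / 108,
                             fallow_age_range = c(1, 30),
                             curve_intercept = NULL,
                             curve_slope = 0.04,
                             age29_mean = 7.44 / 0.03,
                             resid_sd_log10 = 0.25,
                             square_sd_log10 = 0.10,
                             landscape_sd_log10 = 0.05,
                             of_mean = 441.4,
                             of_sd = 60,
                             farmland_geo_mean = 10,
                             farmland_sd_log10 = NULL,
                             dead_fraction = c(farmland = 1,
                                               secondary = 0.25,
                                               old_growth = 0.125),
                             elevation_range = c(1487, 2652),
                             seed = 1L) {
  p <- list(n_landscapes = n_landscapes,
            squares_per_landscape = squares_per_landscape,
            plots_per_square = plots_per_square,
            habitat_mix = habitat_mix,
            fallow_age_range = fallow_age_range,
            curve_intercept = curve_intercept,
            curve_slope = curve_slope,
            age29_mean = age29_mean,
            resid_sd_log10 = resid_sd_log10,
            square_sd_log10 = square_sd_log10,
            landscape_sd_log10 = landscape_sd_log10,
            of_mean = of_mean,
            of_sd = of_sd,
            farmland_geo_mean = farmland_geo_mean,
            farmland_sd_log10 = farmland_sd_log10 %||% resid_sd_log10,
            dead_fraction = dead_fraction,
            elevation_range = elevation_range,
            seed = seed)
  if (is.null(p$curve_intercept)) {
    s2 <- p$resid_sd_log10^2 + p$square_sd_log10^2 + p$landscape_sd_log10^2
    p$curve_intercept <- log10(p$age29_mean) - p$curve_slope * 29 -
      s2 * log(10) / 2
  }
  validate_synthetic_params(p)
  structure(p, class = "synthetic_params")
}

#' Default, fully calibrated synthetic parameters
#'
#' Shorthand for [synthetic_params()] with no arguments.
#' @return A `synthetic_params` object.
#' @export
default_params <- function() synthetic_params()

validate_synthetic_params <- function(p) {
  chk_count <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a positive integer count", field),
           call. = FALSE)
  }
  chk_count("n_landscapes")
  chk_count("squares_per_landscape")
  chk_count("plots_per_square")
  hm <- p$habitat_mix
  if (!all(c("farmland", "secondary", "old_growth") %in% names(hm)))
    stop("`habitat_mix` must be named over farmland/secondary/old_growth",
         call. = FALSE)
  if (any(hm < 0) || abs(sum(hm) - 1) > 1e-8)
    stop("`habitat_mix` proportions must be non-negative and sum to 1",
         call. = FALSE)
  ar <- p$fallow_age_range
  if (length(ar) != 2 || ar[1] < 1 || ar[2] > 60 || ar[1] > ar[2])
    stop("`fallow_age_range` must lie within [1, 60]", call. = FALSE)
  for (field in c("resid_sd_log10", "square_sd_log10", "landscape_sd_log10",
                  "of_sd", "farmland_sd_log10")) {
    if (p[[field]] < 0)
      stop(sprintf("`%s` must be >= 0", field), call. = FALSE)
  }
  for (field in c("of_mean", "farmland_geo_mean", "age29_mean")) {
    if (p[[field]] <= 0)
      stop(sprintf("`%s` must be > 0", field), call. = FALSE)
  }
  if (any(p$dead_fraction < 0) || any(p$dead_fraction > 1))
    stop("`dead_fraction` entries must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.synthetic_params <- function(x, ...) {
  cat("Synthetic landscape parameters\n")
  cat(sprintf("  design: %d landscape(s) x %d square(s) x %d plot(s) = %d plots\n",
              x$n_landscapes, x$squares_per_landscape, x$plots_per_square,
              x$n_landscapes * x$squares_per_landscape * x$plots_per_square))
  cat(sprintf("  habitat mix: farmland %.3f, secondary %.3f, old-growth %.3f\n",
              x$habitat_mix[["farmland"]], x$habitat_mix[["secondary"]],
              x$habitat_mix[["old_growth"]]))
  cat(sprintf("  recovery curve: log10 C = %.4f + %.3f * age (resid SD %.2f)\n",
              x$curve_intercept, x$curve_slope, x$resid_sd_log10))
  cat(sprintf("  old-growth: mean %.1f, SD %.1f Mg/ha; farmland geo mean %.1f\n",
              x$of_mean, x$of_sd, x$farmland_geo_mean))
  invisible(x)
}
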