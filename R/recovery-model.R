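#' Standardize elevation to z-scores
#'
#' Centers and scales (sample SD) so habitat/age coefficients are
#' interpretable at the mean elevation.
#'
#' @param values numeric vector with at least two distinct values.
#' @return z-scores with mean 0 and SD 1.
#' @export
scale_elevation <- function(values) {
  if (length(unique(values)) < 2)
    stop("cannot standardize a constant elevation vector", call. = FALSE)
  as.numeric(scale(values))
}

# AICc small-sample correction
aicc <- function(aic, k, n) {
  if (n - k - 1 <= 0)
    stop(sprintf("AICc undefined: n - k - 1 = %d <= 0", n - k - 1),
         call. = FALSE)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a carbon model on the log10 scale
#'
#' Fits `log10(carbon) ~ fixed terms + (1 | landscape/square)` by maximum
#' likelihood (ML throughout, because AICc comparisons span different
#' fixed-effect structures). Models containing `fallow_age` are fitted on
#' secondary-forest plots only (the recovery chronosequence); models
#' containing `habitat` use all plots with cell-means coding (`~ 0 +
#' habitat + ...`) so each habitat gets its own log10 level. `elevation_z`
#' is standardized within the modelling subset.
#'
#' When the mixed fit fails or its residual variance collapses to zero
#' (e.g. noiseless synthetic data), the fit degrades gracefully to the
#' fixed-effects linear model and is flagged `degenerate`. Convergence
#' warnings are captured into the `converged` flag rather than discarded.
#'
#' @param table a `plot_table` (from [generate_plot_carbon()],
#'   [plot_carbon_table()] or [read_plot_carbon_table()]).
#' @param response one of `"total"`, `"live"`, `"dead"` carbon (Mg/ha).
#' @param fixed character subset of
#'   `c("fallow_age", "habitat", "elevation_z", "interaction")`;
#'   `"interaction"` crosses the first main term with `elevation_z`.
#' @return An object of class `growth_model_fit`: coefficients, covariance,
#'   residual SD, random-intercept variances, `n`, `k`, `AICc`, flags, and
#'   `intercept`/`slope` accessor fields when `fallow_age` is a term.
#' @export
fit_model <- function(table, response = "total", fixed = "fallow_age") {
  response <- match.arg(response, c("total", "live", "dead"))
  ycol <- paste0(response, "_carbon")
  if (!ycol %in% names(table))
    stop("table lacks column ", ycol, call. = FALSE)
  dat <- as.data.frame(table)
  if ("fallow_age" %in% fixed) dat <- dat[dat$habitat == "secondary", ]
  if (nrow(dat) < 10)
    stop("need at least 10 plots to fit a model", call. = FALSE)
  if (any(!(dat[[ycol]] > 0)))
    stop("carbon values must be positive for the log10 transform",
         call. = FALSE)
  dat$log10_carbon <- log10(dat[[ycol]])
  if ("elevation_z" %in% fixed || "interaction" %in% fixed)
    dat$elevation_z <- scale_elevation(dat$elevation)

  main <- intersect(fixed, c("fallow_age", "habitat"))
  terms <- main
  if ("elevation_z" %in% fixed) terms <- c(terms, "elevation_z")
  if ("interaction" %in% fixed) {
    if (length(main) == 0 || !"elevation_z" %in% fixed)
      stop("interaction requires both a main term and elevation_z",
           call. = FALSE)
    terms <- c(terms, paste0(main[1], ":elevation_z"))
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  if ("habitat" %in% main) rhs <- paste("0 +", rhs)
  fml <- as.formula(paste("log10_carbon ~", rhs,
                          "+ (1 | landscape/square)"))

  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(suppressMessages(lme4::lmer(fml, data = dat, REML = FALSE)),
             error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  degenerate <- inherits(fit, "error") ||
    (!inherits(fit, "error") && sigma(fit) < 1e-8)
  if (degenerate) {
    lm_fml <- as.formula(paste("log10_carbon ~", rhs))
    fit <- stats::lm(lm_fml, data = dat)
    beta <- coef(fit)
    # vcov.lm warns "essentially perfect fit" on noiseless data; the zero
    # covariance it returns is exactly what we want there
    vc <- suppressWarnings(vcov(fit))
    ranvar <- c(`square:landscape` = 0, landscape = 0)
    res_sd <- sigma(fit)
    k <- length(beta) + 1
    singular <- FALSE
    converged <- TRUE
  } else {
    beta <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    ranvar <- setNames(vcdf$vcov[vcdf$grp != "Residual"],
                       vcdf$grp[vcdf$grp != "Residual"])
    res_sd <- sigma(fit)
    k <- length(beta) + length(ranvar) + 1
    singular <- lme4::isSingular(fit)
    converged <- !any(grepl("failed to converge", warn))
  }
  n <- nrow(dat)
  out <- list(
    response = response, fixed = fixed, formula = fml,
    coefficients = beta, vcov = vc, resid_sd = res_sd,
    ranef_var = ranvar, n = n, k = k,
    logLik = as.numeric(logLik(fit)),
    AIC = AIC(fit), AICc = aicc(AIC(fit), k, n),
    converged = converged, singular = singular, degenerate = degenerate,
    warnings = warn, model = fit, data = dat)
  if ("fallow_age" %in% fixed) {
    out$intercept <- unname(beta["(Intercept)"])
    out$slope <- unname(beta["fallow_age"])
  }
  class(out) <- "growth_model_fit"
  out
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("log10-carbon model (%s carbon), n = %d, AICc = %.2f%s\n",
              x$response, x$n, x$AICc,
              if (x$degenerate) " [degenerate: fixed-effects fallback]"
              else if (x$singular) " [singular random effects]" else ""))
  print(round(x$coefficients, 4))
  cat(sprintf("residual SD %.4f; random-intercept variances: %s\n",
              x$resid_sd,
              paste(sprintf("%s %.4g", names(x$ranef_var), x$ranef_var),
                    collapse = ", ")))
  invisible(x)
}

#' Rank all fixed-effect subsets by AICc
#'
#' Fits every admissible subset of the base terms (the interaction only
#' together with both mains), computes AICc
#' (`AIC + 2k(k+1)/(n - k - 1)`), the Nakagawa marginal and conditional
#' R-squared, and sorts ascending by AICc; ties keep the model with fewer
#' terms first.
#'
#' @inheritParams fit_model
#' @param base_terms the full term set, e.g.
#'   `c("fallow_age", "elevation_z", "interaction")`.
#' @return A data frame of class `model_rank_table` with columns `terms`,
#'   `k`, `AICc`, `delta_AICc`, `r2_marginal`, `r2_conditional`, plus a
#'   `fits` attribute holding the fitted models in table order.
#' @export
rank_all_subsets <- function(table, response = "total",
                             base_terms = c("fallow_age", "elevation_z",
                                            "interaction")) {
  main <- intersect(base_terms, c("fallow_age", "habitat"))
  if (length(main) != 1)
    stop("base_terms must contain exactly one of fallow_age/habitat",
         call. = FALSE)
  subsets <- list(character(0), main)
  if ("elevation_z" %in% base_terms) {
    subsets <- c(subsets, list("elevation_z", c(main, "elevation_z")))
    if ("interaction" %in% base_terms)
      subsets <- c(subsets, list(c(main, "elevation_z", "interaction")))
  }
  fits <- lapply(subsets, function(s) fit_model(table, response, fixed = s))
  r2 <- lapply(fits, r2_nakagawa)
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s) == 0) "(intercept only)" else paste(s, collapse = " + "),
      character(1)),
    n_terms = lengths(subsets),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    r2_marginal = vapply(r2, `[[`, numeric(1), "marginal"),
    r2_conditional = vapply(r2, `[[`, numeric(1), "conditional"),
    stringsAsFactors = FALSE)
  ord <- order(tab$AICc, tab$n_terms)
  tab <- tab[ord, ]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("model_rank_table", "data.frame")
  tab
}

#' Nakagawa marginal and conditional R-squared
#'
#' `marginal = var(fixed predictions) / (var(fixed) + sum(random-intercept
#' variances) + residual variance)`; the conditional version adds the
#' random-intercept variances to the numerator. Both lie in \[0, 1\] with
#' conditional >= marginal.
#'
#' @param fit a [fit_model()] result.
#' @return A list with elements `marginal` and `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "growth_model_fit"))
  pred_fixed <- if (fit$degenerate) predict(fit$model)
    else predict(fit$model, re.form = NA)
  var_f <- var(pred_fixed)
  var_r <- sum(fit$ranef_var)
  var_e <- fit$resid_sd^2
  total <- var_f + var_r + var_e
  if (total <= 0)
    stop("total variance is zero; R-squared undefined", call. = FALSE)
  list(marginal = var_f / total, conditional = (var_f + var_r) / total)
}

#' Predict secondary-forest carbon at a fallow age
#'
#' Mean mode back-transforms the linear predictor exactly:
#' `10^(intercept + slope * age)`. Draw mode samples a parameter vector
#' from the fit's Gaussian sampling distribution truncated to the joint
#' 95% confidence ellipse (parameter uncertainty only, no residual noise)
#' and back-transforms; each requested draw uses a fresh parameter vector
#' from the session RNG. Ages above `age_cap` (default 30 yr, the oldest
#' sampled fallow) are evaluated at `age_cap` — uncapped exponential
#' extrapolation would exceed old-growth carbon within two decades.
#'
#' @param fit a [fit_model()] result with a `fallow_age` term, or a
#'   [calibrated_growth_fit()].
#' @param age fallow age(s), years (> 0).
#' @param mode `"mean"` or `"draw"`.
#' @param n_draws number of draws per age in draw mode.
#' @param age_cap extrapolation cap in years.
#' @return Mg/ha: a vector (mean mode, or draw mode with one age) or an
#'   `n_draws x length(age)` matrix.
#' @export
predict_secondary_carbon <- function(fit, age, mode = c("mean", "draw"),
                                     n_draws = 1, age_cap = 30) {
  mode <- match.arg(mode)
  if (is.null(fit$intercept) || is.null(fit$slope))
    stop("fit does not contain a fallow-age growth curve", call. = FALSE)
  if (any(!(age > 0))) stop("age must be > 0", call. = FALSE)
  a <- pmin(age, age_cap)
  if (mode == "mean") return(10^(fit$intercept + fit$slope * a))
  pars <- draw_growth_parameters(fit, n_draws)
  out <- 10^(outer(pars[, 1], rep(1, length(a))) + outer(pars[, 2], a))
  if (length(a) == 1) as.numeric(out) else out
}

# parameter draws truncated to the joint 95% confidence ellipse
draw_growth_parameters <- function(fit, n) {
  idx <- c("(Intercept)", "fallow_age")
  mu <- c(fit$intercept, fit$slope)
  vc <- fit$vcov[idx, idx]
  lim <- qchisq(0.95, df = 2)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 16)
    cand <- MASS::mvrnorm(m, mu, vc)
    if (m == 1) cand <- matrix(cand, 1)
    keep <- mahalanobis(cand, mu, vc) <= lim
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Build a growth-curve fit from printed calibration constants
#'
#' Constructs a `growth_model_fit`-compatible object directly from summary
#' values (no data): the curve passes through `value_at_age` Mg/ha at
#' `at_age` with the given slope, and parameter uncertainty is specified as
#' independent SDs of the level at `at_age` (log10 scale) and of the slope.
#' Useful for driving the scenario engine from published coefficients.
#'
#' @param value_at_age back-transformed carbon, Mg/ha, at `at_age`.
#' @param at_age anchor age, years.
#' @param slope log10(Mg/ha) per year.
#' @param slope_sd SD of the slope.
#' @param level_sd_log10 SD of the log10 level at `at_age`.
#' @return An object of class `growth_model_fit` usable by
#'   [predict_secondary_carbon()] and [make_model_sampler()].
#' @export
calibrated_growth_fit <- function(value_at_age, at_age = 29, slope = 0.04,
                                  slope_sd = 0.01, level_sd_log10 = 0.02) {
  level <- log10(value_at_age)
  intercept <- level - slope * at_age
  # (intercept, slope) = (level - at_age * slope, slope); level and slope
  # independent => linear transform of the covariance
  v_l <- level_sd_log10^2; v_s <- slope_sd^2
  vc <- matrix(c(v_l + at_age^2 * v_s, -at_age * v_s,
                 -at_age * v_s, v_s), 2, 2,
               dimnames = list(c("(Intercept)", "fallow_age"),
                               c("(Intercept)", "fallow_age")))
  structure(list(
    response = "total", fixed = "fallow_age",
    coefficients = c(`(Intercept)` = intercept, fallow_age = slope),
    vcov = vc, resid_sd = NA_real_, ranef_var = numeric(0),
    n = NA_integer_, k = 2, AICc = NA_real_,
    converged = TRUE, singular = FALSE, degenerate = FALSE,
    calibrated = TRUE, intercept = intercept, slope = slope),
    class = "growth_model_fit")
}

#' Moran's I spatial-autocorrelation test
#'
#' Standard Moran's I with inverse-distance weights (zero diagonal) and a
#' p-value from the normal approximation under randomization, as in
#' `ape::Moran.I`.
#'
#' @param values numeric vector (non-constant).
#' @param coordinates two-column matrix/data frame of point coordinates
#'   (at least 4 non-identical points).
#' @return A list with `I`, `expected` (`-1/(n-1)`), `sd` and `p`.
#' @export
moran_i <- function(values, coordinates) {
  coordinates <- as.matrix(coordinates)
  n <- length(values)
  if (n < 4 || nrow(coordinates) != n)
    stop("need >= 4 points with matching coordinates", call. = FALSE)
  if (sd(values) == 0)
    stop("Moran's I undefined for constant values", call. = FALSE)
  d <- as.matrix(dist(coordinates))
  if (any(d[upper.tri(d)] == 0))
    stop("coordinates contain identical points", call. = FALSE)
  w <- 1 / d
  diag(w) <- 0
  res <- ape::Moran.I(values, w)
  list(I = res$observed, expected = res$expected, sd = res$sd,
       p = res$p.value)
}
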