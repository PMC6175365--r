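test_that("elevation standardization follows the sample-SD convention", {
  expect_equal(scale_elevation(c(1, 2, 3)), c(-1, 0, 1))
  z <- scale_elevation(runif(50, 1487, 2652))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(scale_elevation(rep(2000, 5)), "constant")
})

test_that("AICc applies the small-sample correction", {
  expect_equal(swidcarbon:::aicc(100, 2, 10) - 100, 12 / 7)
  expect_error(swidcarbon:::aicc(100, 9, 10), "undefined")
})

test_that("habitat model recovers known geometric means", {
  # build a table directly: known geometric means per habitat
  set.seed(31)
  n <- 90
  hab <- rep(c("farmland", "secondary", "old_growth"), each = n / 3)
  geo <- c(farmland = 10, secondary = 60, old_growth = 300)
  tab <- data.frame(
    landscape = rep(c("A", "B", "C"), n / 3),
    square = paste0(rep(c("A", "B", "C"), n / 3), "-",
                    rep(1:15, length.out = n)),
    plot = sprintf("p%02d", 1:n), habitat = hab,
    fallow_age = ifelse(hab == "secondary", 15, NA),
    elevation = runif(n, 1500, 2600),
    total_carbon = 10^(log10(geo[hab]) + rnorm(n, 0, 0.1)))
  tab$live_carbon <- tab$total_carbon * 0.8
  tab$dead_carbon <- tab$total_carbon * 0.2
  fit <- fit_model(tab, "total", fixed = "habitat")
  of <- fit$coefficients[["habitatold_growth"]]
  se <- sqrt(fit$vcov["habitatold_growth", "habitatold_growth"])
  expect_lt(abs(of - log10(300)), 3 * se + 0.05)
  # cell-means coding: one coefficient per habitat
  expect_setequal(names(fit$coefficients),
                  c("habitatfarmland", "habitatsecondary",
                    "habitatold_growth"))
})

test_that("subset ranking is sorted with delta zero at the top", {
  tab <- generate_plot_carbon(default_params(), seed = 13)
  ranks <- rank_all_subsets(tab, "total",
                            c("fallow_age", "elevation_z", "interaction"))
  expect_equal(ranks$delta_AICc[1], 0)
  expect_true(!is.unsorted(ranks$AICc))
  expect_equal(nrow(ranks), 5)
  # response rescaling shifts AICc but preserves the ranking deltas
  tab2 <- tab
  tab2$total_carbon <- tab2$total_carbon * 7
  ranks2 <- rank_all_subsets(tab2, "total",
                             c("fallow_age", "elevation_z", "interaction"))
  expect_equal(ranks2$terms, ranks$terms)
  expect_equal(ranks2$delta_AICc, ranks$delta_AICc, tolerance = 1e-6)
})

test_that("Nakagawa R2 matches direct variance-component arithmetic", {
  tab <- generate_plot_carbon(default_params(), seed = 17)
  fit <- fit_model(tab, "total", "fallow_age")
  r2 <- r2_nakagawa(fit)
  pred <- predict(fit$model, re.form = NA)
  vf <- var(pred); vr <- sum(fit$ranef_var); ve <- fit$resid_sd^2
  expect_equal(r2$marginal, vf / (vf + vr + ve))
  expect_equal(r2$conditional, (vf + vr) / (vf + vr + ve))
  expect_gte(r2$conditional, r2$marginal)
  expect_true(r2$marginal >= 0 && r2$conditional <= 1)

  # degenerate noiseless fit: fixed effects explain everything
  p0 <- synthetic_params(resid_sd_log10 = 0, square_sd_log10 = 0,
                         landscape_sd_log10 = 0)
  fit0 <- fit_model(generate_plot_carbon(p0, seed = 2), "total",
                    "fallow_age")
  r20 <- r2_nakagawa(fit0)
  expect_equal(r20$marginal, 1, tolerance = 1e-6)
  expect_equal(r20$conditional, 1, tolerance = 1e-6)
})

test_that("mean prediction is the exact back-transform, with an age cap", {
  fit <- calibrated_growth_fit(100, at_age = 10, slope = 0)
  expect_equal(predict_secondary_carbon(fit, c(1, 10, 25)), rep(100, 3))
  fit2 <- calibrated_growth_fit(248, at_age = 29, slope = 0.04)
  expect_equal(predict_secondary_carbon(fit2, 29), 248)
  expect_equal(predict_secondary_carbon(fit2, 15),
               10^(fit2$intercept + 0.04 * 15))
  # extrapolation beyond the oldest sampled fallow evaluates at the cap
  expect_equal(predict_secondary_carbon(fit2, 45),
               predict_secondary_carbon(fit2, 30))
  expect_error(predict_secondary_carbon(fit2, -1), "age")
})

test_that("parameter draws stay inside the joint 95% confidence region", {
  fit <- calibrated_growth_fit(248, at_age = 29, slope = 0.04,
                               slope_sd = 0.01, level_sd_log10 = 0.02)
  set.seed(99)
  pars <- swidcarbon:::draw_growth_parameters(fit, 5000)
  mu <- c(fit$intercept, fit$slope)
  d2 <- mahalanobis(pars, mu, fit$vcov)
  expect_true(all(d2 <= qchisq(0.95, 2) + 1e-9))
  # back-transformed draws bracket the mean curve
  draws <- predict_secondary_carbon(fit, 20, mode = "draw", n_draws = 2000)
  expect_true(all(is.finite(draws)) && all(draws > 0))
  expect_lt(abs(median(log10(draws)) - (fit$intercept + fit$slope * 20)),
            0.02)
})

test_that("Moran's I behaves like the randomization null", {
  set.seed(7)
  xy <- expand.grid(x = 1:5, y = 1:5)
  grad <- moran_i(xy$x + xy$y + rnorm(25, 0, 0.1), xy)
  expect_gt(grad$I, 0)
  expect_lt(grad$p, 0.05)
  expect_error(moran_i(rep(1, 25), xy), "constant")
  expect_error(moran_i(1:3, xy[1:3, ]), ">= 4")
  # permutation mean of I approaches -1/(n-1)
  vals <- rnorm(25)
  perms <- replicate(400, moran_i(sample(vals), xy)$I)
  expect_equal(mean(perms), -1 / 24,
               tolerance = 5 * sd(perms) / sqrt(400) / abs(1 / 24))
})
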