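test_that("the route time ratio is recovered on exponential data", {
  cfg <- sim_config(n_patients = 5000, seed = 14, p_ep_base = 0.4,
                    weibull_shape = 1, weibull_scale_ep = 15,
                    aft_route_factor = 2,
                    entry_window_months = 36, admin_cutoff_month = 72)
  ch <- simulate_cohort(cfg)
  fit <- fit_weibull_aft(ch)
  se <- sqrt(diag(vcov(fit$model))["routeGPTWW"])
  expect_lt(abs(log(years_of_life_saved(fit)$time_ratio) - log(2)), 3 * se)

  # null configuration: route coefficient indistinguishable from zero
  null_ch <- simulate_cohort(sim_config(n_patients = 4000, seed = 15,
                                        aft_route_factor = 1))
  nfit <- fit_weibull_aft(null_ch)
  nse <- sqrt(diag(vcov(nfit$model))["routeGPTWW"])
  expect_lt(abs(coef(nfit)["routeGPTWW"]), 3 * nse)
})

test_that("the Weibull shape is recovered from an uncensored sample", {
  cfg <- sim_config(n_patients = 4000, seed = 16, weibull_shape = 1.6,
                    weibull_scale_ep = 30, aft_route_factor = 1,
                    entry_window_months = 1, admin_cutoff_month = 1000)
  ch <- simulate_cohort(cfg)
  # horizon truncation censors survivors past 60 months; survreg handles it
  fit <- fit_weibull_aft(ch)
  se_log_scale <- sqrt(utils::tail(diag(vcov(fit$model)), 1))
  expect_lt(abs(log(fit$scale) - log(1 / 1.6)), 3 * se_log_scale)
})

test_that("survival probabilities follow the Weibull closed form", {
  cfg <- sim_config(n_patients = 8000, seed = 17, weibull_shape = 1,
                    weibull_scale_ep = 20, aft_route_factor = 2,
                    entry_window_months = 36, admin_cutoff_month = 72)
  ch <- simulate_cohort(cfg)
  fit <- fit_weibull_aft(ch)
  expect_identical(survival_prob(fit, "EP", 0), 1)
  expect_equal(survival_prob(fit, "EP", 20), exp(-1), tolerance = 0.03)
  expect_equal(survival_prob(fit, "GPTWW", 40), exp(-1), tolerance = 0.03)
  expect_error(survival_prob(fit, "EP", -1), "non-negative")
})

test_that("RMST closed form and quadrature agree to high precision", {
  ch <- simulate_cohort(sim_config(n_patients = 600, seed = 18,
                                   covariate_coefs_survival =
                                     c(age = -0.2, imd = -0.05, comorb = -0.1)))
  fit <- fit_weibull_aft(ch, c("age", "imd_income"))
  for (tau in c(12, 36, 60)) {
    a <- restricted_mean_survival(fit, "GPTWW", tau, method = "igamma")
    b <- restricted_mean_survival(fit, "GPTWW", tau, method = "quadrature")
    expect_equal(a, b, tolerance = 1e-8)
    expect_lte(a, tau)
  }
  # monotone non-decreasing in tau
  r <- vapply(c(6, 12, 24, 48, 60), function(tau)
    restricted_mean_survival(fit, "EP", tau), numeric(1))
  expect_true(all(diff(r) > 0))
  # short-horizon limit: RMST/tau -> 1
  expect_equal(restricted_mean_survival(fit, "EP", 1e-3) / 1e-3, 1,
               tolerance = 1e-3)
})

test_that("the closed-form Weibull RMST matches quadrature on a parameter grid", {
  for (k in c(0.6, 1, 1.8)) for (lam in c(10, 40, 80)) for (tau in c(12, 60)) {
    q <- stats::integrate(function(t) exp(-(t / lam)^k), 0, tau,
                          rel.tol = 1e-12)$value
    expect_equal(reroutecost:::weibull_rmst(lam, k, tau), q, tolerance = 1e-8)
  }
})

test_that("years of life saved has the sign of the fitted time ratio minus one", {
  for (af in c(0.6, 1.8)) {
    ch <- simulate_cohort(sim_config(n_patients = 2500, seed = 19,
                                     aft_route_factor = af))
    y <- years_of_life_saved(fit_weibull_aft(ch))
    expect_identical(sign(y$yls), sign(y$time_ratio - 1))
  }
})

test_that("an all-censored cohort is rejected", {
  ch <- constant_cost_cohort(3)
  expect_error(fit_weibull_aft(ch), "no observed deaths")
})
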