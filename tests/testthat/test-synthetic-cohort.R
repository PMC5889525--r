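test_that("identical configuration and seed reproduce an identical cohort", {
  cfg <- sim_config(n_patients = 300, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$costs, b$costs)
  expect_error(sim_config(n_patients = 0), "empty")
})

test_that("route assignment matches the configured EP probability without confounding", {
  cfg <- sim_config(n_patients = 20000, seed = 9, p_ep_base = 0.3)
  ch <- simulate_cohort(cfg)
  se <- sqrt(0.3 * 0.7 / 20000)
  expect_lt(abs(mean(ch$patients$route == "EP") - 0.3), 3 * se)
})

test_that("arm-level survival matches the Weibull closed form", {
  # k = 1, lambda_EP = 20: S(12) = exp(-12/20); no censoring before month 12
  cfg <- sim_config(n_patients = 20000, seed = 10, p_ep_base = 0.3,
                    weibull_shape = 1, weibull_scale_ep = 20,
                    aft_route_factor = 2.5,
                    entry_window_months = 36, admin_cutoff_month = 72)
  ch <- simulate_cohort(cfg)
  ep <- ch$patients[ch$patients$route == "EP", ]
  s12 <- mean(ep$time_to_event > 12)
  p <- exp(-12 / 20)
  expect_lt(abs(s12 - p), 3 * sqrt(p * (1 - p) / nrow(ep)))
  gp <- ch$patients[ch$patients$route == "GPTWW", ]
  p_gp <- exp(-12 / 50)
  expect_lt(abs(mean(gp$time_to_event > 12) - p_gp),
            3 * sqrt(p_gp * (1 - p_gp) / nrow(gp)))
})

test_that("censoring is independent of the survival error given covariates", {
  cfg <- sim_config(n_patients = 8000, seed = 4,
                    covariate_coefs_survival = c(age = -0.2, imd = -0.05,
                                                 comorb = -0.1))
  ch <- simulate_cohort(cfg)
  lat <- attr(ch, "latents")
  # Gumbel-scale error of the AFT law vs administrative censoring time
  resid <- log(lat$t_latent) - lat$lp_survival
  r <- cor(lat$censor_time, resid)
  expect_lt(abs(r), 3 / sqrt(nrow(lat)))
})

test_that("a null-effect configuration yields null true effects and the additivity identity", {
  null_cfg <- sim_config(n_patients = 100, seed = 1, aft_route_factor = 1,
                         cost_params = list(route_intensity_ratio = 1,
                                            predx_mean_ep = 100,
                                            predx_mean_gp = 100))
  te <- true_effects(null_cfg, n_oracle = 20000, seed = 2)
  expect_equal(te$total_cost_effect, 0, tolerance = 1e-9)
  expect_equal(te$intensity_effect, 0, tolerance = 1e-6)
  expect_equal(te$delta_surv_prob, 0, tolerance = 1e-12)
  expect_equal(te$yls, 0, tolerance = 1e-12)
  expect_equal(te$prediag_effect, 0)

  # survival-only difference with no end-of-life cost acceleration: the
  # intensity channel vanishes (with a terminal spike it legitimately
  # absorbs the routes' different proximity-to-death composition)
  surv_only <- sim_config(n_patients = 100, seed = 1, aft_route_factor = 2,
                          cost_params = list(route_intensity_ratio = 1,
                                             terminal_spike_mean = 0))
  te2 <- true_effects(surv_only, n_oracle = 20000, seed = 2)
  expect_lt(abs(te2$intensity_effect),
            0.02 * abs(te2$total_cost_effect) + 20)
  expect_gt(abs(te2$survival_effect), 0)

  # decomposition identity holds exactly for any configuration
  te3 <- true_effects(recovery_config(3, n = 100), n_oracle = 20000, seed = 5)
  expect_equal(te3$survival_effect + te3$intensity_effect,
               te3$total_cost_effect, tolerance = 1e-12)
})

test_that("site presets load and respect site structure", {
  for (s in c("colorectal", "breast", "prostate", "lung")) {
    cfg <- site_preset(s, n_patients = 400, seed = 8)
    ch <- simulate_cohort(cfg)
    expect_equal(ch$site, s)
    expect_equal(ch$horizon, site_horizon(s))
    if (s == "breast") expect_true(all(ch$patients$sex == "F"))
    if (s == "prostate") expect_true(all(ch$patients$sex == "M"))
    expect_true(all(ch$costs$month_index <= ch$horizon - 1))
  }
})
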