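test_that("interval grids have the documented structure", {
  expect_equal(length(build_grid(60, "monthly")$boundaries) - 1, 60)
  expect_equal(length(build_grid(36, "monthly")$boundaries) - 1, 36)
  expect_equal(length(build_grid(36, "monthly12_then_quarterly")$boundaries) - 1, 20)
  expect_equal(length(build_grid(60, "monthly12_then_quarterly")$boundaries) - 1, 28)
  g <- build_grid(60)
  expect_equal(g$boundaries[1], 0)
  expect_equal(g$boundaries[length(g$boundaries)], 60)
  expect_true(all(diff(g$boundaries) > 0))
  expect_error(build_grid(48), "horizon")
})

test_that("a no-death constant-cost cohort gives zero hazards and cost c per month", {
  ch <- constant_cost_cohort(n_per_route = 4, cost = 100)
  fit <- bm_fit(ch, build_grid(60, "monthly"))
  h <- vapply(fit$parts, function(p) p$hazard$value, numeric(1))
  expect_true(all(h == 0))
  for (m in c(1, 12, 37, 60)) {
    expect_equal(expected_cumulative_cost(fit, "EP", m), 100 * m,
                 tolerance = 1e-9)
    expect_equal(expected_cumulative_cost(fit, "GPTWW", m), 100 * m,
                 tolerance = 1e-9)
  }
  expect_error(expected_cumulative_cost(fit, "EP", 13.5), "boundary")
})

test_that("an intercept-only saturated interval reproduces the empirical hazard", {
  # 10 at risk in month 1, 5 die there
  p <- do.call(rbind, lapply(1:10, function(i)
    patient_row(sprintf("S%02d", i), route = "EP",
                t = if (i <= 5) 0.5 else 61, event = as.integer(i <= 5))))
  co <- data.frame(patient_id = "S06", month_index = 0, cost_gbp = 10)
  ch <- cohort_table(p, co, "colorectal")
  fit <- bm_fit(ch, build_grid(60, "monthly"))
  pr <- reroutecost:::interval_predictions(fit, "EP")
  expect_equal(unique(pr$h[, 1]), 0.5, tolerance = 1e-6)
})

test_that("on uncensored data the estimator equals the empirical mean cumulative cost", {
  ch <- uncensored_cohort(n = 30, seed = 5)
  grid <- build_grid(60, "monthly")
  fit <- bm_fit(ch, grid, min_decedents = 1L)
  panel <- reroutecost:::make_panel(ch, grid, character(0))
  for (r in c("EP", "GPTWW")) {
    sel <- ch$patients$route == r
    for (m in c(12, 60)) {
      emp <- mean(rowSums(panel$cost_mat[sel, seq_len(m), drop = FALSE]))
      est <- expected_cumulative_cost(fit, r, m,
                                      population = ch$patients[sel, ])
      expect_equal(est, emp, tolerance = 1e-8)
    }
  }
})

test_that("fitted interval hazards recover the Weibull closed form", {
  cfg <- sim_config(n_patients = 12000, seed = 6, p_ep_base = 0.4,
                    weibull_shape = 1, weibull_scale_ep = 20,
                    aft_route_factor = 2,
                    entry_window_months = 36, admin_cutoff_month = 72)
  ch <- simulate_cohort(cfg)
  fit <- bm_fit(ch, build_grid(60, "monthly"))
  pr <- reroutecost:::interval_predictions(fit, "EP")
  n_ep <- sum(ch$patients$route == "EP")
  h_true <- 1 - exp(-1 / 20)      # constant monthly hazard for k = 1
  for (j in c(1, 3, 6, 9, 12)) {
    at_risk <- n_ep * exp(-(j - 1) / 20)
    se <- sqrt(h_true * (1 - h_true) / at_risk)
    expect_lt(abs(mean(pr$h[, j]) - h_true), 3 * se)
  }
})

test_that("decomposition algebra: swapped components isolate each channel", {
  cc <- reroutecost:::cumulate_curve
  set.seed(1)
  n <- 7; J <- 5
  h_e <- matrix(runif(n * J, 0.05, 0.3), n, J)
  h_g <- matrix(runif(n * J, 0.02, 0.2), n, J)
  cost_e <- list(muD = matrix(runif(n * J, 500, 3000), n, J),
                 muS = matrix(runif(n * J, 100, 500), n, J))
  # identical cost components, different hazards: intensity channel is zero
  mu_ep <- cc(h_e, cost_e$muD, cost_e$muS)
  mu_tilde <- cc(h_e, cost_e$muD, cost_e$muS)
  expect_identical(mu_tilde - mu_ep, rep(0, J + 1))
  # identical hazards, different costs: survival channel is zero
  cost_g <- list(muD = cost_e$muD * 1.5, muS = cost_e$muS * 0.7)
  mu_gp <- cc(h_e, cost_g$muD, cost_g$muS)
  mu_tilde2 <- cc(h_e, cost_g$muD, cost_g$muS)
  total <- mu_gp - mu_ep
  intensity <- mu_tilde2 - mu_ep
  expect_equal(total - intensity, rep(0, J + 1), tolerance = 1e-12)
  # survival weights: S_0 = 1 and non-increasing
  S <- t(apply(1 - h_e, 1, cumprod))
  expect_true(all(S <= 1 + 1e-12))
  expect_true(all(diff(t(cbind(1, S))) <= 1e-12))
})

test_that("decomposition additivity holds on fitted models at every month", {
  for (s in c(2, 7)) {
    ch <- simulate_cohort(recovery_config(seed = s, n = 1200))
    for (scheme in c("monthly12_then_quarterly", "monthly")) {
      fit <- bm_fit(ch, build_grid(60, scheme))
      cur <- decompose_effect(fit)
      expect_lt(max(abs(cur$total - cur$survival - cur$intensity)), 1e-9)
      expect_equal(cur$total[1], 0)
    }
  }
})

test_that("sequential and shapley decompositions share the same total", {
  ch <- simulate_cohort(recovery_config(seed = 3, n = 1500))
  fit <- bm_fit(ch)
  seq_ <- decompose_effect(fit, order = "sequential")
  sha <- decompose_effect(fit, order = "shapley")
  expect_equal(seq_$total, sha$total, tolerance = 1e-12)
  expect_lt(max(abs(sha$total - sha$survival - sha$intensity)), 1e-9)
})

test_that("pre-diagnosis cost effect recovers the generating difference", {
  # EP mean 100/month vs GP 55/month over 12 months: effect about -540
  cfg <- sim_config(n_patients = 4000, seed = 12, p_ep_base = 0.5,
                    cost_params = list(predx_mean_ep = 100, predx_mean_gp = 55))
  ch <- simulate_cohort(cfg)
  eff <- prediag_cost_effect(ch)
  expect_lt(abs(eff - (-540)), 60)
  expect_lt(eff, 0)  # sign convention: EP dearer before diagnosis => negative
  expect_error(prediag_cost_effect(constant_cost_cohort(2)), "pre-diagnosis")
})

test_that("estimates are robust to administrative censoring", {
  # same underlying population (same seed), with and without censoring
  cfg_cens <- recovery_config(seed = 9, n = 6000)
  cfg_full <- cfg_cens
  cfg_full$entry_window_months <- 1
  cfg_full$admin_cutoff_month <- 1000
  ch_c <- simulate_cohort(cfg_cens)
  ch_f <- simulate_cohort(cfg_full)
  expect_gt(mean(ch_c$patients$event == 0), 0.2)
  d_c <- decompose_effect(bm_fit(ch_c, covariates = recovery_covariates))
  d_f <- decompose_effect(bm_fit(ch_f, covariates = recovery_covariates))
  # ~3 Monte-Carlo SEs of the total-effect estimate at this n
  expect_lt(abs(d_c$total[nrow(d_c)] - d_f$total[nrow(d_f)]), 900)
})

test_that("bootstrap bands are seed-deterministic and shrink with n", {
  boot_cfg <- function(s, n) sim_config(n_patients = n, seed = s,
                                        weibull_scale_ep = 30,
                                        entry_window_months = 36,
                                        admin_cutoff_month = 96)
  ch <- simulate_cohort(boot_cfg(21, 500))
  b1 <- bootstrap_curves(ch, covariates = character(0), n_reps = 2, seed = 77)
  b2 <- bootstrap_curves(ch, covariates = character(0), n_reps = 2, seed = 77)
  expect_identical(b1$lo, b2$lo)
  expect_identical(b1$hi, b2$hi)
  expect_true(all(b1$lo <= b1$hi))

  w <- vapply(c(400, 1600), function(n) {
    chn <- simulate_cohort(boot_cfg(31, n))
    bb <- bootstrap_curves(chn, covariates = character(0), n_reps = 30,
                           seed = 5)
    bb$hi[nrow(bb)] - bb$lo[nrow(bb)]
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("bootstrap bands cover zero under a null effect", {
  # longer survival and full follow-up keep late risk sets populated at
  # this small n
  null_cfg <- function(s) sim_config(n_patients = 400, seed = s,
                                     aft_route_factor = 1,
                                     cost_params = list(route_intensity_ratio = 1),
                                     weibull_scale_ep = 30,
                                     entry_window_months = 36,
                                     admin_cutoff_month = 96)
  covered <- vapply(1:5, function(s) {
    ch <- simulate_cohort(null_cfg(s))
    bb <- bootstrap_curves(ch, covariates = character(0), n_reps = 30, seed = s)
    J <- nrow(bb)
    bb$lo[J] <= 0 && bb$hi[J] >= 0
  }, logical(1))
  expect_gte(sum(covered), 4)
})
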