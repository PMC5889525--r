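# Shared fixture builders.  Everything is generated in code; no data files.

# minimal hand-written patient row
patient_row <- function(id, route = "EP", t = 61, event = 0, age = 70,
                        sex = "F", site = "colorectal") {
  df <- data.frame(patient_id = id, site = site, route = route, age = age,
                   sex = sex, imd_income = 0.1, region = "R1",
                   n_codiag = 1, surgery_12m = 0,
                   time_to_event = t, event = event,
                   stringsAsFactors = FALSE)
  for (cc in reroutecost:::.charlson_cols) df[[cc]] <- 0
  df
}

# cohort of n patients per route with constant monthly cost, no deaths, no
# censoring before the horizon
constant_cost_cohort <- function(n_per_route = 4, cost = 100, site = "colorectal") {
  horizon <- site_horizon(site)
  p <- do.call(rbind, lapply(seq_len(2 * n_per_route), function(i) {
    patient_row(sprintf("C%02d", i),
                route = if (i <= n_per_route) "EP" else "GPTWW",
                t = horizon + 1, event = 0, site = site)
  }))
  co <- expand.grid(patient_id = p$patient_id, month_index = 0:(horizon - 1),
                    stringsAsFactors = FALSE)
  co$cost_gbp <- cost
  cohort_table(p, co, site = site)
}

# uncensored random cohort: every patient followed to death or the horizon
uncensored_cohort <- function(n = 30, seed = 5, p_zero = 0.2, ratio = 1.5) {
  cfg <- sim_config(n_patients = n, seed = seed, p_ep_base = 0.5,
                    weibull_shape = 1, weibull_scale_ep = 15,
                    aft_route_factor = 2,
                    cost_params = list(p_zero = p_zero, gamma_shape = 1,
                                       route_intensity_ratio = ratio),
                    entry_window_months = 1, admin_cutoff_month = 1000)
  simulate_cohort(cfg)
}

# the frozen parameter-recovery configuration: n = 10,000, confounded route
# assignment, known Weibull and cost laws, ~30% administrative censoring
recovery_config <- function(seed = 1L, n = 10000L) {
  sim_config(n_patients = n, seed = seed,
             p_ep_base = 0.3,
             confounding_coefs = c(age = 0.3, imd = 0.2, comorb = 0.15),
             weibull_shape = 1, weibull_scale_ep = 18, aft_route_factor = 2.6,
             covariate_coefs_survival = c(age = -0.2, imd = -0.05, comorb = -0.1),
             cost_params = list(route_intensity_ratio = 1.6,
                                gamma_shape = 2, p_zero = 0.2),
             entry_window_months = 42, admin_cutoff_month = 63)
}

recovery_covariates <- c("age", "imd_income", "n_codiag")
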