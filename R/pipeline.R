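# End-to-end orchestration: simulate (or read) a cohort, fit the three-part
# cost estimator and the Weibull AFT survival model, assemble the site
# ledger, and optionally scale to a CCG policy scenario.  Every output file
# carries the configuration hash so reruns with identical configuration are
# recognisable; identical seeds give identical numbers.

#' Configure a pipeline run
#'
#' @param site cancer site; sets the horizon.
#' @param sim a [sim_config()] to simulate the cohort, or `NULL` when
#'   reading from files.
#' @param patient_path,cost_path CSV inputs, used when `sim` is `NULL`.
#' @param covariates risk-adjustment columns for both estimators.
#' @param grid_scheme interval grid scheme (see [build_grid()]).
#' @param econ a [referral_economics()]; defaults to the shipped published
#'   rates for the site.
#' @param bootstrap_reps bootstrap replicates for the effect-curve bands
#'   (0 disables the bootstrap).
#' @param ccg_table optional [ccg_share_table()] (or path to its CSV) to run
#'   the policy scale-up stage.
#' @param top_fraction benchmark quantile for the policy stage.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory; created if missing.  `NULL` disables
#'   file output.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(site = "colorectal", sim = site_preset(site),
                            patient_path = NULL, cost_path = NULL,
                            covariates = c("age", "imd_income", "n_codiag"),
                            grid_scheme = "monthly12_then_quarterly",
                            econ = NULL, bootstrap_reps = 0L,
                            ccg_table = NULL, top_fraction = 0.2,
                            seed = 1L, out_dir = NULL) {
  site <- match.arg(site, .sites)
  if (is.null(econ)) {
    ref <- reference_components()$sites[[site]]
    econ <- referral_economics(ref$conversion_rate, ref$cost_per_test)
  }
  fail_if(is.null(sim) && (is.null(patient_path) || is.null(cost_path)),
          "either `sim` or both input paths must be given")
  structure(list(site = site, sim = sim, patient_path = patient_path,
                 cost_path = cost_path, covariates = covariates,
                 grid_scheme = grid_scheme, econ = econ,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ccg_table = ccg_table, top_fraction = top_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full rerouting-cost pipeline
#'
#' Stages: simulate/read cohort, fit the three-part cost model and decompose
#' the route effect, estimate the pre-diagnosis cost difference, fit the
#' Weibull AFT model, assemble the site ledger, and (when a CCG table is
#' supplied) benchmark and scale to a policy scenario.  When `out_dir` is
#' set, writes `curves.csv`, `ledger.json`, `policy.json`, a cumulative
#' effect plot (`curves.pdf`) and `run_log.json` with the configuration
#' hash, seed and wall-clock time per stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `cohort`, `bm`, `curves`, `prediag`,
#'   `aft`, `surv`, `ledger`, `policy` (or `NULL`), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  horizon <- site_horizon(config$site)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_cohort(sim)
    } else read_cohort(config$patient_path, config$cost_path, config$site)
  })

  grid <- build_grid(horizon, config$grid_scheme)
  fit <- stage("fit_bm", bm_fit(cohort, grid, config$covariates))
  curves <- stage("curves", {
    if (config$bootstrap_reps >= 2)
      bootstrap_curves(cohort, grid, config$covariates,
                       n_reps = config$bootstrap_reps, seed = config$seed)
    else decompose_effect(fit)
  })
  prediag <- stage("prediag", prediag_cost_effect(cohort, config$covariates))
  aft <- stage("fit_survival", fit_weibull_aft(cohort, config$covariates))
  surv <- stage("yls", years_of_life_saved(aft, tau = horizon))
  ledger <- stage("ledger",
                  build_ledger(config$econ, prediag, curves, surv, horizon,
                               site = config$site))

  policy <- NULL
  if (!is.null(config$ccg_table)) {
    policy <- stage("policy", {
      tab <- config$ccg_table
      if (is.character(tab))
        tab <- utils::read.csv(tab, stringsAsFactors = FALSE)
      tab <- ccg_share_table(tab)
      bench <- benchmark_share(tab, config$top_fraction)
      n <- rerouted_counts(tab, bench, config$site)
      entry <- scale_policy(ledger, config$econ, n)
      entry$benchmark_share <- bench
      entry
    })
  }

  log <- list(package_version = as.character(utils::packageVersion("reroutecost")),
              r_version = R.version.string,
              config_hash = hash, seed = config$seed,
              site = config$site, horizon = horizon,
              n_patients = nrow(cohort$patients),
              stage_seconds = as.list(timings))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    cdf <- as.data.frame(curves)
    cdf$config_hash <- hash
    utils::write.csv(cdf, out("curves.csv"), row.names = FALSE)
    jsonlite::write_json(c(list(config_hash = hash, site = config$site),
                           lapply(unclass(ledger), identity)),
                         out("ledger.json"), auto_unbox = TRUE, digits = NA,
                         na = "null")
    if (!is.null(policy))
      jsonlite::write_json(c(list(config_hash = hash),
                             lapply(unclass(policy), identity)),
                           out("policy.json"), auto_unbox = TRUE, digits = NA)
    grDevices::pdf(out("curves.pdf"), width = 7, height = 5)
    plot(curves, main = sprintf("Cumulative cost effect, %s", config$site))
    grDevices::dev.off()
    jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE)
  }

  invisible(list(cohort = cohort, bm = fit, curves = curves, prediag = prediag,
                 aft = aft, surv = surv, ledger = ledger, policy = policy,
                 log = log))
}
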