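# Censored-cost three-part estimator.  Follow-up is partitioned into
# intervals; within each interval j three models are fitted on the interval
# risk set (patients alive at the interval start and not censored before its
# end):
#   * a probit (optionally logit) model for death within the interval,
#   * a hurdle-gamma GLM for the interval cost of decedents,
#   * a hurdle-gamma GLM for the interval cost of interval survivors.
# Expected cumulative cost for a covariate row x with route forced is
#   mu(m; x) = sum_{j : end(j) <= m} S_{j-1}(x) [h_j(x) muD_j(x) +
#                                                (1 - h_j(x)) muS_j(x)],
# with S_{j-1}(x) = prod_{k<j} (1 - h_k(x)), averaged over a reference
# population (recycled predictions).  The route effect on cumulative cost is
# decomposed into an intensity channel (swap in the referred route's cost
# models while keeping EP survival) and a residual survival channel.

#' Build an interval grid over the follow-up horizon
#'
#' @param horizon follow-up horizon in months (36 or 60).
#' @param scheme `"monthly"` for unit intervals throughout, or
#'   `"monthly12_then_quarterly"` for 12 monthly intervals followed by
#'   quarterly ones (the default estimation grid: later intervals are wider
#'   so the per-interval decedent cost models keep enough events).
#' @return an `interval_grid`: list with `boundaries` (month offsets starting
#'   at 0 and ending at `horizon`) and `scheme`.
#' @export
build_grid <- function(horizon, scheme = c("monthly12_then_quarterly", "monthly")) {
  scheme <- match.arg(scheme)
  fail_if(!horizon %in% c(36L, 60L), "unsupported horizon %s (use 36 or 60)",
          as.character(horizon))
  b <- if (scheme == "monthly") 0:horizon
       else c(0:12, seq(15L, horizon, by = 3L))
  structure(list(boundaries = as.integer(b), horizon = as.integer(horizon),
                 scheme = scheme),
            class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %d intervals over %d months (%s)\n",
              length(x$boundaries) - 1L, x$horizon, x$scheme))
  invisible(x)
}

# ---- hurdle-gamma cost model ------------------------------------------------

# tight IRLS convergence so saturated fits reproduce sample means to
# near machine precision
.glm_ctl <- function() stats::glm.control(epsilon = 1e-12, maxit = 100)

# Fit P(cost > 0) x E[cost | cost > 0] on one data frame.  Falls back to
# intercept-only parts when the full design cannot be fitted (tiny or
# degenerate strata), recording the fallback.
fit_hurdle <- function(df, rhs) {
  y <- df$.y
  pos <- y > 0
  out <- list(type = "hurdle", fallback = FALSE)
  if (!any(pos)) return(list(type = "zero", fallback = FALSE))
  if (all(pos)) {
    out$p_model <- NULL
    out$p_const <- 1
  } else {
    out$p_model <- tryCatch(
      suppressWarnings(stats::glm(stats::reformulate(rhs, response = ".pos"),
                                  family = stats::binomial("logit"),
                                  control = .glm_ctl(),
                                  data = transform(df, .pos = pos))),
      error = function(e) NULL)
    if (is.null(out$p_model)) {
      out$p_const <- mean(pos)
      out$fallback <- TRUE
    }
  }
  out$g_model <- tryCatch(
    suppressWarnings(stats::glm(stats::reformulate(rhs, response = ".y"),
                                family = stats::Gamma(link = "log"),
                                control = .glm_ctl(),
                                data = df[pos, , drop = FALSE])),
    error = function(e) NULL)
  if (is.null(out$g_model)) {
    out$g_const <- mean(y[pos])
    out$fallback <- TRUE
  }
  out
}

predict_hurdle <- function(model, newdata) {
  n <- nrow(newdata)
  if (model$type == "zero") return(numeric(n))
  p <- if (!is.null(model$p_model))
    suppressWarnings(stats::predict(model$p_model, newdata = newdata,
                                    type = "response"))
  else rep(if (is.null(model$p_const)) 1 else model$p_const, n)
  g <- if (!is.null(model$g_model))
    suppressWarnings(stats::predict(model$g_model, newdata = newdata,
                                    type = "response"))
  else rep(model$g_const, n)
  as.numeric(p * g)
}

# ---- interval panel ---------------------------------------------------------

# Precompute, once per cohort, everything the per-interval fits need:
# per-patient interval cost matrix, last observed month, death interval.
make_panel <- function(cohort, grid, covariates) {
  validate_cohort(cohort)
  p <- cohort$patients
  b <- grid$boundaries
  J <- length(b) - 1L
  fail_if(grid$horizon != cohort$horizon,
          "grid horizon %d does not match cohort horizon %d",
          grid$horizon, cohort$horizon)
  bad <- setdiff(covariates, names(p))
  fail_if(length(bad) > 0, "unknown covariate(s): %s", paste(bad, collapse = ", "))

  # month of death/censoring, uncapped: a patient with follow-up past the
  # horizon is a survivor of every interval
  fu_m <- floor(p$time_to_event)
  dies <- p$event == 1 & fu_m <= cohort$horizon - 1L
  death_int <- rep(NA_integer_, nrow(p))
  death_int[dies] <- findInterval(floor(p$time_to_event[dies]), b,
                                  rightmost.closed = FALSE)

  cost_mat <- matrix(0, nrow(p), J)
  co <- cohort$costs[cohort$costs$month_index >= 0, , drop = FALSE]
  if (nrow(co) > 0) {
    row <- match(co$patient_id, p$patient_id)
    col <- findInterval(co$month_index, b)
    li <- (col - 1L) * nrow(p) + row
    agg <- rowsum(co$cost_gbp, li)
    cost_mat[as.integer(rownames(agg))] <- agg[, 1]
  }

  prediag <- numeric(nrow(p))
  pre <- cohort$costs[cohort$costs$month_index < 0, , drop = FALSE]
  if (nrow(pre) > 0) {
    s <- tapply(pre$cost_gbp, factor(pre$patient_id, levels = p$patient_id), sum)
    prediag <- ifelse(is.na(s), 0, as.numeric(s))
  }

  list(patients = p, cost_mat = cost_mat, prediag = prediag,
       fu_m = fu_m, dies = dies, death_int = death_int,
       grid = grid, covariates = covariates,
       rhs = c("route", covariates), horizon = cohort$horizon,
       site = cohort$site)
}

# Fit the three parts on (a resample of) a panel.  `rows` indexes patients.
fit_bm_panel <- function(panel, rows = seq_len(nrow(panel$patients)),
                         hazard_link = "probit", min_decedents = 5L) {
  b <- panel$grid$boundaries
  J <- length(b) - 1L
  p <- panel$patients[rows, , drop = FALSE]
  cost <- panel$cost_mat[rows, , drop = FALSE]
  fu_m <- panel$fu_m[rows]
  dies <- panel$dies[rows]
  death_int <- panel$death_int[rows]
  rhs <- panel$rhs

  parts <- vector("list", J)
  for (j in seq_len(J)) {
    b0 <- b[j]; b1 <- b[j + 1L]
    died_j <- dies & death_int == j
    # at risk: alive at interval start and not censored before interval end
    at_risk <- (fu_m >= b0) & (died_j | fu_m >= b1)
    fail_if(!any(at_risk), "empty risk set in interval %d (months %d-%d)",
            j, b0, b1)
    df <- p[at_risk, , drop = FALSE]
    df$.died <- died_j[at_risk]
    df$.y <- cost[at_risk, j]

    n_dec <- sum(df$.died)
    if (n_dec == 0L) {
      hz <- list(type = "const", value = 0)
    } else if (n_dec == sum(at_risk)) {
      hz <- list(type = "const", value = 1)
    } else {
      m <- tryCatch(
        suppressWarnings(stats::glm(stats::reformulate(rhs, response = ".died"),
                                    family = stats::binomial(hazard_link),
                                    control = .glm_ctl(),
                                    data = df)),
        error = function(e) NULL)
      hz <- if (is.null(m)) list(type = "const", value = mean(df$.died))
            else list(type = "glm", model = m)
    }

    # decedent cost model; pool decedents forward across intervals when the
    # interval has fewer than `min_decedents` events
    pooled <- j
    dec_rows <- which(dies & death_int == j)
    jj <- j
    while (length(dec_rows) > 0 && length(dec_rows) < min_decedents && jj < J) {
      jj <- jj + 1L
      pooled <- c(pooled, jj)
      dec_rows <- c(dec_rows, which(dies & death_int == jj))
    }
    dec_model <- if (length(dec_rows) == 0L) NULL else {
      ddf <- p[dec_rows, , drop = FALSE]
      ddf$.y <- cost[cbind(dec_rows, death_int[dec_rows])]
      fit_hurdle(ddf, rhs)
    }

    sdf <- df[!df$.died, , drop = FALSE]
    surv_model <- fit_hurdle(sdf, rhs)

    parts[[j]] <- list(hazard = hz, decedent = dec_model,
                       survivor = surv_model, n_at_risk = sum(at_risk),
                       n_deaths = n_dec, pooled_intervals = pooled)
  }

  structure(list(parts = parts, grid = panel$grid,
                 covariates = panel$covariates, rhs = rhs,
                 population = p, prediag = panel$prediag[rows],
                 site = panel$site, horizon = panel$horizon,
                 hazard_link = hazard_link,
                 n = nrow(p), n_deaths = sum(dies)),
            class = "bm_fit")
}

#' Fit the censored-cost three-part estimator
#'
#' @param cohort a [cohort_table()].
#' @param grid an [build_grid()] interval grid; defaults to 12 monthly then
#'   quarterly intervals over the cohort horizon.
#' @param covariates character vector of patient-table columns used for risk
#'   adjustment (route is always included in every part's design).
#' @param hazard_link `"probit"` (default) or `"logit"` link for the
#'   within-interval death model.
#' @param min_decedents intervals with fewer decedents than this pool their
#'   decedent cost model with the neighbouring later interval(s).
#' @return an object of class `bm_fit` with per-interval hazard, decedent
#'   cost and survivor cost model parts.
#' @seealso [expected_cumulative_cost()], [decompose_effect()],
#'   [bootstrap_curves()]
#' @export
bm_fit <- function(cohort, grid = build_grid(cohort$horizon),
                   covariates = character(0),
                   hazard_link = c("probit", "logit"), min_decedents = 5L) {
  hazard_link <- match.arg(hazard_link)
  panel <- make_panel(cohort, grid, covariates)
  fit_bm_panel(panel, hazard_link = hazard_link, min_decedents = min_decedents)
}

# ---- prediction -------------------------------------------------------------

force_route <- function(population, route) {
  route <- match.arg(route, .routes)
  population$route <- factor(route, levels = .routes)
  population
}

# n x J matrices of interval predictions with route forced
interval_predictions <- function(fit, route, population = NULL) {
  pop <- force_route(if (is.null(population)) fit$population else population,
                     route)
  J <- length(fit$parts)
  n <- nrow(pop)
  h <- muD <- muS <- matrix(0, n, J)
  for (j in seq_len(J)) {
    part <- fit$parts[[j]]
    h[, j] <- if (part$hazard$type == "const") part$hazard$value
              else pmin(pmax(suppressWarnings(
                stats::predict(part$hazard$model, newdata = pop,
                               type = "response")), 0), 1)
    muD[, j] <- if (is.null(part$decedent)) 0
                else pmax(predict_hurdle(part$decedent, pop), 0)
    muS[, j] <- pmax(predict_hurdle(part$survivor, pop), 0)
  }
  list(h = h, muD = muD, muS = muS)
}

# population-mean cumulative cost at every grid boundary given interval
# predictions; S_0 = 1, S_j = prod_{k<=j} (1 - h_k)
cumulate_curve <- function(h, muD, muS) {
  n <- nrow(h); J <- ncol(h)
  S <- rep(1, n)
  cum <- rep(0, n)
  out <- numeric(J + 1L)
  for (j in seq_len(J)) {
    cum <- cum + S * (h[, j] * muD[, j] + (1 - h[, j]) * muS[, j])
    S <- S * (1 - h[, j])
    out[j + 1L] <- mean(cum)
  }
  out
}

#' Expected cumulative cost under a forced route
#'
#' Averages the three-part model's expected cumulative post-diagnosis cost up
#' to a grid boundary over a reference population with the route forced
#' (recycled predictions).
#'
#' @param fit a [bm_fit()].
#' @param route `"EP"` or `"GPTWW"`.
#' @param upto month at which the cumulative cost is evaluated; must be an
#'   interval boundary of the fitted grid.
#' @param population optional covariate rows; defaults to the pooled
#'   estimation sample.
#' @return expected cumulative cost in GBP.
#' @export
expected_cumulative_cost <- function(fit, route, upto = fit$horizon,
                                     population = NULL) {
  stopifnot(inherits(fit, "bm_fit"))
  b <- fit$grid$boundaries
  fail_if(!upto %in% b, "upto = %s is not aligned to a grid boundary",
          as.character(upto))
  pr <- interval_predictions(fit, route, population)
  curve <- cumulate_curve(pr$h, pr$muD, pr$muS)
  curve[match(upto, b)]
}

#' Decompose the route effect on cumulative cost
#'
#' With EP as baseline, the total effect at month m is
#' `Delta(m) = mu_GPTWW(m) - mu_EP(m)`.  The intensity effect replaces the EP
#' cost models with the GPTWW ones while keeping EP survival,
#' `I(m) = mu~(m) - mu_EP(m)`; the survival effect is the remainder
#' `Delta(m) - I(m)`.  Negative values mean the referred route is
#' cost-saving.  `order = "shapley"` averages the two decomposition paths
#' (intensity-first and survival-first) instead.
#'
#' @param fit a [bm_fit()].
#' @param population optional covariate rows (defaults to the pooled sample).
#' @param order `"sequential"` (EP baseline, intensity first; default) or
#'   `"shapley"`.
#' @return a `cost_effect_curves` data frame with columns `month`, `total`,
#'   `survival`, `intensity`, one row per grid boundary (month 0 is zero).
#' @export
decompose_effect <- function(fit, population = NULL,
                             order = c("sequential", "shapley")) {
  stopifnot(inherits(fit, "bm_fit"))
  order <- match.arg(order)
  ep <- interval_predictions(fit, "EP", population)
  gp <- interval_predictions(fit, "GPTWW", population)
  mu_ep <- cumulate_curve(ep$h, ep$muD, ep$muS)
  mu_gp <- cumulate_curve(gp$h, gp$muD, gp$muS)
  mu_t1 <- cumulate_curve(ep$h, gp$muD, gp$muS)   # EP survival, GPTWW costs
  total <- mu_gp - mu_ep
  intensity <- if (order == "sequential") mu_t1 - mu_ep else {
    mu_t2 <- cumulate_curve(gp$h, ep$muD, ep$muS) # GPTWW survival, EP costs
    ((mu_t1 - mu_ep) + (mu_gp - mu_t2)) / 2
  }
  structure(data.frame(month = fit$grid$boundaries,
                       total = total,
                       survival = total - intensity,
                       intensity = intensity),
            class = c("cost_effect_curves", "data.frame"),
            order = order)
}

#' Patient-level bootstrap bands for the effect curves
#'
#' Resamples patients with replacement, refits the three-part model on each
#' resample and returns 2.5/97.5 percentile bands for the total effect curve
#' (and each channel).  Resamples in which one route arm comes up empty are
#' redrawn; the number of redraws is recorded as an attribute.
#'
#' @param cohort a [cohort_table()].
#' @param grid interval grid.
#' @param covariates risk-adjustment columns.
#' @param n_reps number of bootstrap replicates (>= 2).
#' @param seed RNG seed; identical seeds give identical bands.
#' @inheritParams bm_fit
#' @return a `cost_effect_curves` data frame with extra columns `lo`, `hi`
#'   (total-effect band) plus `survival_lo/hi`, `intensity_lo/hi`.
#' @export
bootstrap_curves <- function(cohort, grid = build_grid(cohort$horizon),
                             covariates = character(0), n_reps = 200L,
                             seed = 1L, hazard_link = c("probit", "logit"),
                             min_decedents = 5L) {
  hazard_link <- match.arg(hazard_link)
  fail_if(n_reps < 2, "n_reps must be >= 2")
  panel <- make_panel(cohort, grid, covariates)
  fit0 <- fit_bm_panel(panel, hazard_link = hazard_link,
                       min_decedents = min_decedents)
  point <- decompose_effect(fit0)
  n <- nrow(panel$patients)
  route <- panel$patients$route
  with_seed(seed, {
    redrawn <- 0L
    reps_t <- reps_s <- reps_i <- matrix(NA_real_,
                                         length(point$month), n_reps)
    for (r in seq_len(n_reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(route[idx])) == 2L) break
        redrawn <- redrawn + 1L
      }
      fr <- tryCatch(fit_bm_panel(panel, rows = idx,
                                  hazard_link = hazard_link,
                                  min_decedents = min_decedents),
                     error = function(e) NULL)
      if (is.null(fr)) { redrawn <- redrawn + 1L; next }
      cr <- decompose_effect(fr, population = panel$patients)
      reps_t[, r] <- cr$total
      reps_s[, r] <- cr$survival
      reps_i[, r] <- cr$intensity
    }
    q <- function(m, p) apply(m, 1, stats::quantile, probs = p, na.rm = TRUE)
    point$lo <- q(reps_t, 0.025); point$hi <- q(reps_t, 0.975)
    point$survival_lo <- q(reps_s, 0.025); point$survival_hi <- q(reps_s, 0.975)
    point$intensity_lo <- q(reps_i, 0.025); point$intensity_hi <- q(reps_i, 0.975)
    attr(point, "n_reps") <- n_reps
    attr(point, "n_redrawn") <- redrawn
    point
  })
}

#' Risk-adjusted pre-diagnosis cost difference
#'
#' Fits one hurdle-gamma GLM to each patient's total cost over months -12..-1
#' (missing months count as zero) and returns the recycled-prediction GPTWW
#' minus EP contrast.  Negative values mean referred patients cost less
#' before diagnosis.
#'
#' @param cohort a [cohort_table()].
#' @param covariates risk-adjustment columns.
#' @return GBP difference over the pre-diagnosis year.
#' @export
prediag_cost_effect <- function(cohort, covariates = character(0)) {
  validate_cohort(cohort)
  fail_if(!any(cohort$costs$month_index < 0),
          "cohort has no pre-diagnosis cost months")
  p <- cohort$patients
  pre <- cohort$costs[cohort$costs$month_index < 0, , drop = FALSE]
  s <- tapply(pre$cost_gbp, factor(pre$patient_id, levels = p$patient_id), sum)
  p$.y <- ifelse(is.na(s), 0, as.numeric(s))
  m <- fit_hurdle(p, c("route", covariates))
  mean(predict_hurdle(m, force_route(p, "GPTWW"))) -
    mean(predict_hurdle(m, force_route(p, "EP")))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("<bm_fit> %s cohort, %d patients (%d deaths), horizon %d months\n",
              x$site, x$n, x$n_deaths, x$horizon))
  cat(sprintf("  %d intervals (%s), hazard link %s\n",
              length(x$parts), x$grid$scheme, x$hazard_link))
  cat(sprintf("  design: route%s\n",
              if (length(x$covariates)) paste0(" + ",
                paste(x$covariates, collapse = " + ")) else " (intercept-only parts)"))
  invisible(x)
}

#' @export
summary.bm_fit <- function(object, ...) {
  tab <- data.frame(
    interval = seq_along(object$parts),
    start = object$grid$boundaries[-length(object$grid$boundaries)],
    end = object$grid$boundaries[-1],
    n_at_risk = vapply(object$parts, `[[`, numeric(1), "n_at_risk"),
    n_deaths = vapply(object$parts, `[[`, numeric(1), "n_deaths"))
  tab$pooled <- vapply(object$parts,
                       function(p) length(p$pooled_intervals) > 1L, logical(1))
  structure(list(fit = object, intervals = tab), class = "summary.bm_fit")
}

#' @export
print.summary.bm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-interval risk sets:\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bm_fit <- function(object, part = c("hazard", "decedent", "survivor"), ...) {
  part <- match.arg(part)
  get1 <- function(p) {
    m <- switch(part, hazard = if (p$hazard$type == "glm") p$hazard$model,
                decedent = if (!is.null(p$decedent)) p$decedent$g_model,
                survivor = p$survivor$g_model)
    if (is.null(m)) NULL else stats::coef(m)
  }
  cf <- lapply(object$parts, get1)
  nm <- unique(unlist(lapply(cf, names)))
  out <- matrix(NA_real_, length(cf), length(nm),
                dimnames = list(paste0("interval_", seq_along(cf)), nm))
  for (j in seq_along(cf)) if (!is.null(cf[[j]])) out[j, names(cf[[j]])] <- cf[[j]]
  out
}

#' Predict expected cumulative cost from a fitted three-part model
#'
#' @param object a `bm_fit`.
#' @param route `"EP"` or `"GPTWW"`.
#' @param upto grid boundary month.
#' @param population optional covariate rows.
#' @param ... unused.
#' @export
predict.bm_fit <- function(object, route = "GPTWW", upto = object$horizon,
                           population = NULL, ...) {
  expected_cumulative_cost(object, route, upto, population)
}

#' @export
plot.bm_fit <- function(x, ...) {
  plot(decompose_effect(x), ...)
}

#' Plot cumulative cost-effect curves
#'
#' Total effect in black, survival channel in blue, intensity channel in red;
#' shaded band (when present) is the bootstrap 95% interval for the total
#' effect.  Negative values mean the referred route is cost-saving.
#'
#' @param x a `cost_effect_curves` object.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cost_effect_curves <- function(x, main = "Cumulative cost effect of rerouting", ...) {
  rng <- range(unlist(x[setdiff(names(x), "month")]), 0, na.rm = TRUE)
  graphics::plot(x$month, x$total, type = "n", ylim = rng,
                 xlab = "Months from diagnosis",
                 ylab = "Cumulative cost difference (GBP)", main = main, ...)
  if (!is.null(x$lo))
    graphics::polygon(c(x$month, rev(x$month)), c(x$lo, rev(x$hi)),
                      col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::abline(h = 0, lty = 3)
  graphics::lines(x$month, x$total, lwd = 2)
  graphics::lines(x$month, x$survival, col = "blue", lwd = 2)
  graphics::lines(x$month, x$intensity, col = "red", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", "blue", "red"),
                   legend = c("Total", "Survival effect", "Intensity effect"))
  invisible(x)
}
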