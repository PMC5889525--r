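# Referral economics and the per-site aggregation chain:
#   a  non-conversion diagnostic cost per converted case, c (1 - r) / r
#   b  risk-adjusted pre-diagnosis (months -12..-1) cost difference
#   c1, d1  survival / intensity cost channels at 12 months
#   C, D    survival / intensity cost channels at the horizon
#   total_1yr = a + b + c1 + d1;  total_h = a + b + C + D
#   cost per survivor = total_h / delta_surv;  cost per YLS = total_h / yls
# Internal arithmetic is unrounded; report-time figures round half away from
# zero to the nearest pound.

#' Referral economics parameters
#'
#' @param conversion_rate share of positive cancer diagnoses among all
#'   two-week-wait referrals in a year, in (0, 1].  Published rates are
#'   3-decimal rounded; unrounded rates may be supplied to reproduce
#'   published non-conversion costs exactly.
#' @param cost_per_test GBP cost of one diagnostic test (>= 0).
#' @return a `referral_economics` list.
#' @export
referral_economics <- function(conversion_rate, cost_per_test) {
  fail_if(conversion_rate <= 0 || conversion_rate > 1,
          "conversion_rate must be in (0, 1]")
  fail_if(cost_per_test < 0, "cost_per_test must be non-negative")
  structure(list(conversion_rate = conversion_rate,
                 cost_per_test = cost_per_test),
            class = "referral_economics")
}

#' Non-conversion cost per converted case
#'
#' Each positive diagnosis requires `1/r` referrals, of which `1/r - 1` are
#' negative; their diagnostic-test costs are attributed to the positive case:
#' `c (1 - r) / r`.
#'
#' @param econ a [referral_economics()].
#' @return GBP per converted case.
#' @export
cost_per_converted_case <- function(econ) {
  stopifnot(inherits(econ, "referral_economics"))
  econ$cost_per_test * (1 - econ$conversion_rate) / econ$conversion_rate
}

new_site_ledger <- function(a, b, c1, d1, C, D, delta_surv, yls,
                            horizon, site = NA_character_) {
  total_1yr <- a + b + c1 + d1
  total_h <- a + b + C + D
  structure(list(site = site, horizon = horizon,
                 a = a, b = b, c1 = c1, d1 = d1, C = C, D = D,
                 delta_surv = delta_surv, yls = yls,
                 total_1yr = total_1yr, total_h = total_h,
                 cost_per_survivor = if (isTRUE(delta_surv != 0))
                   total_h / delta_surv else NA_real_,
                 cost_per_yls = if (isTRUE(yls != 0))
                   total_h / yls else NA_real_),
            class = "site_ledger")
}

#' Assemble a site ledger from estimator outputs
#'
#' @param econ a [referral_economics()].
#' @param prediag_effect GBP pre-diagnosis cost difference
#'   ([prediag_cost_effect()]).
#' @param bm_curves a `cost_effect_curves` object ([decompose_effect()]),
#'   defined at months 12 and `horizon`.
#' @param surv list with `delta_surv_prob` and `yls`
#'   ([years_of_life_saved()]).
#' @param horizon 60, or 36 for lung.
#' @param site optional site label.
#' @return a `site_ledger`; ratio fields are `NA` (flagged undefined) when
#'   their denominator is zero.
#' @export
build_ledger <- function(econ, prediag_effect, bm_curves, surv, horizon,
                         site = NA_character_) {
  fail_if(!all(c(12, horizon) %in% bm_curves$month),
          "effect curves must be defined at months 12 and %d", horizon)
  at <- function(m, col) bm_curves[[col]][match(m, bm_curves$month)]
  new_site_ledger(a = cost_per_converted_case(econ),
                  b = prediag_effect,
                  c1 = at(12, "survival"), d1 = at(12, "intensity"),
                  C = at(horizon, "survival"), D = at(horizon, "intensity"),
                  delta_surv = surv$delta_surv_prob, yls = surv$yls,
                  horizon = horizon, site = site)
}

#' Rebuild a site ledger from published components
#'
#' Bypass constructor used to verify the aggregation chain against published
#' per-site components (non-conversion cost, pre-diagnosis difference, the
#' four cost channels, survival-probability gap and years of life saved).
#'
#' @param a,b,c1,d1,C,D GBP components.
#' @param delta_surv,yls survival gap and years of life saved at the horizon.
#' @param horizon months.
#' @param site optional label.
#' @return a `site_ledger`.
#' @export
ledger_from_components <- function(a, b, c1, d1, C, D, delta_surv, yls,
                                   horizon = 60, site = NA_character_) {
  new_site_ledger(a, b, c1, d1, C, D, delta_surv, yls, horizon, site)
}

#' Report a ledger rounded to whole pounds
#'
#' @param ledger a `site_ledger`.
#' @return named numeric vector with every GBP field rounded half away from
#'   zero (survival gap and YLS left unrounded).
#' @export
ledger_report <- function(ledger) {
  stopifnot(inherits(ledger, "site_ledger"))
  c(a = round_gbp(ledger$a), b = round_gbp(ledger$b),
    c1 = round_gbp(ledger$c1), d1 = round_gbp(ledger$d1),
    total_1yr = round_gbp(ledger$total_1yr),
    C = round_gbp(ledger$C), D = round_gbp(ledger$D),
    total_h = round_gbp(ledger$total_h),
    delta_surv = ledger$delta_surv,
    cost_per_survivor = round_gbp(ledger$cost_per_survivor),
    yls = ledger$yls,
    cost_per_yls = round_gbp(ledger$cost_per_yls))
}

#' @export
print.site_ledger <- function(x, ...) {
  lab <- if (is.na(x$site)) "" else paste0(" (", x$site, ")")
  h_yr <- as.integer(round(x$horizon / 12))
  fmt <- function(v) if (is.na(v)) "undefined"
         else paste0(ifelse(v < 0, "-", ""), "£",
                     format(abs(round_gbp(v)), big.mark = ",", scientific = FALSE))
  cat(sprintf("<site_ledger>%s, horizon %d months\n", lab, x$horizon))
  cat(sprintf("  non-conversion cost per converted case (a)  %s\n", fmt(x$a)))
  cat(sprintf("  pre-diagnosis cost variation (b)            %s\n", fmt(x$b)))
  cat(sprintf("  survival / intensity at 12 months (c, d)    %s / %s\n",
              fmt(x$c1), fmt(x$d1)))
  cat(sprintf("  survival / intensity at %d years (C, D)      %s / %s\n",
              h_yr, fmt(x$C), fmt(x$D)))
  cat(sprintf("  total 1 year (a+b+c+d)                      %s\n", fmt(x$total_1yr)))
  cat(sprintf("  total %d years (a+b+C+D)                     %s\n", h_yr, fmt(x$total_h)))
  cat(sprintf("  survival-probability gap at %d years         %.3f\n", h_yr, x$delta_surv))
  cat(sprintf("  cost per patient surviving %d years          %s\n", h_yr,
              fmt(x$cost_per_survivor)))
  cat(sprintf("  years of life saved per rerouted patient    %.2f\n", x$yls))
  cat(sprintf("  cost per year of life saved                 %s\n", fmt(x$cost_per_yls)))
  invisible(x)
}

#' Published reference components shipped with the package
#'
#' Loads the per-site referral-economics parameters and ledger components of
#' the published English registry analysis of rerouting cancer diagnoses
#' (colorectal, breast, prostate, lung), together with the published policy
#' scale-up rows.  Used by [verify_reference_tables()] and available to users
#' as a worked numerical example.
#'
#' @return nested list with elements `sites` and `policy`.
#' @export
reference_components <- function() {
  path <- system.file("extdata", "reference_ledgers.json",
                      package = "reroutecost")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Verify the ledger and policy arithmetic against published tables
#'
#' Rebuilds every site ledger from the published components and recomputes
#' every derived row (totals at 1 year and at the horizon, cost per
#' survivor, cost per year of life saved), then rescales the published
#' per-patient rows by the published rerouted counts to reproduce the
#' aggregate policy rows.  Comparisons use report-time rounding to whole
#' pounds.
#'
#' Derived rows are checked step by step: the totals are rebuilt from the
#' published components, and each ratio row from the published rounded total
#' it chains from (`computed`).  A fully unrounded chain from the components
#' alone (`computed_chain`) is also reported; because the published
#' survival-probability gap carries only three decimals, that chain can
#' drift by a few pounds on the ratio rows (most visibly the lung cost per
#' survivor).
#'
#' @return list of two data frames: `ledger` (site, row, computed,
#'   computed_chain, published, diff) and `policy` (site, row, computed,
#'   published, diff, rel_diff).
#' @export
verify_reference_tables <- function() {
  ref <- reference_components()
  sites <- names(ref$sites)

  led <- do.call(rbind, lapply(sites, function(s) {
    r <- ref$sites[[s]]
    lg <- ledger_from_components(r$a, r$b, r$c1, r$d1, r$C, r$D,
                                 r$delta_surv, r$yls,
                                 horizon = r$horizon, site = s)
    rep_ <- ledger_report(lg)
    rows <- c("total_1yr", "total_h", "cost_per_survivor", "cost_per_yls")
    pub <- c(r$total_1yr, r$total_h, r$cost_per_survivor, r$cost_per_yls)
    stepwise <- c(rep_["total_1yr"], rep_["total_h"],
                  round_gbp(r$total_h / r$delta_surv),
                  round_gbp(r$total_h / r$yls))
    data.frame(site = s, row = rows, computed = unname(stepwise),
               computed_chain = unname(rep_[rows]),
               published = pub, diff = unname(stepwise) - pub,
               row.names = NULL)
  }))

  pol <- do.call(rbind, lapply(sites, function(s) {
    r <- ref$sites[[s]]
    pp <- ref$policy
    i <- match(s, pp$site)
    n <- pp$rerouted[i]
    computed <- c(yls_total = round(n * r$yls),
                  survivors = round(n * r$delta_surv),
                  total_cost_1yr = n * r$total_1yr,
                  total_cost_h = n * r$total_h)
    published <- c(pp$yls_total[i], pp$survivors[i],
                   pp$total_cost_1yr[i], pp$total_cost_h[i])
    data.frame(site = s, row = names(computed), computed = unname(computed),
               published = published, diff = unname(computed) - published,
               rel_diff = (unname(computed) - published) /
                 ifelse(published == 0, 1, abs(published)),
               row.names = NULL)
  }))
  list(ledger = led, policy = pol)
}
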