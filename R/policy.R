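# Policy experiment: benchmark every commissioning group (CCG) against the
# mean emergency-presentation share of the best-performing 20%, reroute the
# excess EP diagnoses to GP/TWW referral, and scale the per-patient site
# ledger to aggregate annual impact.

#' Validate a CCG share table
#'
#' @param df data frame with columns `ccg_id`, `ep_share` (in `[0, 1]`) and
#'   one annual-diagnoses column per site: `n_colorectal`, `n_breast`,
#'   `n_prostate`, `n_lung` (non-negative integers).
#' @return the validated data frame with class `ccg_share_table`.
#' @export
ccg_share_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("ccg_id", "ep_share", paste0("n_", .sites))
  missing <- setdiff(need, names(df))
  fail_if(length(missing) > 0, "CCG table is missing column(s): %s",
          paste(missing, collapse = ", "))
  fail_if(nrow(df) == 0, "CCG table is empty")
  fail_if(any(df$ep_share < 0 | df$ep_share > 1), "ep_share must lie in [0, 1]")
  for (s in paste0("n_", .sites)) {
    fail_if(any(df[[s]] < 0), "%s must be non-negative", s)
    fail_if(any(df[[s]] != floor(df[[s]])), "%s must be integer", s)
  }
  class(df) <- c("ccg_share_table", "data.frame")
  df
}

#' Benchmark EP share of the best-performing CCG quintile
#'
#' Sorts CCGs by ascending EP share, takes the lowest `floor(top_fraction
#' * N)` of them (at least one) and returns their mean share — unweighted by
#' default, diagnosis-weighted on request.
#'
#' @param table a [ccg_share_table()].
#' @param top_fraction fraction of CCGs defining the benchmark group
#'   (default 0.2).
#' @param weighted if `TRUE`, weight the benchmark mean by each CCG's total
#'   annual diagnoses across the four sites.
#' @return the benchmark EP share.
#' @export
benchmark_share <- function(table, top_fraction = 0.2, weighted = FALSE) {
  table <- ccg_share_table(table)
  n <- nrow(table)
  fail_if(n < ceiling(1 / top_fraction),
          "need at least %d CCGs for a %.0f%% benchmark",
          ceiling(1 / top_fraction), 100 * top_fraction)
  k <- max(1L, floor(top_fraction * n))
  ord <- order(table$ep_share)
  top <- table[ord[seq_len(k)], ]
  if (!weighted) mean(top$ep_share)
  else {
    w <- rowSums(top[paste0("n_", .sites)])
    sum(w * top$ep_share) / sum(w)
  }
}

#' Number of diagnoses rerouted under a benchmark
#'
#' Each CCG above the benchmark reroutes its excess share of the site's
#' annual diagnoses: `sum_g max(0, share_g - benchmark) * n_g`, rounded to
#' the nearest integer over the whole table.
#'
#' @param table a [ccg_share_table()].
#' @param benchmark EP share in `[0, 1]`.
#' @param site cancer site.
#' @return integer count of rerouted diagnoses.
#' @export
rerouted_counts <- function(table, benchmark, site) {
  table <- ccg_share_table(table)
  site <- match.arg(site, .sites)
  fail_if(benchmark < 0 || benchmark > 1, "benchmark must lie in [0, 1]")
  vol <- table[[paste0("n_", site)]]
  as.integer(round(sum(pmax(0, table$ep_share - benchmark) * vol)))
}

#' Scale a per-patient ledger to aggregate policy impact
#'
#' @param ledger a `site_ledger`.
#' @param econ a [referral_economics()]; its conversion rate sets how many
#'   referrals are needed per rerouted diagnosis.
#' @param rerouted number of diagnoses rerouted in the year (>= 0).
#' @return a `policy_entry` list with `rerouted`, `referrals_needed`,
#'   `non_converted` (referrals minus conversions), `total_cost_1yr`,
#'   `total_cost_horizon`, `survivors_at_horizon`, `yls_total`.
#' @export
scale_policy <- function(ledger, econ, rerouted) {
  stopifnot(inherits(ledger, "site_ledger"),
            inherits(econ, "referral_economics"))
  fail_if(rerouted < 0, "rerouted must be non-negative")
  referrals <- round(rerouted / econ$conversion_rate)
  structure(list(site = ledger$site,
                 rerouted = rerouted,
                 referrals_needed = referrals,
                 non_converted = referrals - rerouted,
                 total_cost_1yr = rerouted * ledger$total_1yr,
                 total_cost_horizon = rerouted * ledger$total_h,
                 survivors_at_horizon = round(rerouted * ledger$delta_surv),
                 yls_total = round(rerouted * ledger$yls)),
            class = "policy_entry")
}

#' @export
print.policy_entry <- function(x, ...) {
  lab <- if (is.na(x$site)) "" else paste0(" (", x$site, ")")
  cat(sprintf("<policy_entry>%s\n", lab))
  cat(sprintf("  rerouted diagnoses            %d\n", x$rerouted))
  cat(sprintf("  referrals needed              %d (%d non-converted)\n",
              x$referrals_needed, x$non_converted))
  cat(sprintf("  total cost, 1 year            £%s\n",
              format(round_gbp(x$total_cost_1yr), big.mark = ",")))
  cat(sprintf("  total cost, horizon           £%s\n",
              format(round_gbp(x$total_cost_horizon), big.mark = ",")))
  cat(sprintf("  additional survivors          %d\n", x$survivors_at_horizon))
  cat(sprintf("  years of life saved           %d\n", x$yls_total))
  invisible(x)
}

#' Simulate a CCG share table calibrated to target rerouted counts
#'
#' Draws `n_ccg` commissioning groups with all-cancer EP shares around the
#' English 2010-2013 distribution (mean about 0.24) and annual site volumes
#' exponentially tilted in the share so that [rerouted_counts()] under the
#' table's own 20% benchmark reproduces the requested per-site totals
#' exactly.  A single largest-excess CCG receives a final integer volume
#' adjustment per site to absorb rounding.
#'
#' @param n_ccg number of CCGs (default 200).
#' @param targets named integer vector of rerouted counts per site; defaults
#'   to the published policy totals.
#' @param annual_diagnoses named vector of national annual diagnoses per
#'   site; defaults to the totals implied by the published rerouted shares.
#' @param seed RNG seed.
#' @return a [ccg_share_table()].
#' @export
simulate_ccg_table <- function(n_ccg = 200L,
                               targets = NULL, annual_diagnoses = NULL,
                               seed = 1L) {
  if (is.null(targets) || is.null(annual_diagnoses)) {
    ref <- reference_components()$policy
    if (is.null(targets))
      targets <- stats::setNames(ref$rerouted, ref$site)
    if (is.null(annual_diagnoses))
      annual_diagnoses <- stats::setNames(
        round(ref$rerouted / ref$share_of_annual_diagnoses), ref$site)
  }
  fail_if(n_ccg < 10, "need at least 10 CCGs")
  with_seed(seed, {
    share <- pmin(pmax(stats::rnorm(n_ccg, 0.24, 0.02), 0.15), 0.35)
    w <- stats::rgamma(n_ccg, shape = 5)
    w <- w / sum(w)
    tab <- data.frame(ccg_id = sprintf("CCG%03d", seq_len(n_ccg)),
                      ep_share = share, stringsAsFactors = FALSE)
    for (s in .sites) tab[[paste0("n_", s)]] <- 0L
    tab <- ccg_share_table(tab)
    b <- benchmark_share(tab)
    e <- pmax(0, share - b)
    s_bar <- sum(w * share)
    for (s in .sites) {
      N <- annual_diagnoses[[s]]
      R <- targets[[s]]
      # exponential volume tilt in the share: sites whose rerouted share of
      # annual diagnoses is below (above) the table average concentrate
      # volume in low-share (high-share) CCGs
      excess_frac <- function(theta) {
        wt <- w * exp(theta * (share - s_bar))
        sum(wt * e) / sum(wt) - R / N
      }
      theta <- stats::uniroot(excess_frac, c(-500, 500), tol = 1e-12)$root
      wt <- w * exp(theta * (share - s_bar))
      vol <- as.integer(round(N * wt / sum(wt)))
      # absorb rounding in the largest-excess CCG so the table's own
      # benchmark reproduces the target exactly after integer rounding
      m <- which.max(e)
      gap <- R - sum(vol * e)
      vol[m] <- max(0L, vol[m] + as.integer(round(gap / e[m])))
      tab[[paste0("n_", s)]] <- vol
    }
    ccg_share_table(tab)
  })
}
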