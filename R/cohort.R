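# Cohort container: one patient table (route, covariates, follow-up) plus a
# long monthly cost table spanning 12 pre-diagnosis to `horizon` post-diagnosis
# months.  Month 0 is the calendar month containing diagnosis; month bins are
# half-open [m, m + 1), and the month containing death or censoring belongs to
# the patient's observed history.  Months with no recorded hospital contact
# are zero-cost months, not missing data.

.patient_cols <- c("patient_id", "site", "route", "age", "sex", "imd_income",
                   "region", .charlson_cols, "n_codiag", "surgery_12m",
                   "time_to_event", "event")
.cost_cols <- c("patient_id", "month_index", "cost_gbp")

#' Assemble and validate a cohort table
#'
#' Bundles a patient table and a long monthly cost table into a validated
#' `cohort_table` object used by every estimation function in the package.
#'
#' @param patients data frame with columns `patient_id`, `site`, `route`
#'   (`"EP"` or `"GPTWW"`), `age`, `sex` (`"F"`/`"M"`), `imd_income` (income
#'   deprivation fraction in `[0, 1]`), `region`, the eleven Charlson
#'   indicator columns `cci_ami` ... `cci_renal`, `n_codiag`, `surgery_12m`,
#'   `time_to_event` (months from diagnosis, positive) and `event`
#'   (1 = death observed, 0 = censored).
#' @param costs data frame with columns `patient_id`, `month_index`
#'   (integer in `[-12, horizon - 1]`, 0 = diagnosis month) and `cost_gbp`
#'   (non-negative, 2010 prices).
#' @param site cancer site; determines the follow-up horizon (36 months for
#'   lung, 60 otherwise).
#' @return an object of class `cohort_table`: a list with elements
#'   `patients`, `costs`, `site`, `horizon`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort_table <- function(patients, costs, site) {
  site <- match.arg(site, .sites)
  horizon <- site_horizon(site)
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  costs <- as.data.frame(costs, stringsAsFactors = FALSE)

  missing_p <- setdiff(.patient_cols, names(patients))
  fail_if(length(missing_p) > 0, "patient table is missing column(s): %s",
          paste(missing_p, collapse = ", "))
  missing_c <- setdiff(.cost_cols, names(costs))
  fail_if(length(missing_c) > 0, "cost table is missing column(s): %s",
          paste(missing_c, collapse = ", "))

  patients$route <- factor(as.character(patients$route), levels = .routes)
  patients$sex <- factor(as.character(patients$sex), levels = c("F", "M"))
  patients$region <- factor(as.character(patients$region))
  patients$patient_id <- as.character(patients$patient_id)
  costs$patient_id <- as.character(costs$patient_id)

  obj <- structure(list(patients = patients, costs = costs,
                        site = site, horizon = horizon),
                   class = "cohort_table")
  validate_cohort(obj)
  obj
}

#' Validate a cohort table against its invariants
#'
#' Checks route/sex coding, adult age, positive follow-up times, site-sex
#' consistency (no male breast, no female prostate records), cost bounds,
#' referential integrity between the two tables, duplicate cost months, and
#' that no cost is recorded after a patient's observed follow-up or beyond
#' the site horizon.
#'
#' @param cohort a `cohort_table`.
#' @return the cohort, invisibly; errors on the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- cohort$patients
  co <- cohort$costs
  horizon <- cohort$horizon

  fail_if(anyDuplicated(p$patient_id) > 0, "duplicate patient_id in patient table")
  fail_if(anyNA(p$route), "route must be one of %s", paste(.routes, collapse = "/"))
  fail_if(anyNA(p$sex), "sex must be F or M")
  fail_if(any(p$age < 18), "age_at_diagnosis must be >= 18")
  fail_if(any(p$time_to_event <= 0), "time_to_event must be positive")
  fail_if(any(p$imd_income < 0 | p$imd_income > 1),
          "imd_income must lie in [0, 1]")
  fail_if(!all(p$event %in% c(0, 1)), "event must be 0/1")
  fail_if(!all(p$surgery_12m %in% c(0, 1)), "surgery_12m must be 0/1")
  fail_if(any(p$n_codiag < 0), "n_codiag must be non-negative")
  for (cc in .charlson_cols)
    fail_if(!all(p[[cc]] %in% c(0, 1)), "%s must be 0/1", cc)
  fail_if(cohort$site == "breast" && any(p$sex == "M"),
          "breast cohort contains sex = M records")
  fail_if(cohort$site == "prostate" && any(p$sex == "F"),
          "prostate cohort contains sex = F records")

  if (nrow(co) > 0) {
    fail_if(any(co$cost_gbp < 0), "negative cost_gbp")
    fail_if(any(co$month_index < -12),
            "cost month_index below -12 (pre-diagnosis window is 12 months)")
    fail_if(any(co$month_index > horizon - 1),
            "cost month_index beyond the %d-month %s horizon", horizon, cohort$site)
    fail_if(any(co$month_index != floor(co$month_index)),
            "month_index must be integer")
    fail_if(anyDuplicated(co[c("patient_id", "month_index")]) > 0,
            "duplicate (patient_id, month_index) cost rows")
    orphan <- setdiff(unique(co$patient_id), p$patient_id)
    fail_if(length(orphan) > 0,
            "cost rows reference unknown patient_id(s): %s",
            paste(utils::head(orphan, 3), collapse = ", "))
    # costs only for months the patient is observed alive; the month
    # containing the event is included
    last_month <- pmin(floor(p$time_to_event), horizon - 1)
    names(last_month) <- p$patient_id
    bad <- co$month_index > last_month[co$patient_id]
    fail_if(any(bad), "cost recorded after observed follow-up for patient %s",
            co$patient_id[which(bad)[1]])
  }
  invisible(cohort)
}

#' Read a cohort from CSV files
#'
#' @param patient_path CSV with the patient schema (see [cohort_table()]).
#' @param cost_path CSV with columns `patient_id,month_index,cost_gbp`.
#' @param site cancer site; defaults to the (single) site found in the
#'   patient file.
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(patient_path, cost_path, site = NULL) {
  fail_if(!file.exists(patient_path), "patient file not found: %s", patient_path)
  fail_if(!file.exists(cost_path), "cost file not found: %s", cost_path)
  # sex codes "F"/"T-like" strings must never be read as logicals
  p <- utils::read.csv(patient_path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      site = "character", route = "character",
                                      sex = "character", region = "character"))
  co <- utils::read.csv(cost_path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  if (is.null(site)) {
    fail_if(!"site" %in% names(p), "patient file has no 'site' column")
    usite <- unique(p$site)
    fail_if(length(usite) != 1 && nrow(p) > 0,
            "patient file mixes sites (%s); pass `site` explicitly",
            paste(usite, collapse = ", "))
    site <- if (nrow(p) == 0) "colorectal" else usite
  }
  cohort_table(p, co, site = site)
}

#' Write a cohort to CSV files
#'
#' Reals are written to 12 significant digits so that a write/read round trip
#' is value-preserving.
#'
#' @param cohort a validated `cohort_table`.
#' @param patient_path,cost_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, patient_path, cost_path) {
  validate_cohort(cohort)
  p <- cohort$patients[, .patient_cols]
  num <- vapply(p, is.double, logical(1))
  p[num] <- lapply(p[num], function(x) signif(x, 12))
  co <- cohort$costs[, .cost_cols, drop = FALSE]
  if (nrow(co) > 0) co$cost_gbp <- signif(co$cost_gbp, 12)
  utils::write.csv(p, patient_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(co, cost_path, row.names = FALSE, quote = FALSE)
  invisible(c(patient_path, cost_path))
}

#' @export
print.cohort_table <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<cohort_table> %s, horizon %d months\n", x$site, x$horizon))
  cat(sprintf("  %d patients (%d EP / %d GP/TWW), %d deaths observed\n",
              nrow(p), sum(p$route == "EP"), sum(p$route == "GPTWW"),
              sum(p$event == 1)))
  cat(sprintf("  %d monthly cost rows, total £%s\n", nrow(x$costs),
              format(round(sum(x$costs$cost_gbp)), big.mark = ",")))
  invisible(x)
}

#' @export
summary.cohort_table <- function(object, ...) {
  p <- object$patients
  by_route <- split(p, p$route)
  out <- do.call(rbind, lapply(names(by_route), function(r) {
    q <- by_route[[r]]
    data.frame(route = r, n = nrow(q), mean_age = mean(q$age),
               mean_imd = mean(q$imd_income),
               surgery_12m = mean(q$surgery_12m),
               deaths = sum(q$event),
               # crude 12-month survival among patients with 12 months of
               # potential follow-up (died earlier or observed past month 12)
               surv_12m = sum(q$time_to_event > 12) /
                 sum(q$event == 1 | q$time_to_event > 12),
               row.names = NULL)
  }))
  structure(list(site = object$site, horizon = object$horizon, table = out),
            class = "summary.cohort_table")
}

#' @export
print.summary.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort summary: %s (horizon %d months)\n", x$site, x$horizon))
  print(x$table, digits = 3)
  invisible(x)
}
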