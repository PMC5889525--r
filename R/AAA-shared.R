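#' @keywords internal
"_PACKAGE"

# Sites and routes are closed vocabularies shared across the whole pipeline.
.sites <- c("colorectal", "breast", "prostate", "lung")
.routes <- c("EP", "GPTWW")

.charlson_cols <- c("cci_ami", "cci_chf", "cci_pvd", "cci_cvd", "cci_dem",
                    "cci_copd", "cci_rheum", "cci_ulcer", "cci_liver",
                    "cci_diab", "cci_renal")

#' Follow-up horizon for a cancer site
#'
#' Lung cohorts are followed 36 months post diagnosis, all other sites 60.
#'
#' @param site one of `"colorectal"`, `"breast"`, `"prostate"`, `"lung"`.
#' @return horizon in months (36 or 60).
#' @export
site_horizon <- function(site) {
  site <- match.arg(site, .sites)
  if (site == "lung") 36L else 60L
}

#' Round to the nearest pound, halves away from zero
#'
#' Ledger arithmetic is carried out unrounded; this rounding is applied only
#' when figures are reported.
#'
#' @param x numeric vector of GBP amounts.
#' @return integer-valued numeric vector.
#' @export
round_gbp <- function(x) {
  out <- sign(x) * floor(abs(x) + 0.5)
  out[is.na(x)] <- NA_real_
  out
}

# Run `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# polynomial rolling hash (mod 2^31 - 1) of a deparsed object; stamps
# pipeline outputs so reruns with the same configuration are recognisable
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
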