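# Growth-rate estimators and the building blocks of the Heinbokel
# clearance/ingestion calculation.

rate_estimate <- function(value, method, window, n_points, fit_r2 = NA_real_,
                          flags = character(0)) {
  structure(list(value = value, method = method,
                 window = as.numeric(window), n_points = as.integer(n_points),
                 fit_r2 = fit_r2, flags = flags),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.6g d^-1 (%s, days %g-%g, %d points%s%s)\n",
              x$value, x$method, x$window[1], x$window[2], x$n_points,
              if (is.na(x$fit_r2)) "" else sprintf(", R2 = %.3f", x$fit_r2),
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

series_conc <- function(series, which) {
  which <- match.arg(which, c("prey", "predator"))
  if (which == "prey") series$prey_conc else series$predator_conc
}

resolve_window <- function(series, window) {
  if (is.null(window)) window <- range(series$days)
  i0 <- match(window[1], series$days)
  i1 <- match(window[2], series$days)
  if (is.na(i0) || is.na(i1) || i1 <= i0)
    gk_domain_error(sprintf("window (%g, %g) does not match sampling days of flask '%s'",
                            window[1], window[2], series$flask_id))
  c(i0, i1)
}

#' Endpoint exponential growth rate
#'
#' The two-point estimator `mu = (ln N_t - ln N_0) / t`, using only the
#' concentrations at the window endpoints. This is the standard estimator
#' for exponentially growing plankton populations between two samplings.
#'
#' @param series A [count_series()].
#' @param which `"prey"` or `"predator"`.
#' @param window `c(start_day, end_day)`; both must be sampling days.
#'   Default: the full series.
#' @return A `rate_estimate` (value in day^-1, method `"exponential_eq3"`).
#' @examples
#' s <- count_series("m", "p", "control", c(0, 5), c(100, 100 * exp(1)))
#' exponential_growth_rate(s)$value # 0.2
#' @export
exponential_growth_rate <- function(series, which = "prey", window = NULL) {
  stopifnot(inherits(series, "count_series"))
  conc <- series_conc(series, which)
  idx <- resolve_window(series, window)
  n0 <- conc[idx[1]]; nt <- conc[idx[2]]
  t0 <- series$days[idx[1]]; t1 <- series$days[idx[2]]
  if (n0 <= 0 || nt <= 0)
    gk_domain_error(sprintf(
      "flask '%s': zero concentration at a window endpoint, exponential rate undefined",
      series$flask_id))
  rate_estimate((log(nt) - log(n0)) / (t1 - t0), "exponential_eq3",
                c(t0, t1), 2L)
}

#' Regression-based linear growth rate
#'
#' Fits ordinary least squares to `ln(concentration)` versus day over all
#' points in the window and reports `mu = e^slope - 1` (the per-day
#' multiplicative increase minus one). Zero counts cannot enter a log fit;
#' they are excluded and the estimate flagged `zero_count_interval` rather
#' than pseudo-counted, which would bias the rate.
#'
#' @inheritParams exponential_growth_rate
#' @return A `rate_estimate` (method `"linear_eq2"`) with `fit_r2` the
#'   R-squared of the log-linear fit.
#' @examples
#' s <- count_series("m", "p", "control", 0:3, 1000 * 1.1^(0:3))
#' linear_growth_rate(s)$value # 0.1
#' @export
linear_growth_rate <- function(series, which = "prey", window = NULL) {
  stopifnot(inherits(series, "count_series"))
  conc <- series_conc(series, which)
  idx <- resolve_window(series, window)
  sel <- seq(idx[1], idx[2])
  flags <- character(0)
  pos <- sel[conc[sel] > 0]
  if (length(pos) < length(sel)) flags <- "zero_count_interval"
  if (length(pos) < 2)
    gk_domain_error(sprintf(
      "flask '%s': fewer than 2 positive concentrations in window", series$flask_id))
  fit <- ols_fit(series$days[pos], log(conc[pos]))
  rate_estimate(exp(fit[["slope"]]) - 1, "linear_eq2",
                c(series$days[idx[1]], series$days[idx[2]]),
                length(pos), fit[["r2"]], flags)
}

#' Logarithmic mean concentration
#'
#' `(B1 - B0) / (ln B1 - ln B0)`: the time-average of a concentration that
#' changes exponentially between two samplings. Continuous at `B1 = B0`
#' (returns `B0` when the endpoints differ by less than 1e-9 relative) and
#' always bounded by its endpoints.
#'
#' @param B0,B1 Positive concentrations (cells mL^-1). Vectorised.
#' @return The logarithmic mean (cells mL^-1).
#' @examples
#' log_mean_concentration(1000, 100) # 900 / ln(10)
#' @export
log_mean_concentration <- function(B0, B1) {
  v <- cbind(B0, B1)
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0))
    gk_domain_error("B0 and B1 must be finite and > 0")
  b0 <- v[, 1]; b1 <- v[, 2]
  same <- abs(b1 - b0) < 1e-9 * pmax(abs(b0), abs(b1))
  # log1p form of ln(B1) - ln(B0): avoids cancellation at near-equal endpoints
  out <- ifelse(same, b0, (b1 - b0) / log1p((b1 - b0) / b0))
  as.numeric(out)
}

#' Clearance rate from the grazed/ungrazed growth-rate difference
#'
#' `F = (k - g) / P`, where `k` is the prey growth rate in the ungrazed
#' monoculture, `g` the prey rate under grazing, and `P` the average
#' predator concentration over the interval. Negative values (prey doing
#' better with grazers than without, i.e. noise or facilitation) are
#' returned unclamped, carrying a `negative_clearance` flag attribute, so
#' that averages over intervals stay unbiased.
#'
#' @param k,g Growth rates (day^-1).
#' @param P Average predator concentration (cells mL^-1), `> 0`.
#' @return Clearance rate (mL predator^-1 day^-1).
#' @export
clearance_rate <- function(k, g, P) {
  v <- cbind(k, g, P)
  if (anyNA(v) || any(!is.finite(v))) gk_domain_error("k, g, P must be finite")
  if (any(v[, 3] <= 0)) gk_domain_error("P must be > 0")
  f <- as.numeric((v[, 1] - v[, 2]) / v[, 3])
  if (any(f < 0)) attr(f, "flags") <- "negative_clearance"
  f
}

#' Ingestion rate
#'
#' `I = B_avg * F`: prey cells ingested per predator per day, the product of
#' the average prey concentration and the clearance rate.
#'
#' @param B_avg Average prey concentration (cells mL^-1).
#' @param F Clearance rate (mL predator^-1 day^-1).
#' @return Ingestion rate (cells predator^-1 day^-1).
#' @export
ingestion_rate <- function(B_avg, F) {
  as.numeric(B_avg) * as.numeric(F)
}

#' Detect the linear prey-decline window
#'
#' Strong grazing shows up as a sustained, log-linear decrease in prey
#' concentration. This detector returns the longest contiguous run of at
#' least `min_run` sampling points over which prey concentration is strictly
#' decreasing, all counts are positive, and the log-linear fit has
#' `R^2 >= r2_min`. Ties on length are broken toward the earlier window.
#'
#' @param series A [count_series()] with at least 3 time points.
#' @param r2_min Minimum R-squared of the log-linear fit (default 0.90).
#' @param min_run Minimum number of sampling points (default 3).
#' @return `c(start_day, end_day)`, or `NULL` if no qualifying run exists.
#' @examples
#' s <- count_series("g", "p", "grazed", seq(0, 8, 2),
#'                   c(1000, 800, 400, 150, 40), rep(200, 5), "cil")
#' detect_decline_window(s) # c(0, 8)
#' @export
detect_decline_window <- function(series, r2_min = 0.9, min_run = 3) {
  stopifnot(inherits(series, "count_series"))
  n <- length(series$days)
  if (n < min_run) return(NULL)
  best <- NULL; best_len <- 0L
  for (i in seq_len(n - min_run + 1L)) {
    for (j in seq(i + min_run - 1L, n)) {
      len <- j - i + 1L
      if (len <= best_len) next # ties go to the earlier (already stored) window
      prey <- series$prey_conc[i:j]
      if (any(prey <= 0) || any(diff(prey) >= 0)) next
      fit <- ols_fit(series$days[i:j], log(prey))
      if (fit[["r2"]] >= r2_min) {
        best <- c(series$days[i], series$days[j]); best_len <- len
      }
    }
  }
  best
}
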