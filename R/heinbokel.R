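#' Fit Heinbokel-style grazing rates to an experiment
#'
#' The central estimator of the package. For every grazed flask and every
#' pair of consecutive sampling days it computes the classical
#' dilution-free grazing quantities:
#' \itemize{
#'   \item `k` — prey growth rate in the strain-matched ungrazed control
#'     over the same interval (endpoint exponential rate; averaged when a
#'     strain has several control flasks),
#'   \item `g` — prey growth rate in the grazed flask over the interval,
#'   \item `B_avg` — logarithmic-mean prey concentration in the grazed flask,
#'   \item `P` — logarithmic-mean predator concentration (the time-average
#'     of an exponentially changing predator population),
#'   \item `F = (k - g) / P` — clearance rate (mL predator^-1 day^-1),
#'   \item `I = B_avg * F` — ingestion rate (cells predator^-1 day^-1).
#' }
#'
#' Two interval-selection modes are offered. `"per_interval"` keeps every
#' consecutive interval (appropriate for weak grazers whose prey keeps
#' growing). `"decline_window"` restricts the summary to intervals that fall
#' inside the detected log-linear prey-decline window
#' ([detect_decline_window()]) *and* over which the predator is growing
#' exponentially (endpoint rate > 0) — the restriction appropriate for a
#' strong grazer that drives the prey toward depletion. Excluded intervals
#' are still reported, flagged `outside_decline_window`.
#'
#' Intervals with a zero count at any endpoint (grazed prey, control prey or
#' predator) cannot enter the log-based formulas; they get `NA` rates and
#' the flag `zero_count_interval`. Negative clearances are reported
#' unclamped with flag `negative_clearance` and *are* included in summary
#' means, so the means stay unbiased.
#'
#' @param experiment An [experiment()] in which every grazed flask has a
#'   same-prey-strain control.
#' @param predator_strain Optional character vector restricting the fit to
#'   particular predator strains. Default: all.
#' @param mode `"per_interval"` or `"decline_window"` (see Details).
#' @param r2_min,min_run Decline-window detector settings, see
#'   [detect_decline_window()].
#' @param global_k Logical; if `TRUE`, `k` is the control's exponential rate
#'   over the whole series (one number per control) instead of the
#'   interval-matched rate. Default `FALSE`.
#' @return An object of class `heinbokel` with components `rates` (a
#'   `grazing_rates` data.frame, one row per flask x interval), `summary`
#'   (per-predator-strain means over unexcluded intervals), `windows`
#'   (detected decline window per grazed flask, `decline_window` mode only)
#'   and the call. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' fx <- make_fixture_experiment("strong_grazer", seed = 1)
#' fit <- heinbokel(fx$experiment, mode = "decline_window")
#' coef(fit)
#' @seealso [grazing_table()] for the bare per-interval table,
#'   [write_rates_table()] to serialise it.
#' @export
heinbokel <- function(experiment, predator_strain = NULL,
                      mode = c("per_interval", "decline_window"),
                      r2_min = 0.9, min_run = 3, global_k = FALSE) {
  stopifnot(inherits(experiment, "experiment"))
  mode <- match.arg(mode)
  ser <- experiment$series
  grazed <- Filter(function(s) s$treatment == "grazed", ser)
  if (!is.null(predator_strain))
    grazed <- Filter(function(s) s$predator_strain %in% predator_strain, grazed)
  if (!length(grazed))
    gk_config_error("no grazed series match the requested predator strain(s)")
  controls <- Filter(function(s) s$treatment == "control", ser)

  rows <- list()
  windows <- list()
  for (s in grazed) {
    ctrl <- Filter(function(c) c$prey_strain == s$prey_strain, controls)
    if (!length(ctrl))
      gk_config_error(sprintf(
        "no control series for prey strain '%s' (needed by flask '%s')",
        s$prey_strain, s$flask_id))
    win <- if (mode == "decline_window")
      detect_decline_window(s, r2_min = r2_min, min_run = min_run) else NULL
    windows[[s$flask_id]] <- win

    gk <- if (global_k) mean(vapply(ctrl, function(c) {
      pos <- which(c$prey_conc > 0)
      if (length(pos) < 2) return(NA_real_)
      exponential_growth_rate(c, "prey",
        c(c$days[pos[1]], c$days[pos[length(pos)]]))$value
    }, numeric(1)), na.rm = TRUE) else NA_real_

    nd <- length(s$days)
    for (ii in seq_len(nd - 1L)) {
      d0 <- s$days[ii]; d1 <- s$days[ii + 1L]
      b0 <- s$prey_conc[ii]; b1 <- s$prey_conc[ii + 1L]
      p0 <- s$predator_conc[ii]; p1 <- s$predator_conc[ii + 1L]
      flags <- character(0)

      kvals <- vapply(ctrl, function(c) {
        j0 <- match(d0, c$days); j1 <- match(d1, c$days)
        if (is.na(j0) || is.na(j1)) return(NA_real_)
        if (c$prey_conc[j0] <= 0 || c$prey_conc[j1] <= 0) return(NA_real_)
        (log(c$prey_conc[j1]) - log(c$prey_conc[j0])) / (d1 - d0)
      }, numeric(1))
      k <- if (global_k) gk else mean(kvals, na.rm = TRUE)

      usable <- b0 > 0 && b1 > 0 && p0 > 0 && p1 > 0 && is.finite(k)
      if (!usable) {
        flags <- c(flags, "zero_count_interval")
        g <- B_avg <- P <- Fv <- I <- NA_real_
      } else {
        g <- (log(b1) - log(b0)) / (d1 - d0)
        B_avg <- log_mean_concentration(b0, b1)
        P <- log_mean_concentration(p0, p1)
        Fv <- as.numeric(clearance_rate(k, g, P))
        I <- ingestion_rate(B_avg, Fv)
        if (Fv < 0) flags <- c(flags, "negative_clearance")
      }
      if (mode == "decline_window") {
        in_win <- !is.null(win) && d0 >= win[1] && d1 <= win[2]
        pred_growing <- p0 > 0 && p1 > 0 && log(p1) > log(p0)
        if (!(in_win && pred_growing))
          flags <- c(flags, "outside_decline_window")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        predator_strain = s$predator_strain, prey_strain = s$prey_strain,
        flask_id = s$flask_id, t_start = d0, t_end = d1,
        k = k, g = g, B_avg = B_avg, P = P, F = Fv, I = I,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(rates) <- c("grazing_rates", "data.frame")

  excl <- grepl("zero_count_interval|outside_decline_window", rates$flags)
  keep <- rates[!excl, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(keep, keep$predator_strain), function(g)
    data.frame(predator_strain = g$predator_strain[1], n_intervals = nrow(g),
               mean_k = mean(g$k), mean_g = mean(g$g), mean_F = mean(g$F),
               mean_I = mean(g$I), stringsAsFactors = FALSE)))
  if (is.null(summ))
    summ <- data.frame(predator_strain = character(0), n_intervals = integer(0),
                       mean_k = numeric(0), mean_g = numeric(0),
                       mean_F = numeric(0), mean_I = numeric(0))
  rownames(summ) <- NULL

  structure(list(rates = rates, summary = summ, windows = windows,
                 mode = mode, r2_min = r2_min, min_run = min_run,
                 global_k = global_k, experiment = experiment,
                 call = match.call()),
            class = "heinbokel")
}

#' Per-interval grazing-rate table
#'
#' Convenience accessor: runs [heinbokel()] and returns just the
#' per-interval `grazing_rates` data.frame.
#'
#' @inheritParams heinbokel
#' @param ... Passed to [heinbokel()].
#' @return A `grazing_rates` data.frame.
#' @export
grazing_table <- function(experiment, predator_strain = NULL,
                          mode = c("per_interval", "decline_window"), ...) {
  heinbokel(experiment, predator_strain = predator_strain,
            mode = mode, ...)$rates
}

#' @export
print.heinbokel <- function(x, digits = 4, ...) {
  cat("Heinbokel grazing-rate fit\n")
  cat("  mode:", x$mode,
      if (x$mode == "decline_window") sprintf("(R2 >= %.2f, run >= %d)", x$r2_min, x$min_run),
      "\n")
  cat(sprintf("  %d grazed flask(s), %d interval(s)\n",
              length(unique(x$rates$flask_id)), nrow(x$rates)))
  cat("\nSummary over unexcluded intervals (per predator strain):\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.heinbokel <- function(object, ...) {
  flg <- unlist(strsplit(object$rates$flags[nzchar(object$rates$flags)], ";"))
  structure(list(fit = object,
                 flag_counts = if (length(flg)) table(flg) else table(character(0))),
            class = "summary.heinbokel")
}

#' @export
print.summary.heinbokel <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (x$fit$mode == "decline_window") {
    cat("\nDetected decline windows:\n")
    for (id in names(x$fit$windows)) {
      w <- x$fit$windows[[id]]
      cat(sprintf("  %s: %s\n", id,
                  if (is.null(w)) "none" else sprintf("days %g-%g", w[1], w[2])))
    }
  }
  if (length(x$flag_counts)) {
    cat("\nInterval flags:\n")
    print(x$flag_counts)
  }
  cat("\nPer-interval rates:\n")
  print(format(as.data.frame(x$fit$rates), digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.heinbokel <- function(object, ...) {
  s <- object$summary
  m <- as.matrix(s[, c("mean_k", "mean_g", "mean_F", "mean_I")])
  rownames(m) <- s$predator_strain
  colnames(m) <- c("k", "g", "F", "I")
  if (nrow(m) == 1L) m[1, ] else m
}

#' @export
plot.heinbokel <- function(x, ...) {
  ex <- x$experiment
  grazed <- Filter(function(s) s$treatment == "grazed", ex$series)
  strains <- unique(vapply(grazed, `[[`, character(1), "prey_strain"))
  op <- graphics::par(mfrow = c(1, length(strains)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ps in strains) {
    ss <- Filter(function(s) s$prey_strain == ps, ex$series)
    all_conc <- unlist(lapply(ss, function(s) c(s$prey_conc, s$predator_conc)))
    ylim <- range(all_conc[all_conc > 0])
    graphics::plot(NA, xlim = range(unlist(lapply(ss, `[[`, "days"))), ylim = ylim,
                   log = "y", xlab = "day", ylab = "cells / mL", main = ps)
    for (s in ss) {
      col <- if (s$treatment == "control") "grey40" else "firebrick"
      graphics::lines(s$days, pmax(s$prey_conc, ylim[1]), col = col,
                      lty = if (s$treatment == "control") 1 else 2)
      if (s$treatment == "grazed")
        graphics::lines(s$days, pmax(s$predator_conc, ylim[1]), col = "black", lty = 3)
    }
  }
  invisible(x)
}
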