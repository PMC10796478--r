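#' Construct a single-flask count time series
#'
#' A `count_series` holds one culture flask's sampling days and the measured
#' prey and predator concentrations (cells mL^-1). Control flasks are prey
#' monocultures: they carry no predator strain and all predator
#' concentrations are zero. Grazed flasks must contain predators.
#'
#' Days are expressed in days since the addition of the grazer (day 0).
#'
#' @param flask_id Character scalar identifying the flask.
#' @param prey_strain Character scalar, prey strain label.
#' @param treatment `"control"` or `"grazed"`.
#' @param days Numeric vector of sampling times (days, >= 0), strictly
#'   increasing after sorting; duplicates are rejected.
#' @param prey_conc Prey concentrations (cells mL^-1, >= 0), one per day.
#' @param predator_conc Predator concentrations (cells mL^-1, >= 0). Defaults
#'   to all zero for controls; required for grazed flasks.
#' @param predator_strain Predator strain label for grazed flasks; must be
#'   `NULL` for controls.
#' @return An object of class `count_series`.
#' @examples
#' count_series("c1", "preyA", "control", days = c(0, 2, 4),
#'              prey_conc = c(1000, 1100, 1210))
#' @export
count_series <- function(flask_id, prey_strain, treatment, days, prey_conc,
                         predator_conc = NULL, predator_strain = NULL) {
  if (!is.character(flask_id) || length(flask_id) != 1L || !nzchar(flask_id))
    gk_validation_error("flask_id must be a non-empty character scalar")
  treatment <- match.arg(treatment, c("control", "grazed"))
  days <- as.numeric(days)
  prey_conc <- as.numeric(prey_conc)
  if (is.null(predator_conc)) {
    if (treatment == "grazed")
      gk_validation_error(sprintf("flask '%s': grazed series needs predator_conc", flask_id))
    predator_conc <- rep(0, length(days))
  }
  predator_conc <- as.numeric(predator_conc)
  if (length(prey_conc) != length(days) || length(predator_conc) != length(days))
    gk_validation_error(sprintf("flask '%s': days, prey_conc and predator_conc lengths differ", flask_id))
  if (length(days) < 1L)
    gk_validation_error(sprintf("flask '%s': empty series", flask_id))
  if (anyNA(days) || any(!is.finite(days)) || any(days < 0))
    gk_validation_error(sprintf("flask '%s': days must be finite and >= 0", flask_id))
  if (anyDuplicated(days))
    gk_validation_error(sprintf("flask '%s': duplicated sampling day", flask_id))
  ord <- order(days)
  days <- days[ord]; prey_conc <- prey_conc[ord]; predator_conc <- predator_conc[ord]
  for (nm in c("prey_conc", "predator_conc")) {
    v <- get(nm)
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
      gk_validation_error(sprintf("flask '%s': %s must be finite and >= 0", flask_id, nm))
  }
  if (treatment == "control") {
    if (!is.null(predator_strain) && !is.na(predator_strain) && nzchar(predator_strain))
      gk_validation_error(sprintf("flask '%s': control series cannot have a predator strain", flask_id))
    if (any(predator_conc > 0))
      gk_validation_error(sprintf("flask '%s': control series has non-zero predator counts", flask_id))
    predator_strain <- NULL
  } else {
    if (is.null(predator_strain) || is.na(predator_strain) || !nzchar(predator_strain))
      gk_validation_error(sprintf("flask '%s': grazed series needs a predator strain", flask_id))
    if (all(predator_conc == 0))
      gk_validation_error(sprintf("flask '%s': grazed series has all-zero predator counts", flask_id))
  }
  structure(
    list(flask_id = flask_id, prey_strain = as.character(prey_strain),
         predator_strain = predator_strain, treatment = treatment,
         days = days, prey_conc = prey_conc, predator_conc = predator_conc),
    class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> flask %s [%s] prey=%s%s, %d time points (day %g-%g)\n",
              x$flask_id, x$treatment, x$prey_strain,
              if (is.null(x$predator_strain)) "" else paste0(", predator=", x$predator_strain),
              length(x$days), min(x$days), max(x$days)))
  print(data.frame(day = x$days, prey_per_ml = x$prey_conc,
                   predator_per_ml = x$predator_conc), row.names = FALSE)
  invisible(x)
}

#' Bundle count series into an experiment
#'
#' An `experiment` is a collection of [count_series()] flasks plus the
#' design table mapping prey and predator strains to flask ids. By default
#' every grazed flask must have at least one control (monoculture) flask of
#' the same prey strain, since the Heinbokel clearance estimator needs the
#' strain-matched ungrazed growth rate.
#'
#' @param series List of `count_series` objects with unique flask ids.
#' @param check_controls Require a same-prey-strain control for every grazed
#'   flask (default `TRUE`).
#' @return An object of class `experiment` with elements `series` (named list)
#'   and `design` (data.frame).
#' @export
experiment <- function(series, check_controls = TRUE) {
  if (!length(series) || !all(vapply(series, inherits, logical(1), "count_series")))
    gk_validation_error("series must be a non-empty list of count_series objects")
  ids <- vapply(series, `[[`, character(1), "flask_id")
  if (anyDuplicated(ids))
    gk_validation_error(sprintf("duplicated flask id '%s'", ids[duplicated(ids)][1]))
  names(series) <- ids
  design <- data.frame(
    flask_id = ids,
    prey_strain = vapply(series, `[[`, character(1), "prey_strain"),
    predator_strain = vapply(series, function(s) s$predator_strain %||% NA_character_, character(1)),
    treatment = vapply(series, `[[`, character(1), "treatment"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (check_controls) {
    ctrl_strains <- design$prey_strain[design$treatment == "control"]
    orphan <- setdiff(design$prey_strain[design$treatment == "grazed"], ctrl_strains)
    if (length(orphan))
      gk_validation_error(sprintf(
        "grazed prey strain '%s' has no matching control series", orphan[1]))
  }
  structure(list(series = series, design = design), class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> %d flasks, %d prey strain(s), %d predator strain(s)\n",
              nrow(x$design), length(unique(x$design$prey_strain)),
              length(unique(stats::na.omit(x$design$predator_strain)))))
  print(x$design, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.experiment <- function(x, ...) {
  do.call(rbind, c(lapply(unname(x$series), function(s) {
    data.frame(flask_id = s$flask_id, day = s$days,
               prey_per_ml = s$prey_conc, predator_per_ml = s$predator_conc,
               treatment = s$treatment, prey_strain = s$prey_strain,
               predator_strain = s$predator_strain %||% "",
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}
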