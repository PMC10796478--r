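#' Read a flask count table
#'
#' Reads the comma-separated count table produced during a grazing
#' experiment (one row per flask and sampling day) and returns a validated
#' [experiment()]. Lines starting with `#` are treated as comments
#' (provenance headers written by this package are of that form).
#'
#' Required columns (renameable through `columns`): `flask_id`, `day`,
#' `prey_per_ml`, `predator_per_ml`, `treatment`, `prey_strain`,
#' `predator_strain`. `treatment` must be `control` or `grazed`;
#' `predator_strain` may be empty on control rows.
#'
#' @param path Path to a CSV file.
#' @param columns Optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   `c(day = "Day", prey_per_ml = "algae")`.
#' @param check_controls Passed to [experiment()].
#' @return An `experiment`.
#' @export
read_counts <- function(path, columns = NULL, check_controls = TRUE) {
  if (!file.exists(path)) gk_format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("flask_id", "day", "prey_per_ml", "predator_per_ml",
           "treatment", "prey_strain", "predator_strain")
  actual <- stats::setNames(req, req)
  if (!is.null(columns)) actual[names(columns)] <- columns
  missing <- actual[!actual %in% names(df)]
  if (length(missing))
    gk_format_error(sprintf("missing column '%s' in %s", missing[1], path))
  df <- df[, actual]
  names(df) <- req
  df$day <- as.numeric(df$day)
  for (nm in c("prey_per_ml", "predator_per_ml")) {
    v <- as.numeric(df[[nm]])
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      gk_validation_error(sprintf("negative or non-numeric %s at file row %d",
                                  nm, bad[1] + 1L))
    df[[nm]] <- v
  }
  dup <- duplicated(df[, c("flask_id", "day")])
  if (any(dup))
    gk_validation_error(sprintf(
      "duplicated (flask_id, day) pair: flask '%s' day %g",
      df$flask_id[dup][1], df$day[dup][1]))
  bad_tr <- !df$treatment %in% c("control", "grazed")
  if (any(bad_tr))
    gk_validation_error(sprintf("unknown treatment '%s' at file row %d",
                                df$treatment[bad_tr][1], which(bad_tr)[1] + 1L))
  ctrl_pred <- df$treatment == "control" & df$predator_per_ml > 0
  if (any(ctrl_pred))
    gk_validation_error(sprintf(
      "control row with predator_per_ml > 0 at file row %d", which(ctrl_pred)[1] + 1L))
  series <- lapply(split(df, df$flask_id), function(g) {
    g <- g[order(g$day), ]
    ps <- unique(g$predator_strain)
    ps <- ps[!is.na(ps) & nzchar(ps)]
    if (length(ps) > 1)
      gk_validation_error(sprintf("flask '%s': inconsistent predator strain", g$flask_id[1]))
    count_series(flask_id = g$flask_id[1], prey_strain = g$prey_strain[1],
                 treatment = g$treatment[1], days = g$day,
                 prey_conc = g$prey_per_ml, predator_conc = g$predator_per_ml,
                 predator_strain = if (length(ps)) ps else NULL)
  })
  experiment(unname(series), check_controls = check_controls)
}

#' Write a flask count table
#'
#' Inverse of [read_counts()]: writes an experiment as the canonical CSV.
#'
#' @param x An `experiment`.
#' @param path Output path.
#' @param comment Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the header.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "experiment"))
  write_csv_commented(as.data.frame(x), path, comment)
}

write_csv_commented <- function(df, path, comment = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e)
    gk_stop(sprintf("cannot open '%s' for writing", path), "gk_io_error"))
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a taxon read-abundance table
#'
#' Reads per-sample amplicon read counts with columns `lake`, `date`,
#' `fraction`, `taxon`, `reads`. `fraction` must be `small` (0.2-10 um
#' filter) or `large` (10-100 um filter); `reads` must be non-negative
#' integers.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of class `abundance_records` with `date` parsed as
#'   `Date` and `reads` as integer.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) gk_format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("lake", "date", "fraction", "taxon", "reads")
  missing <- setdiff(req, names(df))
  if (length(missing))
    gk_format_error(sprintf("missing column '%s' in %s", missing[1], path))
  df <- df[, req]
  bad_fr <- !df$fraction %in% c("small", "large")
  if (any(bad_fr))
    gk_validation_error(sprintf("unknown size fraction '%s' at file row %d",
                                df$fraction[bad_fr][1], which(bad_fr)[1] + 1L))
  reads <- suppressWarnings(as.numeric(df$reads))
  bad <- which(!is.finite(reads) | reads < 0 | abs(reads - round(reads)) > 1e-8)
  if (length(bad))
    gk_validation_error(sprintf("reads must be a non-negative integer at file row %d",
                                bad[1] + 1L))
  df$reads <- as.integer(round(reads))
  dates <- as.Date(df$date)
  if (anyNA(dates))
    gk_validation_error(sprintf("unparseable date at file row %d",
                                which(is.na(dates))[1] + 1L))
  df$date <- dates
  class(df) <- c("abundance_records", "data.frame")
  df
}

#' Write / read a grazing-rates table
#'
#' Serialises the per-interval rate table produced by [heinbokel()] (or
#' [grazing_table()]) as CSV and reads it back. Numeric values round-trip to
#' better than 1e-9 relative.
#'
#' @param rates A `grazing_rates` data.frame (possibly empty).
#' @param path File path.
#' @param comment Optional `#`-prefixed provenance lines.
#' @return `write_rates_table()` returns `path` invisibly;
#'   `read_rates_table()` returns the table.
#' @export
write_rates_table <- function(rates, path, comment = NULL) {
  cols <- c("predator_strain", "prey_strain", "flask_id", "t_start", "t_end",
            "k", "g", "B_avg", "P", "F", "I", "flags")
  if (!all(cols %in% names(rates)))
    gk_validation_error("rates is not a grazing-rates table")
  df <- as.data.frame(rates)[, cols, drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    gk_stop(sprintf("cannot open '%s' for writing", path), "gk_io_error"))
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rates_table
#' @export
read_rates_table <- function(path) {
  if (!file.exists(path)) gk_format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = c(flags = "character"))
  num <- c("t_start", "t_end", "k", "g", "B_avg", "P", "F", "I")
  df[num] <- lapply(df[num], as.numeric)
  df$flags[is.na(df$flags)] <- ""
  class(df) <- c("grazing_rates", "data.frame")
  df
}

#' Read per-cell length/width measurements
#'
#' Columns: `strain`, `length_um`, `width_um` (micrometres).
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `strain`, `length`, `width`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) gk_format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("strain", "length_um", "width_um")
  missing <- setdiff(req, names(df))
  if (length(missing))
    gk_format_error(sprintf("missing column '%s' in %s", missing[1], path))
  out <- data.frame(strain = df$strain, length = as.numeric(df$length_um),
                    width = as.numeric(df$width_um), stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$length) | !is.finite(out$width) |
                 out$length <= 0 | out$width <= 0)
  if (length(bad))
    gk_validation_error(sprintf("non-positive cell dimension at file row %d", bad[1] + 1L))
  out
}
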