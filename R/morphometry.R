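#' Prolate-ellipsoid cell biovolume
#'
#' Biovolume of an elongated cell from its full length and width,
#' `V = 4/3 * pi * length * width^2` (micrometres in, cubic micrometres
#' out). Note this convention uses the full dimensions, not semi-axes, so it
#' is 8x the semi-axis ellipsoid volume; it is applied verbatim because it
#' is the convention the field's morphometry uses for these measurements.
#'
#' @param length Cell length (um), `>= 0`. Vectorised.
#' @param width Cell width (um), `>= 0`. Vectorised.
#' @return Volume(s) in um^3.
#' @examples
#' prolate_volume(16.9, 11.8) # ~9857 um^3
#' @export
prolate_volume <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width))
    gk_domain_error("length and width must be numeric")
  v <- cbind(length, width) # recycles, errors on incompatible lengths
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    gk_domain_error("length and width must be finite and >= 0")
  if (any(v[, 1] < v[, 2]))
    warning("length < width for some cells; check measurement order (prolate convention expects length >= width)")
  as.numeric(4 / 3 * pi * v[, 1] * v[, 2]^2)
}

#' Per-strain biovolume summary
#'
#' Mean length, width and biovolume per strain. The mean volume is the
#' arithmetic mean of per-cell [prolate_volume()] values, not the volume of
#' the mean dimensions (the two differ whenever dimensions vary).
#'
#' @param measurements data.frame with columns `strain`, `length`, `width`
#'   (as returned by [read_measurements()]).
#' @return data.frame with one row per strain: `strain`, `n`, `mean_length`,
#'   `mean_width`, `mean_volume`.
#' @export
volume_summary <- function(measurements) {
  req <- c("strain", "length", "width")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    gk_validation_error("measurements must have columns strain, length, width")
  if (!nrow(measurements))
    gk_validation_error("no measurements supplied")
  vol <- prolate_volume(measurements$length, measurements$width)
  out <- do.call(rbind, lapply(split(seq_len(nrow(measurements)), measurements$strain),
    function(i) data.frame(
      strain = measurements$strain[i[1]], n = length(i),
      mean_length = mean(measurements$length[i]),
      mean_width = mean(measurements$width[i]),
      mean_volume = mean(vol[i]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t-test on cell volumes
#'
#' Student's two-sample t-test with pooled variance (so `df = n_a + n_b - 2`),
#' the classical test for comparing mean cell biovolume between two strains
#' measured on independent cells. A Welch test is deliberately not offered:
#' the pooled test is the convention for equal-effort morphometry samples.
#'
#' @param volumes_a,volumes_b Numeric vectors (um^3), each of length >= 2.
#' @return An object of class `pooled_t_test`: `statistic`, `df`, `p_value`
#'   (two-sided), `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' pooled_t_test(rnorm(20, 10280, 2000), rnorm(20, 5663, 1500))
#' @export
pooled_t_test <- function(volumes_a, volumes_b) {
  a <- as.numeric(volumes_a); b <- as.numeric(volumes_b)
  if (length(a) < 2 || length(b) < 2)
    gk_domain_error("each group needs at least 2 values")
  if (anyNA(a) || anyNA(b)) gk_domain_error("missing values not allowed")
  df <- length(a) + length(b) - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      res <- list(statistic = 0, df = df, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b),
                  n_a = length(a), n_b = length(b))
      class(res) <- "pooled_t_test"
      return(res)
    }
    gk_domain_error("zero pooled variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  res <- list(statistic = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
              p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
              n_a = length(a), n_b = length(b))
  class(res) <- "pooled_t_test"
  res
}

#' @export
print.pooled_t_test <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  group means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean_a, x$mean_b, x$n_a, x$n_b))
  invisible(x)
}
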