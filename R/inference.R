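# Permutation inference for treatment effects on prey trajectories and for
# differences among estimated rates. These replace parametric mixed-model /
# ANOVA machinery with assumption-free, seeded permutation tests on simple
# summary statistics.

#' Per-flask log-linear prey slope
#'
#' OLS slope of `ln(prey concentration)` versus day over the whole series —
#' the one-number summary of a flask's prey trajectory fed to the
#' permutation tests. Zero counts are excluded (log undefined).
#'
#' @param series A [count_series()].
#' @return Slope in day^-1.
#' @export
per_flask_slope <- function(series) {
  stopifnot(inherits(series, "count_series"))
  pos <- which(series$prey_conc > 0)
  if (length(pos) < 2)
    gk_domain_error(sprintf("flask '%s': fewer than 2 positive prey counts", series$flask_id))
  unname(ols_fit(series$days[pos], log(series$prey_conc[pos]))[["slope"]])
}

#' Per-flask slopes for a whole experiment
#'
#' @param experiment An [experiment()].
#' @return data.frame with columns `flask_id`, `prey_strain`,
#'   `predator_strain`, `treatment`, `slope`.
#' @export
experiment_slopes <- function(experiment) {
  stopifnot(inherits(experiment, "experiment"))
  df <- experiment$design
  df$slope <- vapply(experiment$series[df$flask_id], per_flask_slope, numeric(1))
  rownames(df) <- NULL
  df
}

perm_stats_exact <- function(x, n1) {
  n <- length(x)
  total <- sum(x)
  combs <- utils::combn(n, n1)
  s1 <- colSums(matrix(x[combs], nrow = n1))
  s1 / n1 - (total - s1) / (n - n1)
}

#' Two-group permutation test on flask slopes
#'
#' Tests whether the mean per-flask trajectory slope differs between two
#' treatment groups by relabelling flasks. The statistic is the difference
#' in group mean slopes; the two-sided p-value compares `|statistic|` against
#' the relabelled distribution.
#'
#' With `exact = TRUE` all distinct relabellings are enumerated
#' (`choose(n, n1)` of them, capped at 1e6) and
#' `p = #\{|permuted| >= |observed|\} / n_relabellings` (the identity
#' relabelling is included, so p > 0). Otherwise `n_perm` random
#' relabellings are drawn under `seed` and the add-one-corrected
#' `p = (1 + #\{|permuted| >= |observed|\}) / (1 + n_perm)` is reported.
#'
#' @param slopes Numeric vector of per-flask slopes.
#' @param labels Treatment label per flask; exactly 2 distinct labels, each
#'   with >= 2 flasks.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Integer seed for the random relabellings (ignored when
#'   `exact`); `NULL` uses the current RNG stream.
#' @param exact Enumerate all relabellings instead of sampling.
#' @return An object of class `permutation_test`: `statistic` (mean of first
#'   label minus mean of second, labels in sorted order), `p_value`,
#'   `n_permutations`, `seed`, `comparison`, `method`.
#' @examples
#' treatment_permutation_test(c(-.30, -.31, -.29, .07, .08, .06),
#'                            rep(c("grazed", "control"), each = 3), exact = TRUE)
#' @export
treatment_permutation_test <- function(slopes, labels, n_perm = 999,
                                       seed = NULL, exact = FALSE) {
  x <- as.numeric(slopes)
  labels <- as.character(labels)
  if (length(x) != length(labels))
    gk_validation_error("slopes and labels must have the same length")
  lv <- sort(unique(labels))
  if (length(lv) != 2)
    gk_validation_error("exactly 2 distinct labels required")
  n1 <- sum(labels == lv[1])
  if (n1 < 2 || length(x) - n1 < 2)
    gk_validation_error("each label needs at least 2 flasks")
  obs <- mean(x[labels == lv[1]]) - mean(x[labels == lv[2]])
  tol <- 1e-12 * max(1, abs(obs))
  if (exact) {
    if (choose(length(x), n1) > 1e6)
      gk_config_error("too many relabellings to enumerate; use exact = FALSE")
    stats <- perm_stats_exact(x, n1)
    p <- sum(abs(stats) >= abs(obs) - tol) / length(stats)
    nperm <- length(stats)
    seed_used <- NA_integer_
  } else {
    if (!is_scalar_number(n_perm) || n_perm < 1)
      gk_validation_error("n_perm must be a positive integer")
    n_perm <- as.integer(n_perm)
    stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(x), n1)
        mean(x[idx]) - mean(x[-idx])
      }, numeric(1))
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - tol)) / (1 + n_perm)
    nperm <- n_perm
    seed_used <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  }
  structure(list(statistic = obs, p_value = p, n_permutations = nperm,
                 seed = seed_used, comparison = paste(lv[1], "vs", lv[2]),
                 method = if (exact) "exact" else "sampled"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): %s\n", x$method, x$comparison))
  cat(sprintf("  mean difference = %.4g, p = %.4g (%d permutations%s)\n",
              x$statistic, x$p_value, x$n_permutations,
              if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Pairwise permutation comparisons of rate groups
#'
#' All pairwise two-sided permutation tests on differences in group means
#' (e.g. growth or ingestion rates per strain), with Holm step-down
#' adjustment across the pairs. Holm is used instead of a Tukey-style
#' parametric adjustment because it is exact under permutation and needs no
#' normality assumption.
#'
#' @param groups Named list mapping group label to a numeric vector of rate
#'   values; >= 2 groups, each with >= 2 values.
#' @param n_perm,seed,exact As in [treatment_permutation_test()]; when
#'   sampling, pair `i` uses seed `seed + i - 1`.
#' @return data.frame of class `pairwise_rate_comparison` with columns
#'   `group_a`, `group_b`, `statistic`, `p_value`, `p_adjusted`,
#'   `n_permutations`.
#' @export
pairwise_rate_comparison <- function(groups, n_perm = 999, seed = NULL,
                                     exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    gk_validation_error("groups must be a named list with >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    gk_validation_error("each group needs at least 2 values")
  pairs <- utils::combn(names(groups), 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    vals <- c(groups[[a]], groups[[b]])
    labs <- rep(c(a, b), c(length(groups[[a]]), length(groups[[b]])))
    pt <- treatment_permutation_test(vals, labs, n_perm = n_perm,
                                     seed = if (is.null(seed)) NULL else seed + i - 1,
                                     exact = exact)
    data.frame(group_a = a, group_b = b, statistic = pt$statistic,
               p_value = pt$p_value, n_permutations = pt$n_permutations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out <- out[, c("group_a", "group_b", "statistic", "p_value", "p_adjusted",
                 "n_permutations")]
  class(out) <- c("pairwise_rate_comparison", "data.frame")
  out
}
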