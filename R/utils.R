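# Internal helpers: structured error conditions and seeded evaluation.

gk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "grazekit_error"), call = call))
}

gk_format_error <- function(msg) gk_stop(msg, "gk_format_error")
gk_validation_error <- function(msg) gk_stop(msg, "gk_validation_error")
gk_domain_error <- function(msg) gk_stop(msg, "gk_domain_error")
gk_config_error <- function(msg) gk_stop(msg, "gk_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means: use the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# OLS of y on x: returns c(intercept, slope, r2). Manual so that the
# zero-variance-in-y case has a defined R^2 (1: the fit is perfect).
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) gk_domain_error("cannot fit a slope: all x values identical")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ssres <- sum((y - intercept - slope * x)^2)
  sstot <- sum((y - my)^2)
  r2 <- if (sstot <= 0) 1 else max(0, 1 - ssres / sstot)
  c(intercept = intercept, slope = slope, r2 = r2)
}
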