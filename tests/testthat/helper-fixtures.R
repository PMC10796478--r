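# Shared in-code fixtures and independent oracle helpers.

make_control <- function(id = "c1", strain = "preyA", days = c(0, 2, 4),
                         prey = c(1000, 1100, 1210)) {
  count_series(id, strain, "control", days, prey)
}

make_grazed <- function(id = "g1", strain = "preyA", days = c(0, 2, 4),
                        prey = c(1000, 800, 600), pred = c(200, 200, 200),
                        predator = "cilX") {
  count_series(id, strain, "grazed", days, prey, pred, predator)
}

toy_experiment <- function() {
  experiment(list(make_control(), make_grazed()))
}

write_counts_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

counts_df <- function() {
  rbind(
    data.frame(flask_id = "c1", day = c(0, 2, 4), prey_per_ml = c(1000, 1100, 1210),
               predator_per_ml = 0, treatment = "control", prey_strain = "preyA",
               predator_strain = ""),
    data.frame(flask_id = "g1", day = c(0, 2, 4), prey_per_ml = c(1000, 800, 600),
               predator_per_ml = c(200, 250, 300), treatment = "grazed",
               prey_strain = "preyA", predator_strain = "cilX"))
}

# Independent OLS oracle (lm-based; package internals use their own fit).
oracle_log_slope <- function(days, conc) {
  unname(coef(lm(log(conc) ~ days))[2])
}

oracle_log_r2 <- function(days, conc) {
  summary(lm(log(conc) ~ days))$r.squared
}

# Independent full-enumeration oracle for the two-group permutation test.
oracle_perm_p <- function(x, labels) {
  lv <- sort(unique(labels))
  n1 <- sum(labels == lv[1])
  obs <- mean(x[labels == lv[1]]) - mean(x[labels == lv[2]])
  combs <- combn(length(x), n1)
  stats <- apply(combs, 2, function(idx) mean(x[idx]) - mean(x[-idx]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}
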