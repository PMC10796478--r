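# High/low read-abundance co-occurrence screen for a prey taxon and a
# grazer taxon sequenced in separate size fractions. Descriptive only: read
# numbers from separately sequenced filters are not proportional between
# fractions, so no association statistic is computed.

quadrant_levels <- c("prey_high_grazer_high", "prey_high_grazer_low",
                     "prey_low_grazer_high", "prey_low_grazer_low")

#' Classify one sample's prey/grazer read abundances
#'
#' Prey counts as "high" iff `prey_reads > prey_high` and the grazer as
#' "low" iff `grazer_reads < grazer_low` — strict inequalities, so a sample
#' exactly on a threshold falls in the complementary class. Defaults are the
#' conventional 20,000 / 5,000 read cut-offs.
#'
#' @param prey_reads,grazer_reads Non-negative read counts. Vectorised.
#' @param prey_high Reads above which the prey is "high" (default 20000).
#' @param grazer_low Reads below which the grazer is "low" (default 5000).
#' @return Factor with levels `prey_high_grazer_high`,
#'   `prey_high_grazer_low`, `prey_low_grazer_high`, `prey_low_grazer_low`.
#' @examples
#' classify_sample(25000, 4800) # prey_high_grazer_low
#' @export
classify_sample <- function(prey_reads, grazer_reads,
                            prey_high = 20000, grazer_low = 5000) {
  v <- cbind(prey_reads, grazer_reads)
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    gk_domain_error("read counts must be finite and >= 0")
  ph <- v[, 1] > prey_high
  gl <- v[, 2] < grazer_low
  lab <- paste0(ifelse(ph, "prey_high", "prey_low"),
                ifelse(gl, "_grazer_low", "_grazer_high"))
  factor(lab, levels = quadrant_levels)
}

#' Co-occurrence summary of a prey and a grazer taxon
#'
#' For every sampled (lake, date) the prey's reads are taken from the large
#' size fraction and the grazer's from the small fraction (the fractions in
#' which a large microalga and a small ciliate are captured, respectively);
#' a taxon absent from its fraction counts as 0 reads. Each sample is then
#' classified with [classify_sample()] and the quadrant counts tallied.
#'
#' @param records An `abundance_records` data.frame from [read_abundance()].
#' @param prey_taxon,grazer_taxon Taxon labels to screen.
#' @param prey_high,grazer_low Thresholds, see [classify_sample()].
#' @param prey_fraction,grazer_fraction Which size fraction each taxon is
#'   read from (defaults `"large"` and `"small"`).
#' @return An object of class `cooccurrence_summary`: `samples` (scatter-ready
#'   data.frame with `lake`, `date`, `prey_reads`, `grazer_reads`,
#'   `quadrant`), `quadrant_counts` (named integer vector over the four
#'   quadrants), `thresholds`, `n_samples`.
#' @export
cooccurrence_summary <- function(records, prey_taxon, grazer_taxon,
                                 prey_high = 20000, grazer_low = 5000,
                                 prey_fraction = "large",
                                 grazer_fraction = "small") {
  req <- c("lake", "date", "fraction", "taxon", "reads")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    gk_validation_error("records must have columns lake, date, fraction, taxon, reads")
  if (!any(records$taxon %in% c(prey_taxon, grazer_taxon)))
    gk_config_error(sprintf("neither '%s' nor '%s' found in the abundance table",
                            prey_taxon, grazer_taxon))
  key <- unique(records[, c("lake", "date")])
  key <- key[order(key$lake, key$date), , drop = FALSE]
  sum_reads <- function(lk, dt, tax, fr) {
    sel <- records$lake == lk & records$date == dt &
      records$taxon == tax & records$fraction == fr
    if (any(sel)) sum(records$reads[sel]) else 0L
  }
  key$prey_reads <- mapply(sum_reads, key$lake, key$date,
                           MoreArgs = list(tax = prey_taxon, fr = prey_fraction))
  key$grazer_reads <- mapply(sum_reads, key$lake, key$date,
                             MoreArgs = list(tax = grazer_taxon, fr = grazer_fraction))
  key$quadrant <- classify_sample(key$prey_reads, key$grazer_reads,
                                  prey_high = prey_high, grazer_low = grazer_low)
  counts <- table(key$quadrant)
  rownames(key) <- NULL
  structure(list(samples = key,
                 quadrant_counts = stats::setNames(as.integer(counts), names(counts)),
                 thresholds = c(prey_high = prey_high, grazer_low = grazer_low),
                 n_samples = nrow(key)),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat(sprintf("Co-occurrence screen over %d (lake, date) samples\n", x$n_samples))
  cat(sprintf("  thresholds: prey high > %g reads, grazer low < %g reads\n",
              x$thresholds["prey_high"], x$thresholds["grazer_low"]))
  for (q in names(x$quadrant_counts))
    cat(sprintf("  %-22s %d\n", q, x$quadrant_counts[q]))
  invisible(x)
}

#' @export
as.data.frame.cooccurrence_summary <- function(x, ...) x$samples
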