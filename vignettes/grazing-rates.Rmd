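---
title: "Estimating ciliate grazing rates from batch-culture count series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ciliate grazing rates from batch-culture count series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazekit)
```

## The experimental setting

grazekit analyses batch-culture grazing experiments in which a small
predator (here, a prostomatid ciliate such as *Urotricha*) is added to a
culture of a microalgal prey (here, the bloom-forming raphidophyte
*Gonyostomum semen*), and both populations are counted — typically by
settling-chamber microscopy of Lugol-fixed aliquots — every couple of days
over a few weeks. Each grazed flask is paired with an ungrazed monoculture
of the same prey strain, which supplies the reference growth rate. The
question the analysis answers is: how much water does one predator clear of
prey per day, how many prey cells does it ingest per day, and does grazing
significantly alter the prey's trajectory?

## The model behind the estimator

The estimator assumes that, within one sampling interval, prey change
exponentially and the predator population is adequately summarised by its
time-averaged concentration. For an interval $[t_0, t_1]$ of length
$\Delta t$:

* prey growth rate in the ungrazed control,
  $k = (\ln N_{t_1} - \ln N_{t_0}) / \Delta t$;
* prey growth rate under grazing, $g$, computed the same way from the
  grazed flask;
* the time-average of an exponentially changing concentration is its
  logarithmic mean, $B_{avg} = (B_1 - B_0) / (\ln B_1 - \ln B_0)$, applied
  to the grazed flask's prey counts and, for the predator average $P$, to
  its predator counts;
* clearance rate $F = (k - g)/P$ (mL predator$^{-1}$ day$^{-1}$): the
  per-predator volume swept free of prey per day, read off the growth-rate
  deficit the grazers impose;
* ingestion rate $I = B_{avg} \cdot F$ (cells predator$^{-1}$ day$^{-1}$).

An exact property worth knowing: if the predator grows exponentially at
rate $\mu_c$ within the interval, the logarithmic mean of its endpoint
concentrations *equals* its true time average, so on noiseless data the
estimator recovers the generating clearance exactly — not just
approximately — for any $\mu_c \Delta t$. The "within 10% for
$\mu_c \Delta t \le 0.5$" recovery checks in the test suite therefore pass
with machine-precision margins; their role is to guard the implementation,
not to characterise an intrinsic bias.

Two growth-rate conventions are provided because both are in common use:
the endpoint estimator above (`exponential_growth_rate()`), and a
regression form (`linear_growth_rate()`) that fits ordinary least squares
to $\ln$(concentration) versus day and reports $\mu = e^{slope} - 1$, the
per-day multiplicative increase minus one. The regression variable is the
natural-log concentration; that is the only reading under which
$e^{slope}-1$ is dimensionally coherent, and it is documented here as an
interpretation rather than hidden in code.

### Biovolume morphometry

Cell volume is computed from per-cell length and width as
$V = \tfrac{4}{3}\pi \cdot L \cdot W^2$ — the full-dimension prolate
convention used for these measurements. Note this is $8\times$ the
semi-axis ellipsoid formula; `prolate_volume()` applies it verbatim and
says so in its documentation, because reproducing the field's convention
matters more than geometric orthodoxy. Strain means are means of per-cell
volumes (not volumes of mean dimensions), and strains are compared with a
pooled-variance Student t-test (`pooled_t_test()`), whose
$df = n_a + n_b - 2$ is the natural check that the pooled, not Welch, test
is in use. Inputs with length < width are accepted with a warning:
measurement order on micrographs can be ambiguous, and silently rejecting
such rows would bias summaries.

## Decline-window selection

Strong grazers drive the prey into a sustained, roughly log-linear decline,
and rate estimates are most meaningful over exactly that phase; outside it
(lag phases, post-depletion noise) the clearance formula divides small
noisy differences by small numbers. `detect_decline_window()` formalises
"the linear decline" as the longest contiguous run of at least `min_run = 3`
sampling points over which prey counts strictly decrease, all counts are
positive, and the log-linear fit achieves $R^2 \ge$ `r2_min` $= 0.90$, with
ties broken toward the earlier window. No numeric criterion for "linear
decrease" is standard, so both knobs are exposed; 0.90 accepts the modest
curvature that counting noise introduces while rejecting plateaus, and runs
shorter than 3 points cannot witness linearity at all. In
`mode = "decline_window"` the fit additionally requires the predator's
endpoint growth rate to be positive on each interval — grazing estimates
are only trusted while the grazer population is actually thriving —
and flags everything else `outside_decline_window`, excluded from summary
means but still reported.

## Numerical and edge-case policy

* **Zero counts** (a depleted flask) are never pseudo-counted. Log-based
  fits exclude them and flag the estimate; intervals with a zero endpoint
  get `NA` rates and the `zero_count_interval` flag. Pseudo-counts would
  silently bias rates precisely where depletion makes the data most
  interesting.
* **Negative clearances** (prey doing better with grazers than without)
  are reported unclamped and flagged `negative_clearance`, and they *do*
  enter summary means: truncation at zero would bias mean clearance upward.
* The **logarithmic mean** switches to its continuous limit ($B_0$) when
  the endpoints differ by less than $10^{-9}$ relative, and computes the
  denominator as `log1p((B1-B0)/B0)` to avoid cancellation near that
  boundary.
* **Interval-level $k$** comes from the strain-matched control over the
  same interval (averaged when a strain has several controls), keeping $k$
  and $g$ synchronous; a `global_k = TRUE` option uses the control's
  full-series rate instead, for designs where the control is too noisy
  interval-by-interval.
* Summary ingestion rates average unflagged intervals across intervals
  *and* prey strains (per predator strain). Whether one should instead
  average within strains first is a genuine ambiguity; interval-level
  averaging was chosen because it weights every valid observation equally,
  and the per-interval table is always available for other weightings.

## Permutation inference instead of mixed models

The treatment-effect question — does grazing change the prey trajectory? —
is often answered with linear mixed-effects models plus marginal-means
contrasts. This package deliberately substitutes a two-stage permutation
test (`treatment_permutation_test()`): each flask is reduced to the OLS
slope of its log-prey trajectory, and the difference in mean slope between
treatment groups is compared against the distribution obtained by
relabelling flasks. The substitution is prominent and intentional: the
permutation test addresses the same scientific contrast with no normality
or variance-structure assumptions, is exact for small designs (full
enumeration is used whenever requested and feasible), and is reproducible
bit-for-bit under a seed. What is given up is the mixed model's ability to
borrow strength across time points and estimate variance components;
for designs of a handful of flasks, the flask-level summary statistic is
the honest resolution anyway. Pairwise rate comparisons
(`pairwise_rate_comparison()`) use the same machinery with Holm step-down
adjustment — exact under permutation, unlike a Tukey HSD, which assumes
normal theory.

Sampled permutation p-values carry the add-one correction
$p = (1 + \#\{|T^\pi| \ge |T|\})/(1 + n_{perm})$, so $p = 0$ is impossible;
exact enumeration includes the identity relabelling, with the same effect.

## What the simulator emulates — and what it does not

`simulate_grazing()` implements the generative model the estimator assumes:
exogenous exponential predator dynamics $C(t) = C_0 e^{\mu_c t}$ and prey
obeying $dB/dt = (k - F \cdot C(t))\,B$, with the closed form
$\ln B(t) = \ln B_0 + kt - F C_0 (e^{\mu_c t} - 1)/\mu_c$ (limit
$F C_0 t$ at $\mu_c = 0$). Predator growth is deliberately *not* coupled to
prey consumption: the estimator assumes nothing about predator yield, and
small ciliates are known to regrow on bacteria or by cannibalism after
depleting their prey, so a yield coupling would over-model. The test suite
verifies the closed form against an independent numerical ODE integration
(deSolve, log-space to avoid underflow at strong decay) across a 200-point
parameter grid.

Observation noise emulates counting error only: `lognormal` multiplies
each count by $e^{\mathcal{N}(0,\sigma^2)}$ with default $\sigma = 0.1$, a
plausible settling-chamber counting error; `poisson` draws the cells seen
in a counted aliquot. Real experiments also contain biological
between-replicate variability, wall growth, and non-exponential phases —
none of which the generator produces. Passing the recovery tests therefore
demonstrates that the estimator chain is correct *under its own
assumptions*, not that those assumptions hold in any particular lab system.

`make_fixture_experiment()` emits a complete design — 3 prey strains, each
with an ungrazed control and one grazed flask per each of two predator
strains (9 flasks), days 0, 2, …, 20, starting from 1000 prey and
200 predators mL$^{-1}$ — under three scenarios. The scenario parameters
are fixed study conditions chosen once: prey growth $k = 0.074$ d$^{-1}$
(a typical slow raphidophyte monoculture rate); the strong grazer uses
$F = 5\times10^{-5}$ mL pred$^{-1}$ d$^{-1}$ with a 100-fold predator rise
over 20 days, which drives prey to roughly 6% of its start — the magnitude
of depletion such experiments report; the weak grazer uses
$F = 2\times10^{-5}$ with modest predator growth, leaving prey at ~68% of
the control; the null scenario sets $F = 0$ so grazed flasks are
distributed exactly like controls while the predator still grows (as if on
an alternative food source). The two-grazer, nine-flask design is what
makes null calibration of the permutation test meaningful: with 3 controls
versus 6 grazed flasks the exact two-sided test has attainable p-values
below 0.05 (minimum $1/84$), and its size at $\alpha = 0.05$ is $4/84
\approx 0.048$.

## Co-occurrence screening

For environmental amplicon surveys, `cooccurrence_summary()` classifies
each (lake, date) sample by whether the prey taxon's reads (taken from the
large, 10–100 µm size fraction, where a large alga is captured) exceed a
"high" threshold (default > 20,000) and whether the grazer taxon's reads
(small, 0.2–10 µm fraction) fall below a "low" threshold (default
< 5,000), with strict inequalities and missing taxa counted as 0 reads.
The output is purely descriptive — quadrant counts and a scatter-ready
table. No association statistic is computed, on purpose: the two fractions
are sequenced as separate samples, so their read numbers are not mutually
proportional, and a formal test would imply quantitative inference the
data cannot support.

## Problem sizes and reproducibility

All validation is done on data generated in code: 11-point series per
flask, 9-flask fixtures, 20-replicate noise studies, a 200-point
ODE-comparison grid, and 1000-replicate null calibrations — sizes at which
every property is checked exactly or with tight Monte-Carlo bounds while
the whole suite runs in seconds. Every stochastic path takes an explicit
seed, equal seeds give bit-identical output, and the command-line layer
refuses to run stochastic subcommands without one.

## Known limitations

* Clearance is linear in prey concentration; no functional-response
  (Holling) saturation is modelled or fitted.
* The predator average within an interval is its logarithmic mean; no
  higher-order correction for predator dynamics is applied.
* The co-occurrence screen is descriptive only.
* The simulator's noise is observational; it does not generate
  between-replicate biological variance, so recovery bounds measured here
  are optimistic for real data.

## A worked run

```{r example, eval = FALSE}
fx <- make_fixture_experiment("strong_grazer", seed = 1)
fit <- heinbokel(fx$experiment, mode = "decline_window")
print(fit)
coef(fit)

sl <- experiment_slopes(fx$experiment)
treatment_permutation_test(sl$slope, sl$treatment, exact = TRUE)
```
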