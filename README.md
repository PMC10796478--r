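# grazekit

Rate estimation for microzooplankton grazing experiments.

`grazekit` analyses batch-culture predator–prey experiments in which a
small grazer (for example a prostomatid ciliate such as *Urotricha*) is
added to a culture of a microalgal prey (for example the bloom-forming
raphidophyte *Gonyostomum semen*) and both populations are counted every
few days. It answers three questions: how fast do the populations grow,
how much water does each predator clear of prey per day, and does grazing
significantly change the prey's trajectory. It also ships a biovolume
morphometry module, a high/low co-occurrence screen for environmental
amplicon surveys, and a seeded predator–prey simulator used for
parameter-recovery validation.

## The estimator

For each grazed flask paired with an ungrazed monoculture of the same
prey strain, and each interval between consecutive sampling days:

- prey growth in the control: *k* = (ln *N*<sub>t</sub> − ln *N*<sub>0</sub>) / *t*
- prey growth under grazing: *g*, same formula on the grazed flask
- *B*<sub>avg</sub> = (*B*<sub>1</sub> − *B*<sub>0</sub>) / (ln *B*<sub>1</sub> − ln *B*<sub>0</sub>),
  the logarithmic mean prey concentration (the time-average of an
  exponentially changing population); *P* is the same applied to the
  predator counts
- clearance rate **F = (k − g) / P** (mL predator⁻¹ day⁻¹)
- ingestion rate **I = B<sub>avg</sub> · F** (cells predator⁻¹ day⁻¹)

This is the classical growth-rate-difference (Heinbokel-style) method.
For strong grazers the fit can be restricted to the detected log-linear
prey-decline window (longest run of ≥ 3 strictly decreasing samplings
with log-linear R² ≥ 0.9) intersected with intervals of positive predator
growth (`mode = "decline_window"`).

Cell biovolumes use the full-dimension prolate convention
V = 4/3 π · length · width², and strains are compared with a
pooled-variance Student t-test (df = n₁ + n₂ − 2). Treatment effects on
prey trajectories are tested by a seeded permutation test on per-flask
log-slopes (exact enumeration for small designs), replacing mixed-model
machinery with an assumption-free test of the same contrast.

## Worked example

```r
library(grazekit)

fx  <- make_fixture_experiment("strong_grazer", seed = 1)   # 9 flasks, days 0..20
fit <- heinbokel(fx$experiment, mode = "decline_window")
fit
#> Heinbokel grazing-rate fit
#>   mode: decline_window (R2 >= 0.90, run >= 3)
#>   6 grazed flask(s), 60 interval(s)
#>
#> Summary over unexcluded intervals (per predator strain):
#>  predator_strain n_intervals  mean_k  mean_g    mean_F  mean_I
#>          grazerA          12 0.08012 -0.3311 5.268e-05 0.03957
#>          grazerB          12 0.07864 -0.2328 6.621e-05 0.07381
```

Controls grow at about the prey's intrinsic 0.074 day⁻¹ (`mean_k`), grazed
prey declines steeply inside the decline window (`mean_g` < 0), and the
recovered clearance (`mean_F`, mL predator⁻¹ day⁻¹) brackets the generating
value 5 × 10⁻⁵ used by the simulator; `mean_I` is the per-predator
ingestion in prey cells day⁻¹.

```r
sl <- experiment_slopes(fx$experiment)
treatment_permutation_test(sl$slope, sl$treatment, exact = TRUE)
#> Permutation test (exact): control vs grazed
#>   mean difference = 0.1796, p = 0.0119 (84 permutations)
```

The grazing treatment significantly flattens/reverses the prey slope
(p ≈ 0.012 from full enumeration of all 84 relabellings).

```r
path <- system.file("extdata", "synthetic_survey.csv", package = "grazekit")
cooccurrence_summary(read_abundance(path),
                     "Gonyostomum_semen", "Urotricha_cf_pseudofurcata")
#> Co-occurrence screen over 45 (lake, date) samples
#>   thresholds: prey high > 20000 reads, grazer low < 5000 reads
#>   prey_high_grazer_high  0
#>   prey_high_grazer_low   16
#>   prey_low_grazer_high   24
#>   prey_low_grazer_low    5
```

The bundled survey table is synthetic (see the file name); it illustrates
the opposing-abundance pattern the screen is designed to tabulate.

A thin command-line wrapper is installed at
`system.file("cli", "grazekit.R", package = "grazekit")` with subcommands
`validate`, `volumes`, `rates`, `compare`, `cooccur` and `simulate`
(stochastic subcommands require `--seed`).

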