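# paleodem

Radiocarbon-based palaeodemography with a palaeoclimate variability
index, packaged as a tested analysis pipeline.

## The problem

Archaeologists use the density of radiocarbon-dated material through time
as a proxy for relative prehistoric population size: more people deposit
more datable material. The standard instrument is the **summed
probability distribution (SPD)** — the cell-wise sum of many calibrated
^14^C date densities — interrogated with Monte Carlo methods, because the
calibration process itself imprints artefacts that eyeballing cannot
separate from demography. This package implements that inferential
machinery for continental-scale questions of the kind posed about
mid-Holocene South America: did population decline set in around
8.6 k cal BP, in how many phases, and how does its timing relate to the
frequency of extreme hydroclimatic events?

`paleodem` provides, as plain R functions:

- **Calibration** (`calibrate`, `calibrate_dates`): Gaussian-error
  calibration against `.14c`-format curves, with marine reservoir
  handling (`apply_reservoir`, `nearest_delta_r`);
- **SPD construction** (`bin_dates`, `sum_probabilities`,
  `rolling_mean`): same-site dates binned within 200 ^14^C years
  (complete-linkage) so over-dated sites count once, cell-wise summation,
  centred 100-year smoothing;
- **Null-model tests** (`fit_growth_model`, `simulate_null`,
  `model_test`): exponential/linear/logistic trends fitted by nonlinear
  least squares; envelopes built per run by drawing as many calendar
  dates as there are bins from the fitted curve, back-calibrating them
  through the curve error model with errors resampled from the empirical
  pool, and re-summing; z-transformed pointwise 95% bands, deviation
  segments, and a plus-one global p;
- **Regime-shift location** (`breakpoint_sweep`, `conditioned_test`): a
  piecewise-AIC sweep over candidate breakpoints, and a null conditioned
  on the pre-breakpoint regime only;
- **Regional comparison** (`permutation_test`, `pairwise_permutation`):
  mark permutation of region labels at bin level;
- **Climate variability index** (`rolling_mad_outliers`,
  `combine_sources`, `bin_anomalies`): ±3 rolling-MAD outlier detection
  per proxy record with resolution-scaled ~100-year windows, flags summed
  into 100-year bins, bins above mean + 2 SD flagged;
- **Synthetic data** (`simulate_dates`, `make_toy_calcurve`,
  `simulate_climate_record`): generators with known ground truth so every
  stage is testable without downloads.

The model at the core of the null test, for a date with ^14^C age $y$ and
error $\sigma$: the calibrated density at calendar year $t$ is
$f(t) \propto \phi(y;\,\mu(t),\,\sqrt{\sigma^2+\sigma_c(t)^2})$ with
$(\mu, \sigma_c)$ the calibration curve; the null SPD is the sum of $n$
such densities for $y_i \sim N(\mu(t_i), \sigma_c(t_i))$, $t_i$ drawn
from the fitted growth curve. See `vignettes/paleodem-methods.Rmd` for
the full account, including why the observed series joins the simulated
set when the envelope is estimated.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study
on the reference synthetic scenario (a three-phase crash beginning at
8.6 k cal BP). Running them in order:

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_continental_spd.R
Rscript analysis/03_exponential_null_test.R
Rscript analysis/04_breakpoint_conditioned.R
Rscript analysis/05_regional_permutations.R
Rscript analysis/06_climate_index.R
```

`04_breakpoint_conditioned.R` prints, for the bundled scenario
(abridged to the major downturn segments):

```
Breakpoint sweep (linear): optimum at 8700 cal BP
SPD model test: global p = 0.004975 (200 runs), stat = 311.846
  ...
  below segment 6900-6575 cal BP
  below segment 7635-7175 cal BP
  below segment 8580-7910 cal BP
  ...
5 post-breakpoint downturn phase(s); first begins at 8580 cal BP
```

meaning: the piecewise-AIC sweep locates the regime shift within one
candidate step of the planted 8600 cal BP; the SPD falls significantly
below a null conditioned on the earlier regime (global p ≈ 0.005 at 200
runs, the plus-one minimum being 1/201), the three major downturn phases
matching the planted crashes at 8.6, 7.7 and 6.9 k cal BP (the remaining
two "phases" are a narrow window-edge segment near 2 k cal BP and a
short echo at 6.5 k). The climate driver then reports

```
Climate variability index: 100 bins of 100 yr, 334 anomalies from 10 record(s)
  mean 3.34, sd 2.38; 4 bin(s) above mean + 2 SD: 7300, 8100, 8200, 8400 cal BP
```

— the three planted burst bins at 8.4–8.1 k cal BP clear the 2-SD line,
plus one noise-floor bin.

Interactive use mirrors the drivers:

```r
library(paleodem)
curve <- make_toy_calcurve(span = c(0, 15000), wiggle_amp = 20, sigma = 15)
sc <- demographic_scenario("demo",
        crash_density(crashes = three_phase_crashes()),
        n_dates = 3000, n_sites = 400)
dates <- filter_dates(simulate_dates(sc, curve, seed = 1))
dens  <- calibrate_dates(dates, curve, step = 5)
bins  <- bin_dates(dates, h = 200)
spd   <- sum_probabilities(dens, bins, window = c(2000, 12000))
conditioned_test(spd, spd$n_bins,
                 data.frame(c14_error = dates$c14_error,
                            material = dates$material),
                 curve, breakpoint = 8600, runs = 1000, seed = 2)
```

A one-call orchestration over CSV/`.14c` inputs is available as
`run_pipeline(run_config(...), out_dir)`.

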