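---
title: "Methods: SPD null-model testing and the climate variability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPD null-model testing and the climate variability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleodem implements a radiocarbon-based palaeodemographic inference
pipeline — summed probability distributions (SPDs) of calibrated dates
tested against Monte Carlo growth-model nulls and regional permutation
nulls — together with a robust rolling-MAD index of palaeoclimatic
variability, so that mid-Holocene demographic decline analyses can be run
end to end on synthetic or deposited data. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The population proxy

The core assumption is monotonicity between past population size and the
amount of datable archaeological material deposited: more people leave
more dated charcoal. Each determination $(y_i, \sigma_i)$ (a ^14^C age and
its 1-$\sigma$ error) is converted to a density over calendar years $t$
through a calibration curve $(\mu(t), \sigma_c(t))$:

$$ f_i(t) \propto \phi\!\left(y_i;\, \mu(t),\, \sqrt{\sigma_i^2 + \sigma_c(t)^2}\right), $$

with $\mu$ and $\sigma_c$ linearly interpolated between curve knots.
Marine samples are calibrated against the marine curve after subtracting
the locally nearest $\Delta R$ reservoir offset and inflating the error in
quadrature. The per-date density vector is scaled by its integral over the
full curve support; with `normalise = TRUE` the trimmed vector is rescaled
to sum exactly one, otherwise the trimmed tail mass (at most `trim_tail`
of the peak per cell, default $10^{-5}$) is simply absent. Under this
contract the two modes differ only by that tail mass; both are exposed
because downstream mass-conservation checks rely on the normalised mode
while the default pipeline keeps the unrescaled vector.

Same-site dates within `h = 200` ^14^C years are grouped into bins
(complete-linkage clustering cut at `h`; a fixed-width variant is
available behind the `method` flag because the literature rarely states
which was used) and each bin contributes the cell-wise *mean* of its
member densities — one date-equivalent — so intensively dated sites do not
dominate. Bin curves are summed over the analysis window, by default
12–2 k cal BP with reporting focused on 9–3 k cal BP, and smoothed for
display with a centred 100-year rolling mean (truncated symmetrically at
the edges; the effective window is `2*floor(w/2)+1` cells).

## Growth-model nulls by back-calibration

A growth family (exponential $a e^{bt}$, linear $a + bt$, or logistic
$K/(1+e^{-r(t-t_0)})$, $t$ in cal BP) is fitted to the SPD by nonlinear
least squares (`minpack.lm`, with jittered restarts). Goodness of fit is
reported as the squared Pearson correlation between fitted and observed
series, and families are compared by AIC under i.i.d. Gaussian residuals;
the residual sum of squares is floored at an RMS of $10^{-8}$ so that
numerically perfect fits do not produce divergent log-likelihoods.

The null envelope follows the standard back-calibration recipe: per run,
draw as many calendar years as there are bins from the fitted curve
treated as a density on the analysis window; convert each to a ^14^C age
through the curve error model; attach a measurement error resampled with
replacement from the empirical error pool (jointly with the date's
material, so the marine fraction of simulations matches the data);
re-calibrate; sum. Observed and simulated SPDs are z-transformed by the
per-cell mean and SD of the simulated set, and the pointwise 2.5%/97.5%
quantiles of the z-scaled simulations form the 95% band. Deviation
segments are maximal runs of cells where the observation exits the band;
the global statistic is the total area of band exceedance; and the global
p-value uses the plus-one Monte Carlo convention
$(1 + \#\{\text{sim} \ge \text{obs}\})/(\text{runs}+1)$, never zero.

One calibration detail matters for the size of the test. If the observed
statistic is referred to a band, mean and SD estimated from the
simulations alone, the observation is not exchangeable with the
simulations and the test is measurably anti-conservative at Monte Carlo
sizes in the hundreds. `model_test()` therefore includes the observed
series in the set used to estimate the per-cell mean/SD and the quantile
band, making the $n+1$ series exactly exchangeable under the null — the
same convention the permutation test uses when it counts the observed
label assignment as one permutation. The envelope object still records
the simulation-only band for plotting.

### Conditioning and the breakpoint sweep

Fitting a single null to the whole window lets a mid-sequence regime
shift drag the fit and mask deviations. The package therefore (i) locates
the most likely regime boundary with `breakpoint_sweep()`: for every
candidate $c$ on a 100-year grid over 10–8 k cal BP, the family is fitted
separately to $[c, 12000]$ and $[2000, c]$, each side carrying its own
Gaussian variance, and the candidate minimising the summed AIC wins (a
profile flatter than 2 AIC units is flagged as having no distinct
optimum); and (ii) runs `conditioned_test()`: the null is fitted on the
pre-breakpoint window only — linear by default, matching the quasi-stable
weakly linear early-regime description — extrapolated across the whole
window, and the Monte Carlo test is run against it. Segments younger than
the breakpoint are the reportable deviations.

## Regional permutation tests

Regional SPDs are compared with the continental trend by mark
permutation: region labels are shuffled (exactly preserving label
counts), per-label SPDs are recomputed from the already-calibrated
densities, and each label's observation is referred to its permuted set
with the same z-transform/band/exceedance machinery, the observed
assignment counting as one permutation. Labels are permuted at bin level
by default so several dates from one over-dated site cannot leak label
information; date-level permutation is available behind `level = "date"`.
The sum of per-label SPDs equals the pooled SPD for every permutation by
construction. Pairwise comparisons pool only the two sets; their
statistic is the sum of both labels' exceedances, which makes the p-value
invariant to swapping the sets.

## Climate variability index

Each proxy record is screened for extreme hydroclimatic anomalies with a
rolling robust rule: a point is flagged when it deviates from its centred
window median by more than $k = 3$ times the window MAD. The window is
scaled to the record's resolution (the median successive age difference)
as `max(3, round(100 / resolution))` points, approximating a 100-year
window across records of different sampling density; records coarser than
3 points per 100 years are rejected and logged. Edge windows are
truncated and cannot flag with fewer than 3 points; a zero-MAD window
flags any centre that deviates at all, so constant records yield no
flags. The MAD carries the usual 1.4826 Gaussian consistency constant
(`stats::mad()`'s convention), making $k = 3$ an approximately 3-$\sigma$
— deliberately conservative — threshold with a false-positive rate well
under 1% per point on Gaussian noise for windows of a few dozen points;
the raw MAD is available via `mad_constant = 1`, but at $k = 3$ it is
only a ~2-$\sigma$ rule and floods the index with noise flags. The
evaluated point is included in its own window by default
(`include_centre`), the less sensitive of the two conventions.

Multiple sources of one record (e.g. two speleothems from one cave) are
screened separately and merged, flags within 10 years collapsing to one
event. Flags from all records are then summed into half-open 100-year
bins aligned to multiples of 100 cal BP; only incidence is counted, not
magnitude, sign or location. Bins exceeding the dataset mean by more than
two standard deviations (both computed over the full analysis window —
the reporting window is a display choice) mark significantly above-normal
variability.

## The synthetic-data generator

`simulate_dates()` draws calendar years in proportion to a scenario
density, back-calibrates them through a toy curve's error model, attaches
log-normal 1-$\sigma$ errors (median 60 years, log-SD 0.45, truncated at
200 years by resampling — the shape of large empirical compilations,
respecting the >200-year filter), allocates dates to sites with a
Zipf(1.2) size bias so that over-dated sites genuinely exercise the
binning, and fills region-consistent site metadata so `assign_region()`
reproduces the scenario's labels. Toy calibration curves are
$\mu(t) = \text{slope}\cdot t + A\sin(2\pi t/P)$ with constant curve
error; monotonicity (slope $> 2\pi A/P$) is enforced unless explicitly
disabled. `simulate_climate_record()` plants spikes of known age and
amplitude on trend-plus-noise series. All generators are pure functions
of their parameters and a mandatory seed.

The reference scenario mirrors the study conditions the package targets:
quasi-stable weakly linear early-Holocene growth, then three crash phases
dropping relative population to 30% of trend beginning at 8.6, 7.7 and
6.9 k cal BP with 200-year recoveries; and a ten-record proxy set, eight
records carrying anomaly bursts at 8.45/8.25/8.15 k cal BP. What the
generator does *not* emulate: real spatial geography beyond region
labels, calibration-curve plateaus of the real Holocene curves
(toy wiggles are regular sinusoids), heterogeneous per-record proxy
seasonality, taphonomic age-dependent loss, and inter-laboratory error
structure. Passing tests therefore demonstrate the statistical machinery
under controlled conditions, not the historical conclusions themselves.

## Numerical choices and problem sizes

- Calendar grid: 1-year default for single-date calibration, 5-year for
  the Monte Carlo engines; densities are evaluated at cell centres, with
  an optional sub-cell quadrature (`fine`) for high-accuracy work. The
  engines locate each date's support by an 8-$\sigma$ window, outside
  which the Gaussian contributes less than $10^{-14}$ of its peak.
- The Peru–Chile border latitude is fixed at −18.35°; Pacific-coast
  membership below the 300 m contour is operationalised as
  Chile anywhere, or Peru/Ecuador west of −74.5° longitude, since the
  package deliberately does no geocoding or DEM lookups.
- Accumulation orders in SPD summation are canonicalised (sorted by bin
  then lab id) so results are bit-identical under input permutation.
- Monte Carlo sizes: the analysis drivers default to 200 runs and the
  acceptance run to 1000 runs (the minimum reportable p is then
  1/1001 < 0.001); the package's statistical validation uses 100–200
  runs per test and 50–200 replicates per property, sizes at which the
  type-I and power properties reported in the test suite are stable.

## Known limitations

- The breakpoint sweep scores a piecewise fit with independently fitted
  variances on each side; it locates level/trend discontinuities well but
  is not a general multiple-changepoint method.
- The conditioned test extrapolates a linear pre-regime fit across the
  whole window; for strongly curved early regimes the exponential or
  logistic families should be selected instead.
- The "non-normalised" summation contract keeps the global scaling of
  each density vector, so it differs from the normalised mode only
  through tail trimming; users wanting rcarbon-style raw-likelihood
  summation should calibrate with `trim_tail = 0` and sum the raw
  Gaussian densities themselves.
- Permutation tests assume calibrated densities are fixed under label
  permutation; they inherit whatever biases the calibration and binning
  stages carry.
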