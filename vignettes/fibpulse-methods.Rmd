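---
title: "Methods: high-frequency FIB variability and driver analysis"
author: "fibpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-frequency FIB variability and driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Recreational beaches are managed on fecal indicator bacteria (FIB) —
total coliforms (TC), *E. coli* (EC) and *Enterococcus* (ENT) — measured
by culture assays in units of MPN/100 mL. Routine monitoring is weekly or
less frequent, yet FIB concentrations in the nearshore can change on
sub-hourly time scales, so a single sample may misrepresent water quality
at the time of use. fibpulse implements the analysis chain for a
*high-frequency sampling event*: a 48-hour deployment sampled every 30
minutes (N = 96), optionally with a nested 1-minute "sprint" block,
together with co-measured environmental covariates (water temperature,
salinity, chlorophyll *a*, turbidity, solar irradiance, tide level, and
airport meteorology).

The chain has four stages:

1. **Censoring-aware preprocessing** (`read_event_csv()`,
   `process_event()`): left-censored concentrations (below the assay lower
   limit of detection, 10 MPN/100 mL) are replaced by 1 MPN/100 mL,
   missing covariate values are linearly interpolated, and model features
   are derived.
2. **Variability analysis** (`variability_report()`): the coefficient of
   variation, the normalized adjacent-sample difference
   $\delta_i(t) = |c(t+i) - c(t)| / \mu$, a downsampling analysis of
   $\delta_i$ across sampling intervals, counts of detection- and
   exceedance-status changes between adjacent samples, and the partial
   autocorrelation function.
3. **Association screening** (`association_report()`): Spearman
   correlations between log10 FIB and environmental variables lagged up to
   3 hours, per-variable best-lag selection, and Kruskal–Wallis
   comparisons across day/night, tide and cloud categories.
4. **A two-part hurdle model** (`fit_hurdle()`): a random-forest binary
   part classifying detection above the LOD, pruned by permutation feature
   importance, and a generalized-least-squares concentration part with
   AR(2) errors, pruned by iterative variance-inflation-factor removal;
   overall predictions are the product of the two parts.

A synthetic-data generator (`generate_event()`) emulates the statistical
structure this chain assumes, so every stage is exercisable and testable
without field data.

## Preprocessing conventions

* **Censoring.** Values below the lower LOD are flagged and replaced by 1
  MPN/100 mL. The replacement only affects summaries and plots; the hurdle
  model treats censored samples through its binary part, so the choice of
  substitute does not drive the regression.
* **Exceedance** is strict: a sample exceeds when its concentration is
  strictly greater than the single-sample threshold (TC 10,000; EC 400,
  the fecal-coliform proxy; ENT 104 MPN/100 mL). A sample exactly at the
  threshold does not exceed, following the regulatory convention of
  concentrations *rising above* the standard.
* **Interpolation.** Interior gaps are filled linearly in time; leading or
  trailing gaps are extended from the nearest observed value, since linear
  interpolation needs a neighbour on both sides. Series longer than ten
  samples with more than 20% missing fail loudly rather than being
  silently patched. Irradiance is forced to 0 W/m² at night *after*
  interpolation so night-time gaps cannot acquire positive irradiance.
* **Wind decomposition.** With $\theta$ the direction the wind blows
  toward (meteorological direction + 180°) and a beach-normal angle of
  140° from true north, `owind` $= s\cos(\theta - 140°)$ is positive for
  onshore flow along the normal and `awind` $= s\sin(\theta - 140°)$ is
  positive 90° counter-clockwise of the normal. Any fixed convention works
  because modeling uses z-scored variables; this one is chosen so the
  projection identity `owind² + awind² = wspd²` holds exactly.
* **Clock features.** `hours_from_noon` uses local clock noon rather than
  astronomical solar noon — an approximation adequate for a two-day
  record. Timestamps are treated as timezone-naive local standard time.
* **Daytime.** If no flag is supplied, day is defined by positive
  irradiance; for synthetic data the generator's daylight window (06:15 to
  20:15) applies.

## The variability statistics

$\delta_i$ divides the absolute change between samples $i$ minutes apart
by the mean concentration $\mu$ of the entire series, so $\delta = 1$
means adjacent samples differ on average by the whole-record mean. Both
$\delta$ and the CV are computed on the raw (substituted) concentration
scale, not on log10 values — that is the scale on which the statistic has
its interpretation, and the scale consistent with CV = sd/mean summaries
of concentration. The sample standard deviation uses the $n-1$
denominator.

**Downsampling.** Resampling a 30-minute record to a coarser interval $k$
steps wide admits $k$ choices of first sample. `downsample_delta()`
enumerates all offsets, recomputes $\mu$ from each resampled subseries
(each downsampled dataset is analysed as a dataset in its own right), and
reports the mean and standard deviation of the per-offset mean $\delta$.
The spread across offsets is the practically important quantity: it is the
luck-of-the-draw range a sparse monitoring program is exposed to.

**PACF.** Partial autocorrelations come from the Durbin–Levinson recursion
on sample autocorrelations, with the large-sample two-sided band
$\pm 1.96/\sqrt{n}$.

## Association screening

Spearman correlations are tie-corrected (average ranks) with p-values from
the asymptotic t approximation. Cross-correlation pairs each FIB sample
with the covariate value observed $L$ minutes earlier, $L \in \{0, 30,
\ldots, 180\}$; lagged values that precede the record start are dropped
pairwise (a 48-h record loses at most six pairs). For each covariate only
the lag with the largest $|\rho|$ is kept, ties broken toward the smaller
lag; `daytime` and `hours_from_noon` are exempt because they encode the
diel clock itself. FIB enters as log10 concentration, which by monotone
invariance leaves Spearman values unchanged — asserted by test rather than
assumed. Variables constant over the record (e.g. a cloud category that
never occurs) carry no rank information and are dropped from the screen.
No multiple-testing correction is applied to the screen; it is a
descriptive filter, not an inference.

## The hurdle model

FIB records with censored samples are zero-inflated: part of the question
is *whether* the indicator is quantifiable, part is *how much* given that
it is. The hurdle model separates the two.

**Binary part.** A random forest (100 trees, bootstrap resampling,
$\lfloor\sqrt{p}\rfloor$ candidate variables per split, unlimited depth)
classifies detection. Variables are selected by permutation feature
importance: the mean drop in in-sample accuracy over five shuffles of one
column at evaluation time. We shuffle at evaluation time without refitting
per shuffle — the standard permutation-importance algorithm — and remove
variables whose mean importance is not positive (sampled importances
scatter around zero for uninformative variables; negative values are the
same evidence as zero). The forest is then refit on the survivors and
importances are recomputed from the refit, so reported values are
normalized to the final variable set. An indicator never measured below
the LOD has no binary part.

**Concentration part.** Log10 concentration given detection is modelled by
feasible generalized least squares with AR(2) errors: OLS first, then five
rounds of (i) re-deriving residuals on the original scale from current
coefficients, (ii) estimating the two AR coefficients by least squares of
the residual on its lags, (iii) quasi-differencing response, intercept and
columns by the AR filter and refitting. Standard errors, t statistics and
p-values come from the final whitened regression; with order 0 the
procedure reduces exactly to OLS, which pins the contract by test. AR
estimation uses least squares on lagged residuals rather than Yule–Walker;
at the sample sizes involved the two agree to well within estimation
noise (cross-checked against `stats::ar.ols` in the test suite).

Before fitting, variance inflation factors ($1/(1-R^2_j)$ from OLS of
column $j$ on the rest) are computed and the largest-VIF variable is
removed repeatedly until all VIFs are below 5. VIF pruning applies to the
concentration part only — the binary part is pruned solely by permutation
importance. Both prunings are logged; the removal order is the audit
trail.

**Combination and metrics.** Overall predictions are the binary class
(majority vote, 0 or 1) times the concentration-part prediction, so a
predicted non-detect maps to log10 of the substitute value (0). All
metrics are in-sample: these are descriptive models of association over a
single event, not forecasts, and a train/test split of 96 autocorrelated
samples would measure mostly the split. $R^2 = 1-\mathrm{SSE}/\mathrm{SST}$,
RMSE is in log10 units, and the Durbin–Watson statistic is computed on the
concentration part's whitened residuals (values near 2 indicate the AR(2)
structure absorbed the serial correlation). Overall metrics encode
below-LOD observations as 0.

A probability-weighted alternative to the hard binary class would change
little when in-sample detection accuracy is 1, as it typically is here;
the hard class keeps the product interpretation exact.

## The synthetic generator

`generate_event()` produces a 48-h, 30-min event (N = 96): tide as a
clipped sum of semidiurnal (12.42 h) and diurnal (23.93 h) sinusoids
spanning roughly 0.1–1.6 m above MLLW; covariates as diel/tidal
deterministic components plus AR(1) noise with ranges matching a summer
harbor deployment (salinity ~34, chlorophyll skewed up to ~180 µg/L,
turbidity 3–256 NTU, wind averaging ~3 m/s); irradiance as a half-sinusoid
zeroed at night and damped under cloud; and cloud category as a persistent
three-state Markov chain. FIB follow the lagged log-linear response

$$\log_{10} c(t) = \alpha + \sum_j \beta_j z_j(t - \mathrm{lag}_j) + \varepsilon(t)$$

with $z_j$ z-scored derived features, $\varepsilon$ AR(2) on the log10
scale, and left-censoring below 10 MPN/100 mL. Default coefficients mirror
the magnitudes of a fitted Enterococcus model at an enclosed beach
(chlorophyll and clear-sky effects ~+0.2, hours-from-noon ~−0.23, a weak
negative tide-state effect, AR structure (0.5, 0.2), innovation sd 0.5),
giving roughly a quarter of ENT samples censored; the EC-like
configuration censors ~10–20% and the TC-like configuration sits far
enough above the LOD that censoring is negligible. Lagged driver values
before the record start are padded with the first value; a driver constant
over a short block (e.g. tide state within the 31-minute sprint) is
absorbed into the intercept. The sprint block reuses the generator at
1-minute resolution with the innovation sd halved, reflecting the smaller
sample-to-sample variation seen at 1-minute spacing.

What the generator does *not* emulate: the discrete MPN ladder of
defined-substrate assays (concentrations stay continuous), intermittent
point-source loading events, advective plumes, or any mechanistic
hydrodynamics. Passing tests on synthetic data therefore demonstrate that
the statistical machinery is correct under the model's own assumptions —
not that the model is right for any particular beach.

## Numerical choices and testing conditions

* Ties in best-lag selection break toward the smaller lag; ties in VIF
  removal break toward the earlier column.
* Exact fits (zero residual variance) short-circuit AR estimation, which
  would otherwise be degenerate.
* Constant design columns are dropped with a warning at z-scoring;
  rank-deficient concentration designs fail with the offending columns
  named.
* All stochastic fits take an explicit integer seed and are
  bit-reproducible given it.
* Parameter-recovery checks run at n = 500 with $|\beta| \ge 0.3$, AR(2)
  errors $\varphi = (0.5, 0.2)$, and an intercept high enough that
  censoring is negligible. Fitting the concentration part on detected
  samples only is conditioning on the response exceeding the LOD; with
  appreciable censoring this truncation attenuates slopes (about 10% at
  ~6% censoring in our simulations), which is a property of the
  conditional-on-detection design shared with any hurdle analysis, not an
  estimator defect. The recovery check therefore isolates the estimator;
  the attenuation is worth remembering when interpreting fitted
  coefficients on heavily censored records.
* The downsampling-trend and hurdle-behavior checks use 100 and 20
  simulated events respectively at the study's own size (N = 96), sizes at
  which the whole suite completes in well under a minute on one core.

## Limitations

* Single-event scope: nothing here pools events or models seasonality.
* The AR error model treats detected samples as contiguous in time even
  when censored samples interrupt the series — the same simplification the
  two-part design implies.
* In-sample metrics overstate predictive skill by construction; the
  random-forest part in particular fits 96 samples essentially perfectly.
* Best-lag selection reuses the data that the model is then fit on; the
  selected lags inherit screening noise.
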