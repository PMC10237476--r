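# fibpulse

Analysis of high-frequency (sub-hourly) fecal indicator bacteria (FIB)
time series at recreational beaches, and of the environmental drivers of
their variability.

## The problem

Beach water quality is managed on FIB — total coliforms (TC), *E. coli*
(EC) and *Enterococcus* (ENT), measured in MPN/100 mL — but routine
monitoring is weekly or sparser while concentrations can swing by orders
of magnitude within hours. A *high-frequency sampling event* (e.g. 48
hours at 30-minute intervals, N = 96, optionally with a nested 1-minute
"sprint" block) characterizes that short-term variability directly and
supplies the data for driver analysis. fibpulse implements the full
chain for such an event:

* **Censoring-aware preprocessing** — left-censored values (below the
  assay lower limit of detection, 10 MPN/100 mL) substituted with 1,
  linear interpolation of missing covariates, alignment of external
  records (e.g. 6-minute tide gauges), and feature engineering
  (log transforms, tide state, alongshore/offshore wind from the
  beach-normal angle, cloud dummies, diel clock features).
* **Variability statistics** — coefficient of variation; the normalized
  adjacent-sample difference
  `δ_i(t) = |c(t+i) − c(t)| / μ`
  (with `μ` the whole-series mean concentration); a downsampling analysis
  of `δ_i` over intervals from 30 minutes to 24 hours across every
  resampling start offset; counts of detection- and exceedance-status
  changes between adjacent samples; partial autocorrelation with a
  `±1.96/√n` band.
* **Association screening** — tie-corrected Spearman correlations of
  log10 FIB against environmental variables lagged 0–180 minutes,
  best-lag selection per variable, Kruskal–Wallis comparisons across
  day/night, tide and cloud groupings.
* **A two-part hurdle model** per indicator —
  a random-forest binary part (100 trees, `⌊√p⌋` variables per split)
  classifying detection above the LOD, pruned by permutation feature
  importance (mean accuracy drop over 5 shuffles); and a
  generalized-least-squares concentration part with AR(2) errors fit by
  iterative quasi-differencing, pruned until every variance inflation
  factor is below 5. Overall prediction is the product of the two parts;
  an indicator never measured below the LOD gets the regression part
  alone.
* **A synthetic-data generator** with stored ground truth — tidal
  (12.42 h / 23.93 h) and diel covariate structure, AR(1) covariate
  noise, a Markov cloud chain, and FIB from a lagged log-linear model
  with AR(2) log-scale noise left-censored at the LOD — so the entire
  pipeline is testable without field data.

## Worked example

```r
library(fibpulse)

g   <- generate_event(seed = 42)          # 48 h, 30-min synthetic event
rep <- run_event_analysis(g$event, seed = 42)

rep$summary[, c("indicator", "n", "exceedances", "below_lod",
                "mean", "cv", "mean_delta", "max_delta")]
#>   indicator  n exceedances below_lod mean   cv mean_delta max_delta
#> 1        tc 96           1         0  766 2.38      0.896     19.43
#> 2        ec 96           7        14  118 1.47      0.646      5.78
#> 3       ent 96          28        28  207 3.11      0.944     12.85

print(rep$models$ent)
#> <hurdle_model> ENT: 24 below LOD of 91 samples
#>   binary part: 8 variables retained, in-sample accuracy 1
#>   concentration part: 12 variables (VIF-pruned: cloud_partly, rad, tide,
#>     temp, wtemp, hours_from_noon, pres)
#>   conc R2 0.412 RMSE 0.484 DW 1.98 | overall R2 0.828 RMSE 0.416
```

Reading the output: ENT is censored in 28 of 96 samples and exceeds its
single-sample threshold (104 MPN/100 mL) in 28; a mean `δ_30m` of 0.94
says consecutive samples differ on average by nearly the whole-record
mean concentration. In the hurdle model (fit on the 91 rows remaining
after lag alignment, 24 of them censored), the forest separates detects
from non-detects perfectly in-sample, seven collinear variables are
removed by VIF pruning, the AR(2) concentration model leaves a
Durbin–Watson statistic of ~2 (serial correlation absorbed), and the
overall hurdle R² (0.83) exceeds the concentration part's (0.41) because
correctly classified non-detects are predicted exactly.

`variability_report()`, `association_report()`, `build_lagged_design()`
and `fit_hurdle()` expose the stages individually;
`run_event_analysis(..., out_dir = "out")` writes the processed CSV and
JSON reports for every stage. The methods vignette
(`vignettes/fibpulse-methods.Rmd`) documents the statistical conventions
and the generator's assumptions.

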