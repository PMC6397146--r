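# seasdhr

Time-varying seasonal analysis of irregularly sampled stream-monitoring
series, with companion tools for diatom-based water-quality metrics,
antecedent sensor-window aggregation, species ordination, and synthetic
data generation.

## The problem

Benthic diatom assemblages are the workhorse biological indicator of river
ecological status: valve counts are condensed into an abundance-weighted
sensitivity index, expressed relative to a reference expectation as an
Ecological Quality Ratio (EQR), and banded into high / good / moderate /
poor / bad classes. Monthly sampling shows that EQR in small streams cycles
strongly and recurrently with season — the same reach can band "high" in
summer and "poor" in winter — so the timing of a survey can change its
regulatory verdict. Detecting and quantifying that cycle needs a seasonal
model whose amplitude and phase can drift over the years, estimated on
irregularly spaced samples.

## The model

`seasdhr`'s core is dynamic harmonic regression in state-space form. The
series decomposes as

```
y_t = T_t + S_t + e_t,    S_t = Σ_{i=1..Rs} a_{i,t} cos(ω_i t) + b_{i,t} sin(ω_i t)
```

with ω_i = 2πi/p (fundamental period p = 1 year by default). The trend T_t
(integrated random walk) and the harmonic coefficients a_{i,t}, b_{i,t}
(random walks) are stochastic time-varying parameters whose rates of change
are governed by noise variance ratios (NVRs), estimated by maximum
likelihood. Estimation uses Kalman filtering and fixed-interval smoothing
in continuous time — process variance accumulates with the actual gap
between samples — so jittered, gappy field campaigns are handled exactly.
The initial state is fully diffuse and handled exactly by regression
augmentation, so with NVRs of zero the fit reproduces ordinary harmonic
regression to machine precision. The fit reports R², an ANOVA-style F test
whose model degrees of freedom are the trace of the smoother's influence
map, and pointwise 95% confidence bands for the fit and for the seasonal
component.

Around the core: valve-count matrices → weighted-average index → EQR →
status banding (boundaries 0.8/0.6/0.4/0.2, ties upward); 15-minute sensor
records → half-open 21-day antecedent-window means with coverage
accounting; covariance PCA of the log species matrix with passive
environmental arrows; and seeded generators for EQR series, 300-valve
seasonal assemblages and event-driven sensor records, each paired with its
ground truth.

## Worked example

```r
library(seasdhr)

g <- gen_eqr_series(seed = 1)   # 5.5 yr of jittered mid-monthly EQR + truth
fit <- asdhr(g$series)          # annual period, 2 harmonics, ML-estimated NVRs
fit
#> Arbitrary-sampled dynamic harmonic regression
#>   2 harmonic(s), fundamental period 1 yr; trend: irw
#>   n = 66, R-squared = 0.9401, F(24.54, 40.46) = 25.873, p = 1.17e-17
#>   NVR: trend = 3.309e-07, seasonal = 1.097 ; sigma2_e = 0.002639
```

The fit explains 94% of the variance; the near-zero trend NVR says the
level is effectively constant (the generator's trend slope is zero), while
the seasonal NVR of about 1.1 reflects the drifting annual amplitude the
generator injected (drift variance / noise variance ≈ 0.9 here). The F test
at the effective degrees of freedom rejects "no structure" at p ≈ 1e-17.
`plot(fit)` shows the data, the smoothed fit with its 95% band and the
seasonal component; `predict(fit, times = ...)` interpolates between
samples through the same continuous-time transition law.

The diatom chain, from counts to a status series ready for `asdhr()`:

```r
dates <- gen_sample_dates(2, seed = 1)              # 24 mid-monthly dates
cm    <- gen_counts(dates, seed = 1)$counts         # 300 valves per sample
eq    <- eqr_series(cm, expected_index = 25)
head(eq$table, 4)
#>         date      wms coverage    index       eqr capped status
#> 1 2011-03-14 2.755513        1 43.88783 0.7481622  FALSE   good
#> 2 2011-04-19 2.353271        1 33.83178 0.8822430  FALSE   high
#> 3 2011-05-13 1.962451        1 24.06126 1.0125165  FALSE   high
#> 4 2011-06-10 1.709266        1 17.73166 1.0969112  FALSE   high
table(eq$table$status)
#>      bad     poor moderate     good     high
#>        0        0        1        9       14
```

Spring/summer samples (dominated by the clean-water pioneer in the summer
pool) band high; winter samples slide toward moderate — the seasonal class
cycling the decomposition then quantifies. `run_pipeline(pipeline_config(seed = 1), "run1")`
chains every stage (simulate → EQR → decomposition → antecedent windows →
ordination) into an output directory with CSVs, JSON summaries and a
provenance log.

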