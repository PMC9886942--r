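# vegresilience

Estimation of vegetation resilience from deseasonalized index time series,
and of how that resilience depends on water availability and variability.

Ecosystems under stress recover more slowly from shocks ("critical slowing
down"). For a vegetation anomaly \(\bar{x}\) linearized around a stable
state,

    dx̄ = λ x̄ dt + σ dW,      λ < 0,

the restoring rate λ (1/yr) *is* the resilience: the closer λ is to zero,
the slower the recovery, and the larger both the variance
⟨x̄²⟩ = −σ²/(2λ) and the lag-one autocorrelation AC1 = e^{λΔt} of the
sampled anomaly. The package estimates λ per pixel three ways —

* inverting AC1: λ̂ = log(AC1)/Δt,
* inverting the variance via the AR(1) innovation identity,
* fitting x(t) = x₀·e^{rt} to the relaxation after detected abrupt drops
  (percentile slope detection → drop + Kolmogorov–Smirnov validation →
  R²-screened exponential fit),

computes the water covariates the relationships are drawn against
(PET/MAP aridity, Walsh–Lawler seasonality index, MAP-normalized
inter-annual precipitation variability), and summarizes each
resilience–water relationship per land-cover class as binned medians with
tie-aware Kendall-τ and a 1000-draw Monte-Carlo surrogate significance
check. A synthetic-landscape generator with full ground truth (known λ,
injected recoveries, prescribed climate gradients) backs every step with
testable expectations. Intended for method development and teaching in
ecological time-series analysis; it is written against bi-weekly
(24/yr) series such as resampled NDVI or VOD records.

## Worked example

Estimate resilience for one simulated pixel (λ = −2/yr, σ = 0.1,
bi-weekly sampling, 30 years):

```r
library(vegresilience)

x <- sim_ou_residual(lambda = -2, sigma = 0.1, dt = 1/24,
                     n_steps = 720, seed = 1)
resilience_estimate(as.numeric(x), dt = 1/24)
#>     ac1 variance noise_var lambda_ac1 lambda_var n_eff flag
#> 1 0.903  0.00218  0.000402      -2.45      -2.22   720 <NA>
```

Both theory-based estimates land near the true −2/yr: the sample AC1
(0.903) inverts to −2.45/yr and the variance route gives −2.22/yr; the
gap between them is ordinary estimator noise at this series length.

Detect and fit an injected abrupt drop (amplitude −0.4, recovering at the
true λ) after seasonal-trend removal:

```r
ser <- sim_vegetation_series(-2, 0.1, 1/24, 720, seasonal_amplitude = 0.2,
         perturbations = data.frame(time_index = 300, amplitude = -0.4,
                                    recovery_rate = -2),
         seed = 6)
resid <- stl_residual(ser$values)
ev <- recovery_events(as.numeric(resid))
ev[ev$accepted, c("peak_index", "slope_at_peak", "ks_p", "x0", "r", "r2")]
#>   peak_index slope_at_peak     ks_p     x0     r    r2
#> 1        298        -0.545 1.21e-08 -0.424 -2.78 0.835
```

The injected drop at sample 300 is found at sample 298, passes the KS
state-shift screen (p ≈ 10⁻⁸), and fits an exponential recovery with
r = −2.78/yr and R² = 0.84. Single-event estimates scatter around the
injected rate; ensemble medians over many events recover it to within a
few percent (see below).

The full pipeline — simulate a 4500-pixel landscape, preprocess, estimate
resilience, fit recoveries, compute climate metrics, and relate them per
land cover — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 42))
subset(res$relationships, !omitted & predictor == "aridity" &
       metric == "lambda_ac1", select = c(landcover, tau, p, sign_fraction))
#>    landcover   tau        p sign_fraction
#> 1     forest 0.780 1.92e-05         0.894
#> 2  grassland 0.962 1.82e-10         0.999
#> 3    savanna 0.912 5.18e-08         0.987
```

The landscape is constructed with resilience decreasing toward drier,
more variable climates, and the pipeline recovers exactly that: strongly
positive Kendall-τ (λ rises toward zero with aridity) at p ≪ 0.05 in
every reportable class. A shell entry point over the same pipeline lives
at `inst/scripts/run_pipeline.R`.

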