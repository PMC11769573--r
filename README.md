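# rapsignal

Derivation and characterization of the **RAP compensatory reserve index**
from intracranial pressure (ICP) and arterial blood pressure (ABP)
recordings, for researchers working with multimodal neuromonitoring data
in traumatic brain injury and related conditions.

RAP is the moving Pearson correlation (R) between the pulse amplitude of
ICP (A, "AMP") and mean ICP (P), computed over 30 consecutive 10-second
means (a 5-minute window) and updated every minute. Near-zero RAP
indicates intact compensatory reserve, RAP > 0.4 impaired reserve, and
negative RAP exhausted reserve. The companion index PRx applies the same
moving correlation to (ICP, MAP) as a proxy for cerebrovascular
reactivity.

The package covers four layers:

1. **Derivation** — 10-s decimation, spectral AMP extraction
   (fundamental cardiac harmonic per 10-s block), RAP/PRx moving
   correlations, CPP, physiologic validity filtering, and resampling to
   10/30/60-minute resolutions.
2. **Description** — summary statistics, time-in-state percentages over
   the RAP ranges [0.4, 1], (0, 0.4), [−1, 0], and subgroup comparisons
   (Mann–Whitney U for two groups, one-way ANOVA for more).
3. **Time-series structure** — ADF/KPSS stationarity testing, first
   differencing, an exhaustive ARIMA(p, 1, q) order search over
   p, q ∈ 0..10 under AIC (`X_t = c + e_t + Σ φ_i X_{t−i} + Σ θ_j e_{t−j}`),
   population median optimal models, and residual ACF/PACF diagnostics
   across temporal resolutions.
4. **Artifact detection** — clean/non-clean timestamp alignment and
   three sliding-window detectors built on the ARIMA structure (order
   deviation, residual variance, residual cross-correlation), evaluated
   as (captured artifacts / true artifacts) × 100 with explicit
   false-positive accounting.

Because bedside archives are not shareable, a first-class synthetic
module generates pulsatile ICP/ABP with a tunable coupling between slow
ICP and pulse amplitude (the dial that sets the RAP regime), ARMA series
of known order, labeled artifacts of five kinds, and whole cohorts with
clinical covariates — so every stage is testable with known ground truth.

## Worked example

```r
library(rapsignal)

# two hours of coupled pulsatile ICP/ABP at 100 Hz (impaired regime)
rec <- simulate_pulsatile(waveform_params(duration = 7200,
                                          coupling = 0.75, seed = 42))
idx <- derive_indices(rec)

summarize_series(idx$RAP)
#> n=116 mean=0.8993 sd=0.1418 min=0.2775 q25=0.8982 median=0.9566 q75=0.985 max=0.9981

round(time_in_ranges(idx$RAP), 1)
#>  impaired    intact exhausted
#>      98.3       1.7       0.0

g <- grid_search(idx$RAP, d = 1)
g
#> <arima_grid> optimal ARIMA(4,1,2) by AIC over 121 cells (121 converged)

d  <- arima_diagnostics(idx$RAP, g$spec)
d0 <- arima_diagnostics(idx$RAP, arima_spec(0, 0, 0))
#> median |residual|: baseline 0.0787 -> optimal 0.0139
```

With strong coupling the derived RAP sits deep in the impaired range
(mean 0.90, 98% of minutes at or above 0.4), as it should by
construction. The series carries real autoregressive structure — the
order search lands on ARIMA(4,1,2), and fitting it cuts the median
absolute residual to a fifth of the no-model baseline, which is the
adequacy pattern the structure analysis looks for on longer recordings
as well.

For artifact work, `make_detection_benchmark()` builds a long recording
with ~5% labeled artifacts, and `run_detection_suite()` scores all three
detectors against the ground truth at minute and 10-minute resolution.

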