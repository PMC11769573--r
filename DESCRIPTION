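Package: rapsignal
Title: Compensatory Reserve (RAP) Signal Derivation, Time-Series
    Structure, and Artifact Detection for Intracranial Pressure Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and characterizing the RAP compensatory
    reserve index from intracranial pressure (ICP) and arterial blood
    pressure (ABP) recordings. Implements the standard bedside derivation
    chain (10-second decimation, pulse-amplitude extraction via the
    fundamental cardiac harmonic, moving Pearson correlation for RAP and
    PRx, validity filtering, multi-resolution resampling), summary and
    subgroup statistics with RAP state classification, ARIMA order
    selection by exhaustive information-criterion grid search with
    stationarity testing (ADF/KPSS) and residual diagnostics across
    temporal resolutions, and sliding-window artifact detectors based on
    ARIMA order deviation, residual variance, and residual
    cross-correlation. A synthetic-signal module generates pulsatile
    pressure waveforms with tunable coupling between slow intracranial
    pressure and pulse amplitude, ARMA series of known order, labeled
    artifacts, and cohorts with clinical covariates, so that every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
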