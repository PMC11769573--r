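#' Parameters for the pulsatile pressure waveform generator
#'
#' Defines the acquisition regime that [simulate_pulsatile()] emulates:
#' high-frequency (>= 50 Hz) pulsatile ICP and ABP with a cardiac pulse, a
#' respiratory component, a slow random-walk drift, and broadband noise.
#' `coupling` controls the strength and sign of the relationship between the
#' slow ICP trend and the ICP pulse amplitude; positive coupling makes slow
#' ICP and pulse amplitude co-move (the high-RAP, impaired-reserve regime)
#' while zero decouples them (the low-RAP, intact-reserve regime).
#'
#' @param duration Recording length in seconds.
#' @param sample_rate Sampling frequency in Hz (>= 50).
#' @param heart_rate Cardiac frequency in beats/min, within \[40, 180\].
#' @param resp_rate Respiratory frequency in breaths/min.
#' @param icp_baseline,abp_baseline Mean pressure levels in mmHg.
#' @param pulse_amplitude Amplitude of the fundamental cardiac harmonic of
#'   ICP in mmHg (the quantity that AMP extraction recovers).
#' @param pulse_jitter_sd SD of the multiplicative beat-to-beat pulse
#'   amplitude variability (fraction of `pulse_amplitude`, drawn per 10-s
#'   knot). This variability is independent of the slow ICP trend, so it
#'   is what makes `coupling` a graded dial: with no jitter any non-zero
#'   coupling saturates the derived RAP near 1.
#' @param resp_amplitude Amplitude of the respiratory modulation in mmHg.
#' @param coupling Unitless in \[-1, 1\]; strength/sign of the
#'   slow-ICP-to-pulse-amplitude relationship.
#' @param trend_sd Step SD in mmHg of the slow drift (one innovation per
#'   10-s knot; the drift is mean-reverting with a time constant of a few
#'   hours, so its stationary spread is about 22 times the step SD).
#' @param noise_sd SD in mmHg of additive white measurement noise.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A validated list of class `waveform_params`.
#' @seealso [simulate_pulsatile()]
#' @export
waveform_params <- function(duration = 7200, sample_rate = 100,
                            heart_rate = 72, resp_rate = 16,
                            icp_baseline = 15, abp_baseline = 90,
                            pulse_amplitude = 2, pulse_jitter_sd = 0.1,
                            resp_amplitude = 0.5,
                            coupling = 0.6, trend_sd = 0.4,
                            noise_sd = 0.3, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be a positive number of seconds")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be a positive frequency in Hz")
  if (sample_rate < 50)
    stop("pulsatile output requires sample_rate >= 50 Hz")
  if (heart_rate < 40 || heart_rate > 180)
    stop("'heart_rate' must lie in [40, 180] beats/min")
  if (abs(coupling) > 1) stop("'coupling' must lie in [-1, 1]")
  if (trend_sd < 0 || noise_sd < 0 || pulse_jitter_sd < 0)
    stop("SD parameters must be >= 0")
  structure(list(duration = duration, sample_rate = sample_rate,
                 heart_rate = heart_rate, resp_rate = resp_rate,
                 icp_baseline = icp_baseline, abp_baseline = abp_baseline,
                 pulse_amplitude = pulse_amplitude,
                 pulse_jitter_sd = pulse_jitter_sd,
                 resp_amplitude = resp_amplitude, coupling = coupling,
                 trend_sd = trend_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "waveform_params")
}

#' Simulate a pulsatile ICP/ABP recording with tunable compliance coupling
#'
#' Generates synchronous ICP and ABP channels. The cardiac pulse is the
#' fundamental harmonic plus a small fixed second harmonic; pulse-waveform
#' sub-peak morphology is deliberately not modelled because downstream AMP
#' extraction is spectral (fundamental harmonic only). The instantaneous ICP
#' pulse amplitude is `pulse_amplitude * (1 + coupling * z(t))`, where
#' `z(t)` is the standardized slow ICP trend (a random walk on 10-s knots,
#' linearly interpolated), floored at 5% of `pulse_amplitude` so the
#' amplitude stays positive. Under positive coupling, slow ICP and pulse
#' amplitude therefore co-move and the derived RAP is high; under zero
#' coupling they are independent and RAP fluctuates around zero.
#'
#' @param params A [waveform_params()] object.
#' @return A [physio_recording()] with channels `ICP` and `ABP`.
#' @examples
#' rec <- simulate_pulsatile(waveform_params(duration = 60, seed = 7))
#' rec
#' @export
simulate_pulsatile <- function(params) {
  if (!inherits(params, "waveform_params"))
    params <- do.call(waveform_params, as.list(params))
  fs <- params$sample_rate
  n <- floor(params$duration * fs)
  if (n < 1) stop("'duration' too short for one sample")
  t <- (seq_len(n) - 1) / fs

  with_seed(params$seed, {
    # slow mean-reverting drifts on 10-s knots (AR(1), time constant a
    # few hours), linearly interpolated to the full rate; locally they
    # wander like a random walk with the given step SD, but over days
    # they stay near the patient's level instead of drifting out of the
    # physiologic range
    n_knots <- ceiling(params$duration / 10) + 1
    knot_t <- (seq_len(n_knots) - 1) * 10
    icp_trend_k <- as.numeric(stats::filter(
      stats::rnorm(n_knots, 0, params$trend_sd), 0.999,
      method = "recursive"))
    abp_trend_k <- as.numeric(stats::filter(
      stats::rnorm(n_knots, 0, 2 * params$trend_sd), 0.999,
      method = "recursive"))
    icp_trend <- stats::approx(knot_t, icp_trend_k, xout = t, rule = 2)$y
    abp_trend <- stats::approx(knot_t, abp_trend_k, xout = t, rule = 2)$y

    z <- if (stats::sd(icp_trend) > 0)
      (icp_trend - mean(icp_trend)) / stats::sd(icp_trend) else rep(0, n)
    # Beat-to-beat amplitude variability with slowly drifting volatility:
    # the jitter decouples AMP from the slow trend (making `coupling` a
    # graded dial), while its AR(1) log-volatility (time constant on the
    # order of an hour, log-SD 1) creates prolonged epochs of stronger
    # and weaker effective coupling. These epochs are what give derived
    # RAP its documented character: persistent autoregressive structure
    # at the minute scale, wide excursions across the reserve states
    # over a recording, and hour-scale changes larger than the
    # minute-scale innovations.
    eta <- as.numeric(stats::filter(
      stats::rnorm(n_knots, 0, 1.2 * sqrt(1 - 0.9972^2)), 0.9972,
      method = "recursive"))
    sigma_j <- params$pulse_jitter_sd * exp(eta - 0.72)
    jit_k <- stats::rnorm(n_knots, 0, 1) * sigma_j
    jit <- stats::approx(knot_t, jit_k, xout = t, rule = 2)$y
    # softplus keeps the amplitude positive without the flat-pinning a
    # hard floor causes (pinned stretches destroy the trend-amplitude
    # correlation precisely when coupling is strong); in the normal
    # regime it is the linear law pulse_amplitude * (1 + coupling * z)
    u <- 1 + params$coupling * z + jit
    amp_t <- params$pulse_amplitude * 0.25 * log1p(exp(pmin(u, 30) / 0.25))

    cardiac <- 2 * pi * params$heart_rate / 60 * t
    resp <- 2 * pi * params$resp_rate / 60 * t
    pulse_shape <- sin(cardiac) + 0.25 * sin(2 * cardiac)

    icp <- params$icp_baseline + icp_trend + amp_t * pulse_shape +
      params$resp_amplitude * sin(resp) +
      stats::rnorm(n, 0, params$noise_sd)
    abp <- params$abp_baseline + abp_trend + 20 * pulse_shape +
      3 * params$resp_amplitude * sin(resp + pi / 3) +
      stats::rnorm(n, 0, params$noise_sd)

    physio_recording(time = t, channels = list(ICP = icp, ABP = abp),
                     sample_rate = fs)
  })
}

#' Simulate an ARMA/ARIMA series of known order
#'
#' Draws from the Gaussian ARMA recursion
#' `X_t = c + e_t + sum(phi_i X_(t-i)) + sum(theta_j e_(t-j))`.
#' With `d = 1` in `spec` the cumulative sum of the ARMA draw is returned,
#' i.e. an integrated series whose first difference has the given orders.
#'
#' @param spec An [arima_spec()] (only `p` and `q` consistent with the
#'   coefficient lengths; `d` of 1 integrates the draw).
#' @param ar,ma Numeric coefficient vectors (`phi`, `theta`); may be empty.
#'   The AR polynomial must be stationary and the MA polynomial invertible.
#' @param n Number of samples.
#' @param innovation_sd SD of the Gaussian innovations.
#' @param mean Constant level added to the stationary ARMA component.
#' @param seed Integer seed.
#' @param resolution Resolution label for the returned series.
#' @param name Signal name for the returned series.
#' @return An [index_series()].
#' @examples
#' s <- simulate_arma(arima_spec(1, 0, 0), ar = 0.8, n = 500, seed = 1)
#' @export
simulate_arma <- function(spec, ar = numeric(0), ma = numeric(0), n,
                          innovation_sd = 1, mean = 0, seed = 1L,
                          resolution = "1min", name = "SYN") {
  if (!inherits(spec, "arima_spec")) spec <- do.call(arima_spec, as.list(spec))
  if (length(ar) != spec$p || length(ma) != spec$q)
    stop("coefficient lengths must match the orders in 'spec'")
  if (n < 1) stop("'n' must be >= 1")
  if (spec$p > 0 && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop("AR polynomial is not stationary (root on or inside unit circle)")
  if (spec$q > 0 && any(Mod(polyroot(c(1, ma))) <= 1))
    stop("MA polynomial is not invertible (root on or inside unit circle)")
  x <- with_seed(seed, {
    model <- list()
    if (spec$p > 0) model$ar <- ar
    if (spec$q > 0) model$ma <- ma
    as.numeric(stats::arima.sim(model, n = n, sd = innovation_sd)) + mean
  })
  if (spec$d == 1) x <- cumsum(x)
  step <- resolution_seconds(resolution)
  index_series(name = name, time = seq_len(n) * step, values = x,
               resolution = resolution)
}

#' Specification of synthetic artifact injection
#'
#' The artifact taxonomy covers the failure modes seen in bedside pressure
#' monitoring: transducer hits (`spike`), frozen output (`flatline`),
#' zeroing/repositioning offsets (`step`), electrical interference
#' (`noise_burst`), and disconnections (`dropout`). The kinds jointly
#' stress the three detector families (order change, variance change, and
#' decorrelation from the parent signals).
#'
#' @param kinds Subset of `c("spike", "flatline", "step", "noise_burst",
#'   "dropout")`.
#' @param rate Events per hour (>= 0); the default, with the default
#'   durations, corrupts roughly 5% of samples.
#' @param duration_range Two ordered positive numbers: event duration
#'   bounds in seconds.
#' @param magnitude_range Two ordered numbers: event magnitude bounds in
#'   multiples of the clean channel SD.
#' @param seed Integer seed.
#' @return A validated list of class `artifact_spec`.
#' @export
artifact_spec <- function(kinds = c("spike", "flatline", "step",
                                    "noise_burst", "dropout"),
                          rate = 5, duration_range = c(10, 60),
                          magnitude_range = c(5, 10), seed = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (rate < 0) stop("'rate' must be >= 0")
  if (length(duration_range) != 2 || any(duration_range <= 0) ||
      duration_range[1] > duration_range[2])
    stop("'duration_range' must be two ordered positive numbers")
  if (length(magnitude_range) != 2 || magnitude_range[1] > magnitude_range[2])
    stop("'magnitude_range' must be ordered")
  structure(list(kinds = kinds, rate = rate,
                 duration_range = duration_range,
                 magnitude_range = magnitude_range, seed = as.integer(seed)),
            class = "artifact_spec")
}

# Corrupt a numeric vector in place according to drawn events; returns the
# corrupted values and the logical mask. Internal workhorse shared by the
# recording- and series-level interfaces.
inject_into_values <- function(x, step_seconds, spec, baseline = 0) {
  n <- length(x)
  mask <- rep(FALSE, n)
  total_hours <- n * step_seconds / 3600
  n_events <- stats::rpois(1, spec$rate * total_hours)
  if (n_events == 0) return(list(values = x, mask = mask))
  sd_x <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sd_x) || sd_x == 0) sd_x <- 1
  for (ev in seq_len(n_events)) {
    kind <- sample(spec$kinds, 1)
    dur_s <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
    len <- max(1L, round(dur_s / step_seconds))
    start <- sample.int(max(1L, n - len + 1L), 1)
    idx <- start:min(n, start + len - 1L)
    mag <- stats::runif(1, spec$magnitude_range[1], spec$magnitude_range[2]) * sd_x
    x[idx] <- switch(kind,
      spike = x[idx] + mag * sin(pi * seq_along(idx) / (length(idx) + 1)),
      flatline = x[idx[1]],
      step = x[idx] + mag,
      noise_burst = x[idx] + stats::rnorm(length(idx), 0, mag),
      dropout = baseline)
    mask[idx] <- TRUE
  }
  list(values = x, mask = mask)
}

#' Inject labeled artifacts into a recording or index series
#'
#' Returns a corrupted copy of the input together with a ground-truth
#' [artifact_mask()] marking every modified sample. Samples outside events
#' are bit-identical to the input; a zero-rate specification returns the
#' input unchanged with an all-false mask. Event placement, kind, duration
#' and magnitude are deterministic given the specification seed.
#'
#' For a [physio_recording()], the same event windows corrupt every channel
#' (a sensor-level event affects all derived quantities); for an
#' [index_series()], the single value stream is corrupted.
#'
#' @param x A [physio_recording()] or [index_series()].
#' @param spec An [artifact_spec()].
#' @return A list with elements `recording` (or `series`) and `mask`.
#' @export
inject_artifacts <- function(x, spec) UseMethod("inject_artifacts")

#' @rdname inject_artifacts
#' @export
inject_artifacts.physio_recording <- function(x, spec) {
  if (length(x$time) == 0) stop("recording is empty")
  step <- if (identical(x$sample_rate, "irregular"))
    stats::median(diff(x$time)) else 1 / x$sample_rate
  with_seed(spec$seed, {
    mask <- rep(FALSE, length(x$time))
    out <- x
    # one event stream drawn once, applied to all channels over the same
    # windows: replay by drawing events on the first channel, then applying
    # identical windows to the rest
    first <- names(x$channels)[1]
    res <- inject_into_values(x$channels[[first]], step, spec,
                              baseline = 0)
    out$channels[[first]] <- res$values
    mask <- res$mask
    if (length(x$channels) > 1) {
      runs <- true_runs(mask)
      for (nm in names(x$channels)[-1]) {
        v <- x$channels[[nm]]
        sd_v <- stats::sd(v, na.rm = TRUE); if (!is.finite(sd_v) || sd_v == 0) sd_v <- 1
        if (nrow(runs) > 0) for (r in seq_len(nrow(runs))) {
          idx <- runs[r, 1]:runs[r, 2]
          kind <- sample(spec$kinds, 1)
          mag <- stats::runif(1, spec$magnitude_range[1],
                              spec$magnitude_range[2]) * sd_v
          v[idx] <- switch(kind,
            spike = v[idx] + mag * sin(pi * seq_along(idx) / (length(idx) + 1)),
            flatline = v[idx[1]],
            step = v[idx] + mag,
            noise_burst = v[idx] + stats::rnorm(length(idx), 0, mag),
            dropout = 0)
        }
        out$channels[[nm]] <- v
      }
    }
    list(recording = out,
         mask = artifact_mask(x$time, mask, "ground_truth"))
  })
}

#' @rdname inject_artifacts
#' @export
inject_artifacts.index_series <- function(x, spec) {
  if (length(x$values) == 0) stop("series is empty")
  step <- resolution_seconds(x$resolution)
  with_seed(spec$seed, {
    res <- inject_into_values(x$values, step, spec,
                              baseline = mean(x$values, na.rm = TRUE))
    out <- x
    out$values <- res$values
    list(series = out, mask = artifact_mask(x$time, res$mask, "ground_truth"))
  })
}

# Default covariate sampler for synthetic cohorts. Distributions mirror a
# moderate/severe TBI monitoring population: median age in the 40s with wide
# spread, ~80% male, pupillary response mostly bilaterally reactive, and
# Marshall CT grades dominated by high grades. The waveform coupling is tied
# to Marshall grade (rising II -> IV, dipping at V, post-surgical) so that
# group-level RAP ordering is a construction property of the cohort.
default_covariate_sampler <- function() {
  list(
    age = function(n) round(pmin(pmax(stats::rnorm(n, 43, 18), 16), 89)),
    sex = function(n) sample(c("M", "F"), n, replace = TRUE,
                             prob = c(0.82, 0.18)),
    pupils = function(n) sample(
      c("bilateral_reactive", "unilateral_reactive", "bilateral_unreactive"),
      n, replace = TRUE, prob = c(0.60, 0.23, 0.17)),
    marshall = function(n) sample(c("II", "III", "IV", "V"), n,
                                  replace = TRUE,
                                  prob = c(0.03, 0.28, 0.18, 0.51)),
    gose = function(n) sample(1:8, n, replace = TRUE,
                              prob = c(0.25, 0.05, 0.15, 0.15,
                                       0.15, 0.10, 0.10, 0.05)),
    coupling_by_marshall = c(II = 0.2, III = 0.45, IV = 0.7, V = 0.55)
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient covariates (age, sex, pupillary response, Marshall CT
#' grade, 1- and 6-month GOSE), simulates one pulsatile recording per
#' patient with coupling tied to Marshall grade, and optionally injects
#' labeled artifacts. Per-patient seeds are derived deterministically from
#' the master seed, so the whole cohort is a pure function of `seed`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param waveform_params_sampler Optional `function(i, covariates)`
#'   returning the [waveform_params()] for patient `i`; the default ties
#'   coupling to Marshall grade and uses 30-minute recordings.
#' @param artifacts An [artifact_spec()] or `NULL` for clean recordings.
#' @param seed Master integer seed.
#' @param covariate_sampler Optional list of sampling functions overriding
#'   the documented defaults.
#' @return A list of class `synthetic_cohort`; element `patients` is a list
#'   with `id`, `recording`, `covariates`, and `mask` per patient.
#' @export
make_cohort <- function(n_patients, waveform_params_sampler = NULL,
                        artifacts = NULL, seed = 1L,
                        covariate_sampler = NULL) {
  if (n_patients < 1) stop("'n_patients' must be >= 1")
  cs <- default_covariate_sampler()
  if (!is.null(covariate_sampler)) cs[names(covariate_sampler)] <- covariate_sampler
  cov_df <- with_seed(seed, data.frame(
    id = sprintf("P%03d", seq_len(n_patients)),
    age = cs$age(n_patients),
    sex = cs$sex(n_patients),
    pupils = cs$pupils(n_patients),
    marshall_grade = cs$marshall(n_patients),
    gose_1m = cs$gose(n_patients),
    gose_6m = cs$gose(n_patients),
    stringsAsFactors = FALSE))
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sub_seed <- derive_subseed(seed, i)
    cov_i <- cov_df[i, ]
    params <- if (!is.null(waveform_params_sampler)) {
      waveform_params_sampler(i, cov_i)
    } else {
      base <- cs$coupling_by_marshall[[cov_i$marshall_grade]]
      cpl <- with_seed(sub_seed + 1L,
                       min(1, max(-1, base + stats::rnorm(1, 0, 0.05))))
      waveform_params(duration = 1800, sample_rate = 100,
                      coupling = cpl, seed = sub_seed)
    }
    rec <- simulate_pulsatile(params)
    mask <- artifact_mask(rec$time, rep(FALSE, length(rec$time)),
                          "ground_truth")
    if (!is.null(artifacts)) {
      sp <- artifacts
      sp$seed <- derive_subseed(sub_seed, 2L)
      inj <- inject_artifacts(rec, sp)
      rec <- inj$recording
      mask <- inj$mask
    }
    patients[[i]] <- list(id = cov_df$id[i], recording = rec,
                          covariates = cov_i, mask = mask)
  }
  structure(list(patients = patients, covariates = cov_df, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (seed %d)\n",
              length(x$patients), x$seed))
  invisible(x)
}

#' Default ARMA coefficient sets of known order
#'
#' Reference coefficient sets used by the order-recovery simulations. Both
#' were specified through their polynomial roots, all placed at moduli
#' 1.25-1.7 so that the AR and MA components are strong, well separated
#' (no near-cancelling root pairs), and hence identifiable from realistic
#' sample sizes.
#'
#' @param order `"arma22"` or `"arma33"`.
#' @return List with `ar`, `ma`, and `spec`.
#' @export
reference_arma_coefficients <- function(order = c("arma22", "arma33")) {
  order <- match.arg(order)
  switch(order,
    arma22 = list(ar = c(1.2, -0.6), ma = c(-0.5, 0.4),
                  spec = arima_spec(2, 0, 2)),
    arma33 = list(ar = c(0.5571, 0.1758, -0.4267),
                  ma = c(-0.0142, 0.1380, -0.2798),
                  spec = arima_spec(3, 0, 3)))
}
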