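test_that("pulsatile generator is deterministic and validates parameters", {
  p <- waveform_params(duration = 30, seed = 5)
  r1 <- simulate_pulsatile(p)
  r2 <- simulate_pulsatile(p)
  expect_identical(r1, r2)
  expect_length(r1$time, 30 * 100)
  expect_error(waveform_params(duration = -1), "duration")
  expect_error(waveform_params(sample_rate = 20), "50 Hz")
  expect_error(waveform_params(heart_rate = 200), "heart_rate")
  expect_error(waveform_params(coupling = 1.5), "coupling")
})

test_that("noiseless fixed-rate ICP is exactly periodic at 60/heart_rate", {
  p <- waveform_params(duration = 20, sample_rate = 100, heart_rate = 75,
                       trend_sd = 0, noise_sd = 0, pulse_jitter_sd = 0,
                       resp_amplitude = 0, seed = 1)
  rec <- simulate_pulsatile(p)
  period_samples <- 100 * 60 / 75  # 80 samples
  icp <- rec$channels$ICP
  shifted <- icp[seq_len(length(icp) - period_samples) + period_samples]
  expect_equal(icp[seq_along(shifted)], shifted, tolerance = 1e-12)
})

test_that("ARMA generator matches its theoretical autocorrelation", {
  # white noise: lag-1 sample ACF inside the 95% i.i.d. band
  w <- simulate_arma(arima_spec(0, 0, 0), n = 4000, seed = 2)
  r1 <- acf(w$values, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 1.96 / sqrt(4000))
  # AR(1) phi = 0.8: theoretical rho(1) = 0.8
  a <- simulate_arma(arima_spec(1, 0, 0), ar = 0.8, n = 10000, seed = 3)
  r1 <- acf(a$values, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.8, tolerance = 0.025)
  # d = 1 integrates: differencing recovers the ARMA part's scale
  i <- simulate_arma(arima_spec(0, 1, 0), n = 1000, innovation_sd = 2,
                     seed = 4)
  expect_equal(sd(diff(i$values)), 2, tolerance = 0.15)
})

test_that("ARMA generator rejects unusable inputs", {
  expect_error(simulate_arma(arima_spec(1, 0, 0), ar = 1.2, n = 100),
               "stationary")
  expect_error(simulate_arma(arima_spec(0, 0, 1), ma = -1.5, n = 100),
               "invertible")
  expect_error(simulate_arma(arima_spec(2, 0, 0), ar = 0.5, n = 100),
               "length")
})

test_that("artifact injection is conservative, labelled, and seeded", {
  s <- simulate_arma(arima_spec(1, 0, 0), ar = 0.5, n = 600, seed = 6)
  spec0 <- artifact_spec(rate = 0, seed = 1)
  out0 <- inject_artifacts(s, spec0)
  expect_identical(out0$series$values, s$values)
  expect_false(any(out0$mask$flags))

  spec <- artifact_spec(rate = 6, seed = 9)
  out <- inject_artifacts(s, spec)
  out2 <- inject_artifacts(s, spec)
  expect_identical(out$series$values, out2$series$values)
  # untouched samples bit-identical; mask marks exactly the modified region
  expect_identical(out$series$values[!out$mask$flags],
                   s$values[!out$mask$flags])
  expect_gt(sum(out$mask$flags), 0)
})

test_that("noise-burst artifacts inflate segment variance", {
  s <- simulate_arma(arima_spec(0, 0, 0), n = 2000, seed = 7)
  spec <- artifact_spec(kinds = "noise_burst", rate = 8,
                        magnitude_range = c(10, 10), seed = 3)
  out <- inject_artifacts(s, spec)
  expect_gt(var(out$series$values[out$mask$flags]),
            var(out$series$values[!out$mask$flags]))
})

test_that("cohorts are pure functions of the master seed", {
  short <- function(i, cov) waveform_params(duration = 60, seed = 1000 + i)
  c1 <- make_cohort(4, waveform_params_sampler = short, seed = 11)
  c2 <- make_cohort(4, waveform_params_sampler = short, seed = 11)
  expect_identical(c1, c2)
  expect_identical(anyDuplicated(c1$covariates$id), 0L)
  c3 <- make_cohort(4, waveform_params_sampler = short, seed = 12)
  expect_false(identical(c1$covariates, c3$covariates))
})

test_that("cohort covariates follow the documented sampler", {
  short <- function(i, cov) waveform_params(duration = 60, seed = i)
  co <- make_cohort(150, waveform_params_sampler = short, seed = 21)
  ages <- co$covariates$age
  expect_gt(median(ages), 43 - 18)  # within sampler IQR bounds
  expect_lt(median(ages), 43 + 18)
  expect_gt(mean(co$covariates$sex == "M"), 0.6)
  expect_true(all(co$covariates$marshall_grade %in% c("II", "III", "IV", "V")))
})

test_that("mean RAP is non-decreasing in the coupling", {
  grid <- c(0, 0.3, 0.6, 0.9)
  mean_rap <- vapply(grid, function(cpl) {
    mean(vapply(1:3, function(r)
      mean_rap_for_coupling(cpl, seed = 100 * r + 7, duration = 1800),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rap) >= 0))
})

test_that("stationary ARMA draws pass both stationarity tests", {
  co <- reference_arma_coefficients("arma22")
  verdicts <- vapply(1:40, function(s) {
    x <- simulate_arma(co$spec, co$ar, co$ma, n = 1000, seed = 5000 + s)
    isTRUE(test_stationarity(x)$stationary)
  }, logical(1))
  expect_gte(mean(verdicts), 0.95)
})
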