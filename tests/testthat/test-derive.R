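test_that("10-s decimation equals brute-force block means", {
  # constant channel
  rec <- tiny_recording(rep(12, 3000))
  expect_true(all(decimate_10s(rec)$values == 12))
  # 20-s ramp at 100 Hz: two block means by direct summation
  ramp <- seq(0, 20, length.out = 2000)
  dec <- decimate_10s(tiny_recording(ramp))
  expect_equal(dec$values,
               c(sum(ramp[1:1000]) / 1000, sum(ramp[1001:2000]) / 1000),
               tolerance = 1e-12)
  # 25-s input: trailing 5 s dropped
  expect_length(decimate_10s(tiny_recording(rnorm(2500)))$values, 2)
  # shorter than a block: error
  expect_error(decimate_10s(tiny_recording(rnorm(500))), "10-s block")
})

test_that("AMP recovers the fundamental harmonic amplitude", {
  fs <- 100
  t <- (0:(30 * fs - 1)) / fs
  # pure 1.2 Hz sinusoid of amplitude 2 mmHg on a DC offset
  rec <- tiny_recording(10 + 2 * sin(2 * pi * 1.2 * t), fs = fs)
  amp <- compute_amp(rec)
  expect_equal(amp$values, rep(2, 3), tolerance = 0.02)
  # an off-bin cardiac frequency still lands within the leakage tolerance
  rec_off <- tiny_recording(10 + 2 * sin(2 * pi * 1.234 * t), fs = fs)
  expect_equal(compute_amp(rec_off)$values, rep(2, 3), tolerance = 0.05)
  # flatline -> AMP 0
  expect_true(all(compute_amp(tiny_recording(rep(15, 2000)))$values == 0))
})

test_that("AMP recovers the generator's pulse amplitude within 5%", {
  p <- waveform_params(duration = 300, pulse_amplitude = 1.7, coupling = 0,
                       trend_sd = 0, noise_sd = 0.05, seed = 17)
  rec <- simulate_pulsatile(p)
  amp <- compute_amp(rec)
  expect_equal(mean(amp$values), 1.7, tolerance = 0.05 * 1.7)
})

test_that("moving correlation matches the two-pass Pearson oracle", {
  set.seed(55)
  x <- tiny_series(rnorm(300))
  y <- tiny_series(rnorm(300), name = "AMP")
  mc <- moving_correlation(x, y)
  ends <- seq(30, 300, by = 6)
  oracle <- vapply(ends, function(e)
    pearson_two_pass(x$values[(e - 29):e], y$values[(e - 29):e]), numeric(1))
  expect_equal(mc$values, oracle, tolerance = 1e-12)
  expect_equal(mc$time, x$time[ends])
})

test_that("moving correlation honours affine invariance and degeneracy", {
  x <- tiny_series(rnorm(60))
  y2 <- tiny_series(2 * x$values + 3, name = "AMP")
  expect_true(all(abs(moving_correlation(x, y2)$values - 1) < 1e-12))
  yn <- tiny_series(-x$values, name = "AMP")
  expect_true(all(abs(moving_correlation(x, yn)$values + 1) < 1e-12))
  # zero variance in a window -> missing, not 0 or +/-1
  const <- tiny_series(rep(5, 60), name = "AMP")
  expect_true(all(is.na(moving_correlation(x, const)$values)))
})

test_that("CPP is the elementwise MAP - ICP identity", {
  map <- tiny_series(c(80, 90, NA), name = "MAP", resolution = "1min")
  icp <- tiny_series(c(15, 20, 25), name = "ICP", resolution = "1min")
  cpp <- compute_cpp(map, icp)
  expect_equal(cpp$values, c(65, 70, NA))
  expect_equal(cpp$values + icp$values, map$values)
  icp_off <- tiny_series(c(15, 20, 25), name = "ICP", resolution = "1min",
                         t0 = 7)
  expect_error(compute_cpp(map, icp_off), "time base")
})

test_that("validity filtering blanks parents and dependents together", {
  icp <- tiny_series(c(10, 150, 12, -20, 14), name = "ICP",
                     resolution = "1min")
  map <- tiny_series(c(80, 85, 250, 90, 95), name = "MAP",
                     resolution = "1min")
  amp <- tiny_series(c(1, 2, 3, 4, 5), name = "AMP", resolution = "1min")
  out <- apply_validity_filter(icp, map, dependents = list(amp))
  expect_equal(out$n_excluded, 3)
  expect_equal(which(is.na(out$icp$values)), c(2, 3, 4))
  expect_equal(which(is.na(out$dependents[[1]]$values)), c(2, 3, 4))
  # all in bounds -> untouched
  ok <- apply_validity_filter(tiny_series(c(10, 11), name = "ICP",
                                          resolution = "1min"))
  expect_equal(ok$icp$values, c(10, 11))
  expect_equal(ok$n_excluded, 0)
})

test_that("resampling equals brute-force block means at every resolution", {
  s <- tiny_series(1:60, name = "ICP", resolution = "1min")
  hr <- resample_mean(s, "60min")
  expect_equal(hr$values, 30.5)
  set.seed(8)
  v <- rnorm(125)
  s2 <- tiny_series(v, name = "ICP", resolution = "1min")
  r10 <- resample_mean(s2, "10min")
  oracle <- vapply(1:12, function(b) mean(v[((b - 1) * 10 + 1):(b * 10)]),
                   numeric(1))
  expect_equal(r10$values, oracle, tolerance = 1e-12)
  # constant series stays constant
  expect_true(all(resample_mean(tiny_series(rep(3, 90), name = "ICP",
                                            resolution = "1min"),
                                "30min")$values == 3))
  # blocks over 50% missing become missing
  v[1:6] <- NA
  r <- resample_mean(tiny_series(v, name = "ICP", resolution = "1min"),
                     "10min")
  expect_true(is.na(r$values[1]))
  expect_error(resample_mean(s, "5min"))
})

test_that("the derivation pipeline is deterministic and bounded", {
  rec <- simulate_pulsatile(waveform_params(duration = 1200, seed = 77))
  i1 <- derive_indices(rec)
  i2 <- derive_indices(rec)
  expect_identical(i1, i2)
  for (nm in c("RAP", "PRx")) {
    v <- i1[[nm]]$values
    expect_true(all(is.na(v) | (v >= -1 & v <= 1)))
  }
})
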