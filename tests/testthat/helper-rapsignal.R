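# Shared fixtures, all generated in code.

# Small uniform recording with arbitrary channel values.
tiny_recording <- function(values, fs = 100, channel = "ICP") {
  n <- length(values)
  ch <- list()
  ch[[channel]] <- values
  physio_recording(time = (0:(n - 1)) / fs, channels = ch, sample_rate = fs)
}

# 10-s index series from plain values.
tiny_series <- function(values, name = "ICP", resolution = "10s", t0 = 0) {
  step <- resolution_seconds(resolution)
  index_series(name, t0 + step * seq_along(values), values, resolution)
}

# Two-pass Pearson correlation, the independent oracle for the moving
# correlation: explicit means first, then explicit cross-products.
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Mean RAP of a derived recording with the given coupling.
mean_rap_for_coupling <- function(coupling, seed, duration = 3600,
                                  sample_rate = 100) {
  rec <- simulate_pulsatile(waveform_params(duration = duration,
                                            sample_rate = sample_rate,
                                            coupling = coupling,
                                            seed = seed))
  mean(derive_indices(rec)$RAP$values, na.rm = TRUE)
}
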