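#' Validity bounds for physiologic plausibility filtering
#'
#' Samples with ICP above 100 mmHg or below -15 mmHg, or MAP above 200 mmHg
#' or below 0 mmHg, are physiologically implausible and are excluded
#' together with every index derived from them.
#'
#' @param icp_min,icp_max,map_min,map_max Bounds in mmHg.
#' @return A list of class `validity_bounds`.
#' @export
validity_bounds <- function(icp_min = -15, icp_max = 100,
                            map_min = 0, map_max = 200) {
  if (icp_min >= icp_max || map_min >= map_max)
    stop("each channel needs min < max")
  structure(list(icp_min = icp_min, icp_max = icp_max,
                 map_min = map_min, map_max = map_max),
            class = "validity_bounds")
}

#' Decimate a raw waveform channel to non-overlapping 10-s means
#'
#' Each output sample is the arithmetic mean of one 10-second block of raw
#' samples, updated every 10 s so blocks never overlap; a trailing partial
#' block is dropped. Output samples are stamped at the block end.
#'
#' @param recording A [physio_recording()] uniformly sampled at >= 50 Hz.
#' @param channel Channel name, e.g. `"ICP"`.
#' @param name Name for the output series (defaults to the channel name).
#' @return An [index_series()] at `"10s"` resolution.
#' @export
decimate_10s <- function(recording, channel = "ICP", name = channel) {
  x <- recording$channels[[channel]]
  if (is.null(x)) stop(sprintf("no channel '%s' in recording", channel))
  fs <- recording$sample_rate
  if (identical(fs, "irregular") || fs < 50)
    stop("decimation requires uniform sampling at >= 50 Hz")
  k <- round(10 * fs)
  if (length(x) < k) stop("recording shorter than one 10-s block")
  vals <- block_means(x, k, max_missing = 0.25)
  t0 <- recording$time[1]
  index_series(name = name, time = t0 + 10 * seq_along(vals), values = vals,
               resolution = "10s")
}

#' Extract ICP pulse amplitude (AMP) per 10-s block
#'
#' AMP is the amplitude of the fundamental cardiac harmonic of the ICP
#' waveform, obtained by Fourier analysis of each non-overlapping 10-s
#' block: the spectral peak is located within the cardiac band (40-180
#' beats/min by default) and its amplitude is `2 * |coefficient| / N`. To
#' make the estimate robust to spectral leakage when the cardiac frequency
#' falls between DFT bins, the energy of the peak bin and its three
#' neighbours on each side is pooled before conversion to amplitude. A
#' block with no spectral content in the band (e.g. a flatline) yields
#' AMP = 0.
#'
#' @param recording A [physio_recording()] with an ICP channel at >= 50 Hz.
#' @param channel Channel holding the pulsatile ICP waveform.
#' @param band Cardiac search band in beats/min.
#' @return An [index_series()] named `"AMP"` at `"10s"` resolution.
#' @export
compute_amp <- function(recording, channel = "ICP", band = c(40, 180)) {
  x <- recording$channels[[channel]]
  if (is.null(x)) stop(sprintf("no channel '%s' in recording", channel))
  fs <- recording$sample_rate
  if (identical(fs, "irregular") || fs < 50)
    stop("AMP extraction requires uniform sampling at >= 50 Hz")
  k <- round(10 * fs)
  if (length(x) < k) stop("recording shorter than one 10-s block")
  n_blocks <- length(x) %/% k
  freq <- (seq_len(k %/% 2)) * fs / k           # positive frequencies, Hz
  in_band <- freq >= band[1] / 60 & freq <= band[2] / 60
  band_idx <- which(in_band)
  vals <- vapply(seq_len(n_blocks), function(b) {
    seg <- x[((b - 1) * k + 1):(b * k)]
    miss <- is.na(seg)
    if (mean(miss) > 0.25) return(NA_real_)
    if (any(miss)) { # fill sparse gaps so the DFT is computable
      seg <- stats::approx(which(!miss), seg[!miss], xout = seq_len(k),
                           rule = 2)$y
    }
    if (stats::sd(seg) < 1e-12) return(0)
    co <- stats::fft(seg - mean(seg))
    mag2 <- Mod(co[band_idx + 1])^2             # +1 skips the DC bin
    peak <- which.max(mag2)
    if (mag2[peak] <= 0) return(0)
    lo <- max(1, band_idx[peak] - 3)
    hi <- min(k %/% 2, band_idx[peak] + 3)
    2 * sqrt(sum(Mod(co[(lo:hi) + 1])^2)) / k
  }, numeric(1))
  t0 <- recording$time[1]
  index_series(name = "AMP", time = t0 + 10 * seq_len(n_blocks),
               values = vals, resolution = "10s")
}

#' Moving Pearson correlation between two 10-s series
#'
#' The engine behind RAP and PRx: a Pearson correlation over a window of 30
#' consecutive 10-s means (a 5-minute window), updated every minute (every
#' 6th 10-s step), with each value stamped at the window end. A window with
#' zero variance in either parent yields a missing value; windows with more
#' than 25% missing parent samples are also missing, otherwise the
#' correlation uses the complete pairs.
#'
#' @param x,y Aligned [index_series()] at `"10s"` resolution.
#' @param window_samples Window length in parent samples (default 30).
#' @param update_samples Emission cadence in parent samples (default 6,
#'   i.e. one value per minute).
#' @param name Name for the output series.
#' @return An [index_series()] at `"1min"` resolution.
#' @export
moving_correlation <- function(x, y, window_samples = 30, update_samples = 6,
                               name = "RAP") {
  if (length(x$values) != length(y$values) ||
      any(abs(x$time - y$time) > 1e-6))
    stop("'x' and 'y' must share one time base")
  n <- length(x$values)
  if (n < window_samples)
    return(index_series(name, numeric(0), numeric(0), "1min"))
  ends <- seq(window_samples, n, by = update_samples)
  vals <- vapply(ends, function(e) {
    i <- (e - window_samples + 1):e
    xv <- x$values[i]; yv <- y$values[i]
    ok <- !is.na(xv) & !is.na(yv)
    if (mean(ok) < 0.75) return(NA_real_)
    if (stats::sd(xv[ok]) < 1e-12 || stats::sd(yv[ok]) < 1e-12)
      return(NA_real_)
    r <- stats::cor(xv[ok], yv[ok])
    min(1, max(-1, r))
  }, numeric(1))
  index_series(name = name, time = x$time[ends], values = vals,
               resolution = "1min")
}

#' Cerebral perfusion pressure
#'
#' Elementwise `CPP = MAP - ICP` on aligned series; missing values
#' propagate.
#'
#' @param map,icp Aligned [index_series()] at the same resolution.
#' @return An [index_series()] named `"CPP"`.
#' @export
compute_cpp <- function(map, icp) {
  if (length(map$values) != length(icp$values) ||
      any(abs(map$time - icp$time) > 1e-6))
    stop("'map' and 'icp' must share one time base")
  index_series(name = "CPP", time = map$time, values = map$values - icp$values,
               resolution = map$resolution)
}

#' Exclude physiologically implausible samples and their derived values
#'
#' Scans the ICP and MAP series for samples outside the validity bounds and
#' sets those timestamps to missing in ICP and MAP themselves and in every
#' dependent series (CPP, AMP, RAP, PRx, ...) supplied, since values
#' derived from an implausible parent are themselves erroneous. Dependent
#' series may live on a different (e.g. delayed) time base; matching is by
#' timestamp within half a resolution step.
#'
#' @param icp,map [index_series()] at a common resolution (either may be
#'   `NULL` to skip its bounds).
#' @param dependents List of [index_series()] to blank at the excluded
#'   timestamps.
#' @param bounds A [validity_bounds()].
#' @return List with the filtered `icp`, `map`, `dependents`, and
#'   `n_excluded` (number of timestamps excluded by direct bound violation).
#' @export
apply_validity_filter <- function(icp = NULL, map = NULL,
                                  dependents = list(),
                                  bounds = validity_bounds()) {
  bad_times <- numeric(0)
  step <- NULL
  if (!is.null(icp)) {
    step <- resolution_seconds(icp$resolution)
    bad <- !is.na(icp$values) &
      (icp$values > bounds$icp_max | icp$values < bounds$icp_min)
    bad_times <- c(bad_times, icp$time[bad])
  }
  if (!is.null(map)) {
    if (is.null(step)) step <- resolution_seconds(map$resolution)
    bad <- !is.na(map$values) &
      (map$values > bounds$map_max | map$values < bounds$map_min)
    bad_times <- c(bad_times, map$time[bad])
  }
  bad_times <- sort(unique(bad_times))
  blank <- function(s) {
    if (length(bad_times) == 0 || length(s$values) == 0) return(s)
    hit <- vapply(s$time, function(t) any(abs(bad_times - t) <= step / 2),
                  logical(1))
    s$values[hit] <- NA_real_
    s
  }
  list(icp = if (is.null(icp)) NULL else blank(icp),
       map = if (is.null(map)) NULL else blank(map),
       dependents = lapply(dependents, blank),
       n_excluded = length(bad_times))
}

#' Reduce a minute-level series to a lower temporal resolution
#'
#' Non-overlapping block means of 10, 30, or 60 consecutive minute-level
#' samples, stamped at the block end; a block with more than 50% missing
#' samples yields a missing value, and a trailing partial block is dropped.
#'
#' @param series An [index_series()] at `"1min"` resolution.
#' @param resolution Target: `"10min"`, `"30min"`, or `"60min"`.
#' @return An [index_series()] at the target resolution.
#' @export
resample_mean <- function(series, resolution) {
  if (series$resolution != "1min")
    stop("resampling starts from the 1min resolution")
  if (!resolution %in% c("10min", "30min", "60min"))
    stop("unsupported target resolution")
  k <- resolution_seconds(resolution) / 60
  vals <- block_means(series$values, k, max_missing = 0.5)
  t0 <- if (length(series$time)) series$time[1] - 60 else 0
  index_series(name = series$name,
               time = t0 + resolution_seconds(resolution) * seq_along(vals),
               values = vals, resolution = resolution)
}

# Non-overlapping means of 6 consecutive 10-s samples -> minute level.
minute_means <- function(series10s) {
  vals <- block_means(series10s$values, 6, max_missing = 0.5)
  t0 <- if (length(series10s$time)) series10s$time[1] - 10 else 0
  index_series(name = series10s$name, time = t0 + 60 * seq_along(vals),
               values = vals, resolution = "1min")
}

#' Run the full index-derivation chain on a raw recording
#'
#' From pulsatile ICP/ABP to the minute-level index set: 10-s decimation of
#' ICP and ABP (the 10-s ABP mean is the MAP estimate, i.e. the
#' time-averaged pressure over the window), spectral AMP extraction, RAP
#' (moving correlation of ICP and AMP) and PRx (moving correlation of ICP
#' and MAP), CPP, minute-level aggregation, and validity filtering at the
#' minute level.
#'
#' @param recording A [physio_recording()] with `ICP` and `ABP` channels.
#' @param bounds A [validity_bounds()], or `NULL` to skip filtering.
#' @param resolutions Additional resolutions (subset of `"10min"`,
#'   `"30min"`, `"60min"`) to attach, resampled from the minute level.
#' @return A list of class `index_set`: minute-level `ICP`, `MAP`, `AMP`,
#'   `CPP`, `RAP`, `PRx`, the 10-s parents under `parents_10s`, and one
#'   named sublist per extra resolution.
#' @export
derive_indices <- function(recording, bounds = validity_bounds(),
                           resolutions = character(0)) {
  icp10 <- decimate_10s(recording, "ICP")
  map10 <- decimate_10s(recording, "ABP", name = "MAP")
  amp10 <- compute_amp(recording, "ICP")
  rap <- moving_correlation(icp10, amp10, name = "RAP")
  prx <- moving_correlation(icp10, map10, name = "PRx")
  icp1 <- minute_means(icp10)
  map1 <- minute_means(map10)
  amp1 <- minute_means(amp10)
  cpp1 <- compute_cpp(map1, icp1)
  if (!is.null(bounds)) {
    filt <- apply_validity_filter(icp1, map1,
                                  dependents = list(amp1, cpp1, rap, prx),
                                  bounds = bounds)
    icp1 <- filt$icp; map1 <- filt$map
    amp1 <- filt$dependents[[1]]; cpp1 <- filt$dependents[[2]]
    rap <- filt$dependents[[3]]; prx <- filt$dependents[[4]]
  }
  out <- list(ICP = icp1, MAP = map1, AMP = amp1, CPP = cpp1,
              RAP = rap, PRx = prx,
              parents_10s = list(ICP = icp10, MAP = map10, AMP = amp10))
  for (res in resolutions) {
    out[[res]] <- lapply(list(ICP = icp1, MAP = map1, AMP = amp1,
                              CPP = cpp1, RAP = rap, PRx = prx),
                         resample_mean, resolution = res)
  }
  structure(out, class = "index_set")
}
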