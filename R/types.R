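#' Known temporal resolutions and their step in seconds
#'
#' @keywords internal
RESOLUTION_SECONDS <- c("10s" = 10, "1min" = 60, "10min" = 600,
                        "30min" = 1800, "60min" = 3600)

#' Seconds per step for a named temporal resolution
#'
#' @param resolution One of `"10s"`, `"1min"`, `"10min"`, `"30min"`, `"60min"`.
#' @return Step length in seconds.
#' @export
resolution_seconds <- function(resolution) {
  resolution <- match.arg(resolution, names(RESOLUTION_SECONDS))
  unname(RESOLUTION_SECONDS[resolution])
}

#' Multi-channel time-stamped physiological recording
#'
#' A light container for raw pressure waveforms (or pre-decimated series):
#' a strictly increasing time base in seconds plus one numeric vector per
#' channel. Missing samples are explicit `NA`s, never dropped rows.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param channels Named list of numeric vectors, each the same length as
#'   `time` (e.g. `list(ICP = ..., ABP = ...)`, in mmHg).
#' @param sample_rate Sampling frequency in Hz, or `"irregular"`.
#' @return An object of class `physio_recording`.
#' @export
physio_recording <- function(time, channels, sample_rate) {
  time <- as.numeric(time)
  if (anyNA(time)) stop("timestamps must not be missing")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a named list of numeric vectors")
  for (nm in names(channels)) {
    channels[[nm]] <- as.numeric(channels[[nm]])
    if (length(channels[[nm]]) != length(time))
      stop(sprintf("channel '%s' length (%d) differs from time length (%d)",
                   nm, length(channels[[nm]]), length(time)))
  }
  structure(list(time = time, channels = channels, sample_rate = sample_rate),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  dur <- if (length(x$time) > 1) diff(range(x$time)) else 0
  cat(sprintf("<physio_recording> %d samples, %.1f s, rate %s Hz\n",
              length(x$time), dur, format(x$sample_rate)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.physio_recording <- function(x) length(x$time)

#' Uniformly sampled derived index series
#'
#' Holds one derived signal (ICP, MAP, AMP, CPP, RAP or PRx) at a named
#' temporal resolution. Correlation indices (RAP, PRx) are unitless in
#' \[-1, 1\]; pressures and AMP are in mmHg. Values may be `NA`.
#'
#' @param name Signal name, e.g. `"RAP"`.
#' @param time Numeric timestamps in seconds, uniformly spaced at the
#'   resolution step (each value is stamped at the end of the window or
#'   block that produced it).
#' @param values Numeric vector, same length as `time`.
#' @param resolution One of `"10s"`, `"1min"`, `"10min"`, `"30min"`, `"60min"`.
#' @return An object of class `index_series`.
#' @export
index_series <- function(name, time, values, resolution) {
  resolution <- match.arg(resolution, names(RESOLUTION_SECONDS))
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values))
    stop("'time' and 'values' must have equal length")
  step <- RESOLUTION_SECONDS[[resolution]]
  if (length(time) > 1) {
    d <- diff(time)
    # the time base is a uniform grid at the resolution step; whole grid
    # rows may be absent (e.g. a clean series after artifact removal), so
    # any gap must be a positive integer multiple of the step
    mult <- d / step
    if (any(mult < 1 - 1e-6) || any(abs(mult - round(mult)) > 1e-6))
      stop(sprintf("'%s' series is not on a uniform %s grid", name, resolution))
  }
  if (name %in% c("RAP", "PRx")) {
    bad <- !is.na(values) & (values < -1 - 1e-12 | values > 1 + 1e-12)
    if (any(bad)) stop(sprintf("%s values outside [-1, 1]", name))
  }
  structure(list(name = name, time = time, values = values,
                 resolution = resolution),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series> %s @ %s, %d samples (%d missing)\n",
              x$name, x$resolution, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.index_series <- function(x) length(x$values)

#' @export
as.data.frame.index_series <- function(x, ...) {
  data.frame(DateTime = x$time, value = x$values)
}

#' Boolean artifact labels aligned to a time base
#'
#' @param time Numeric timestamps (seconds) of the labelled series.
#' @param flags Logical vector, `TRUE` = artifact sample.
#' @param provenance Either `"ground_truth"` or `"detected"`.
#' @return An object of class `artifact_mask`.
#' @export
artifact_mask <- function(time, flags, provenance = c("ground_truth", "detected")) {
  provenance <- match.arg(provenance)
  flags <- as.logical(flags)
  if (length(time) != length(flags))
    stop("'time' and 'flags' must have equal length")
  if (anyNA(flags)) stop("mask flags must not be missing")
  structure(list(time = as.numeric(time), flags = flags,
                 provenance = provenance),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> (%s) %d samples, %d flagged (%.1f%%)\n",
              x$provenance, length(x$flags), sum(x$flags),
              100 * mean(x$flags)))
  invisible(x)
}

#' @export
length.artifact_mask <- function(x) length(x$flags)

#' ARIMA order triple
#'
#' @param p Autoregressive order, 0-10.
#' @param d Differencing order, 0 or 1.
#' @param q Moving-average order, 0-10.
#' @return An object of class `arima_spec`.
#' @export
arima_spec <- function(p, d = 0, q = 0) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (is.na(p) || p < 0 || p > 10) stop("'p' must be an integer in 0..10")
  if (is.na(q) || q < 0 || q > 10) stop("'q' must be an integer in 0..10")
  if (is.na(d) || !d %in% c(0L, 1L)) stop("'d' must be 0 or 1")
  structure(list(p = p, d = d, q = q), class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("ARIMA(%d, %d, %d)\n", x$p, x$d, x$q))
  invisible(x)
}

#' @export
format.arima_spec <- function(x, ...) sprintf("(%d,%d,%d)", x$p, x$d, x$q)
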