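#' Read a time-stamped physiologic CSV export
#'
#' Expects a comma-separated file with a header row, a `DateTime` column
#' (epoch seconds or ISO-8601), and one numeric column per channel.
#' Unparseable rows are reported with their line numbers; duplicated or
#' non-monotone timestamps are rejected. Empty fields become explicit `NA`
#' samples, never dropped rows.
#'
#' @param path Path to the CSV file.
#' @param channel_map Optional named character vector renaming file columns
#'   to channel names, e.g. `c(icp_mmhg = "ICP")`.
#' @param time_column Name of the timestamp column.
#' @param sample_rate Sampling rate to record; `NULL` infers it from the
#'   median timestamp step (`"irregular"` if steps vary by > 1%).
#' @return A [physio_recording()].
#' @export
read_physio_csv <- function(path, channel_map = NULL,
                            time_column = "DateTime", sample_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!time_column %in% names(df))
    stop(sprintf("no '%s' column in %s", time_column, path))
  raw_t <- df[[time_column]]
  t <- suppressWarnings(as.numeric(raw_t))
  if (anyNA(t)) {
    parsed <- tryCatch(
      as.POSIXct(as.character(raw_t), tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                "%Y-%m-%d %H:%M:%OS")),
      error = function(e) rep(as.POSIXct(NA), length(raw_t)))
    t <- as.numeric(parsed)
  }
  if (anyNA(t)) {
    bad <- which(is.na(t)) + 1L  # +1 for the header line
    stop(sprintf("unparseable timestamps at line(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (anyDuplicated(t)) {
    dup <- which(duplicated(t)) + 1L
    stop(sprintf("duplicated timestamps at line(s): %s",
                 paste(utils::head(dup, 10), collapse = ", ")))
  }
  if (is.unsorted(t)) stop("timestamps are not increasing")
  chan_cols <- setdiff(names(df), time_column)
  channels <- lapply(df[chan_cols], function(col) {
    suppressWarnings(as.numeric(col))
  })
  names(channels) <- chan_cols
  if (!is.null(channel_map)) {
    hit <- names(channels) %in% names(channel_map)
    names(channels)[hit] <- channel_map[names(channels)[hit]]
  }
  if (is.null(sample_rate)) {
    d <- diff(t)
    sample_rate <- if (length(d) == 0) "irregular"
    else if (max(abs(d - stats::median(d))) <= 0.01 * stats::median(d))
      1 / stats::median(d) else "irregular"
  }
  physio_recording(time = t, channels = channels, sample_rate = sample_rate)
}

#' Write a recording (and optional mask) to CSV
#'
#' Emits a `DateTime` column (epoch seconds, full precision) plus one
#' column per channel; an [artifact_mask()] is written as a 0/1 column
#' named `artifact`.
#'
#' @param recording A [physio_recording()].
#' @param path Output path.
#' @param mask Optional [artifact_mask()] aligned to the recording.
#' @return `path`, invisibly.
#' @export
write_physio_csv <- function(recording, path, mask = NULL) {
  df <- data.frame(DateTime = recording$time, check.names = FALSE)
  for (nm in names(recording$channels)) df[[nm]] <- recording$channels[[nm]]
  if (!is.null(mask)) {
    if (length(mask$flags) != length(recording$time))
      stop("mask length differs from recording length")
    df$artifact <- as.integer(mask$flags)
  }
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identify artifact samples by aligning clean and non-clean series
#'
#' Expert cleaning removes artifact samples from an archived recording, so
#' any timestamp present in the non-clean series but absent from the clean
#' one is an artifact sample. Timestamps match when they agree within half
#' the nominal resolution step. The clean series must be a subset of the
#' non-clean series.
#'
#' @param clean,nonclean [index_series()] at a common resolution.
#' @return An [artifact_mask()] over the non-clean time base.
#' @export
align_clean_nonclean <- function(clean, nonclean) {
  step <- resolution_seconds(nonclean$resolution)
  tol <- step / 2
  # nearest-match each clean timestamp into the non-clean base
  idx <- findInterval(clean$time, nonclean$time + tol) + 1L
  ok <- idx >= 1 & idx <= length(nonclean$time) &
    abs(nonclean$time[pmin(idx, length(nonclean$time))] - clean$time) <= tol
  if (!all(ok))
    stop(sprintf("%d clean timestamp(s) absent from the non-clean series",
                 sum(!ok)))
  flags <- rep(TRUE, length(nonclean$time))
  flags[idx] <- FALSE
  artifact_mask(nonclean$time, flags, "ground_truth")
}

#' Export maximal artifact segments to CSV files
#'
#' Each maximal run of flagged samples becomes one CSV (DateTime + value),
#' mirroring the archival convention of storing artifact segments
#' separately from clean data.
#'
#' @param series An [index_series()].
#' @param mask An aligned [artifact_mask()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of the files written.
#' @export
write_artifact_segments <- function(series, mask, dir, prefix = series$name) {
  if (length(mask$flags) != length(series$values))
    stop("mask length differs from series length")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs <- true_runs(mask$flags)
  files <- character(0)
  if (nrow(runs) > 0) for (r in seq_len(nrow(runs))) {
    i <- runs[r, 1]:runs[r, 2]
    f <- file.path(dir, sprintf("%s_artifact_%03d.csv", prefix, r))
    utils::write.csv(data.frame(DateTime = series$time[i],
                                value = series$values[i]),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  files
}

#' Run configuration with field defaults
#'
#' Central bundle of tunables for the derivation, structure, and detection
#' stages. Every numeric default is the value used throughout the package
#' documentation: 30-sample (5-minute) correlation windows updated every
#' minute, validity bounds of \[-15, 100\] mmHg for ICP and \[0, 200\] mmHg
#' for MAP, ARIMA orders searched over 0..10, and the sliding-window
#' detector geometries (order detector 100/50 at 1 min and 50/25 at 10 min;
#' variance and cross-correlation detectors 50/25 at both).
#'
#' @param resolutions Resolutions to analyse.
#' @param bounds A [validity_bounds()].
#' @param rap_window,rap_update RAP/PRx window and update cadence in 10-s
#'   samples.
#' @param p_max,q_max ARIMA grid bounds.
#' @param criterion Information criterion for model selection.
#' @param order_tolerance Order-deviation detector threshold.
#' @param detector_windows Named list of `c(window, step)` pairs per
#'   detector kind and resolution.
#' @return A list of class `run_config`.
#' @export
run_config <- function(resolutions = c("1min", "10min", "30min", "60min"),
                       bounds = validity_bounds(),
                       rap_window = 30, rap_update = 6,
                       p_max = 10, q_max = 10,
                       criterion = c("aic", "bic", "ll"),
                       order_tolerance = 3,
                       detector_windows = list(
                         order_1min = c(100, 50), order_10min = c(50, 25),
                         variance = c(50, 25), xcorr = c(50, 25))) {
  criterion <- match.arg(criterion)
  resolutions <- match.arg(resolutions, names(RESOLUTION_SECONDS),
                           several.ok = TRUE)
  stopifnot(rap_window > 0, rap_update > 0, p_max >= 0, q_max >= 0,
            order_tolerance >= 0)
  for (w in detector_windows)
    if (length(w) != 2 || w[2] <= 0 || w[2] > w[1])
      stop("each detector window must satisfy 0 < step <= window")
  structure(list(resolutions = resolutions, bounds = bounds,
                 rap_window = rap_window, rap_update = rap_update,
                 p_max = p_max, q_max = q_max, criterion = criterion,
                 order_tolerance = order_tolerance,
                 detector_windows = detector_windows),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' `bounds` may be a mapping with `icp_min`, `icp_max`, `map_min`,
#' `map_max`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(raw$bounds)) raw$bounds <- do.call(validity_bounds, raw$bounds)
  do.call(run_config, raw)
}
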