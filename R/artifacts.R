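# Clean-vs-artifact discrimination: per-segment ARIMA order comparison,
# residuals under a reference model, residual cross-correlation, the three
# sliding-window detectors, and success-rate evaluation.

#' Sliding-window detector configuration
#'
#' Window geometry follows the sliding-window convention of 50% overlap:
#' the step (stride) is half the window, i.e. window 100 / step 50 for the
#' order-deviation detector at minute resolution and 50 / 25 elsewhere.
#'
#' @param kind One of `"order_deviation"`, `"residual_variance"`,
#'   `"cross_correlation"`.
#' @param window,step Window length and stride in samples
#'   (`0 < step <= window`).
#' @param order_tolerance Order-deviation threshold: a window is flagged
#'   when a fitted order differs from the reference by *more than* this.
#' @param p_max,q_max Order-search bounds for per-window fits.
#' @param refine_k Exact-likelihood refinements per window fit (small, for
#'   speed; the window argmin needs only a coarse criterion ranking).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(kind = c("order_deviation", "residual_variance",
                                     "cross_correlation"),
                            window = 100, step = 50, order_tolerance = 3,
                            p_max = 10, q_max = 10, refine_k = 3) {
  kind <- match.arg(kind)
  if (step <= 0 || step > window)
    stop("need 0 < step <= window")
  if (order_tolerance < 0) stop("'order_tolerance' must be >= 0")
  structure(list(kind = kind, window = window, step = step,
                 order_tolerance = order_tolerance, p_max = p_max,
                 q_max = q_max, refine_k = refine_k),
            class = "detector_config")
}

# Start indices of sliding windows: floor((n - window) / step) + 1 windows.
window_starts <- function(n, window, step) {
  if (n < window) return(integer(0))
  seq(1L, n - window + 1L, by = step)
}

#' Optimal ARIMA models for the clean and artifact parts of a series
#'
#' Splits a series by its artifact mask, concatenates each class's
#' samples (artifact segments are typically short, so per-class
#' concatenation is what makes an order search feasible; the spliced
#' boundaries contribute a handful of spurious transitions, acceptable
#' next to the order signal itself), and runs the exhaustive order search
#' on each. A class with fewer than `min_samples` values yields an
#' `"insufficient_data"` marker instead of a model.
#'
#' @param series An [index_series()].
#' @param mask An aligned [artifact_mask()].
#' @param min_samples Minimum class size for a search (default 50).
#' @param ... Passed to [grid_search()].
#' @return List with `clean` and `artifact`, each either an `arima_grid`
#'   or the string `"insufficient_data"`.
#' @export
segment_models <- function(series, mask, min_samples = 50, ...) {
  if (length(mask$flags) != length(series$values))
    stop("mask length differs from series length")
  one <- function(keep) {
    v <- series$values[keep]
    v <- v[!is.na(v)]
    if (length(v) < min_samples) return("insufficient_data")
    grid_search(v, ...)
  }
  list(clean = one(!mask$flags), artifact = one(mask$flags))
}

#' Compare clean and artifact ARIMA orders across patients
#'
#' For each signal, runs a two-sided Mann-Whitney U test between the
#' clean-group and artifact-group order values, separately for p-orders
#' and q-orders. The d-order is excluded (it is fixed at 1 throughout).
#'
#' @param clean,artifact Data frames with columns `signal`, `p`, `q`, one
#'   row per patient; at least two patients per group and signal.
#' @return Data frame with columns `signal`, `order`, `p_value`.
#' @export
compare_orders <- function(clean, artifact) {
  signals <- sort(unique(c(clean$signal, artifact$signal)))
  rows <- list()
  for (sig in signals) {
    a <- clean[clean$signal == sig, ]
    b <- artifact[artifact$signal == sig, ]
    if (nrow(a) < 2 || nrow(b) < 2)
      stop(sprintf("signal '%s' needs >= 2 patients per group", sig))
    for (ord in c("p", "q")) {
      ht <- suppressWarnings(stats::wilcox.test(a[[ord]], b[[ord]],
                                                exact = FALSE))
      pv <- unname(ht$p.value)
      # fully tied samples give an indeterminate normal approximation;
      # there is then no detectable location shift
      if (is.na(pv)) pv <- 1
      rows[[length(rows) + 1]] <- data.frame(
        signal = sig, order = paste0(ord, "-order"), p_value = pv)
    }
  }
  do.call(rbind, rows)
}

#' Residuals of a segment under a reference ARIMA specification
#'
#' Fixes the reference orders (typically the population median optimal
#' model of the clean data) and re-estimates the coefficients on the
#' segment by maximum likelihood, returning the residual series. Segments
#' shorter than `p + q + 2` (after differencing) yield an
#' `"insufficient_data"` marker rather than an error.
#'
#' @param segment An [index_series()] or numeric vector.
#' @param reference An [arima_spec()].
#' @return Numeric residual vector, or the string `"insufficient_data"`.
#' @export
residuals_under_reference <- function(segment, reference) {
  fit <- fit_arima(segment, reference)
  if (fit$status != "ok") return("insufficient_data")
  res <- fit$residuals
  res[!is.na(res)]
}

#' Maximum cross-correlation between two residual streams
#'
#' Slides one series over the other across every lag and returns the
#' maximum of the raw sliding dot products (unnormalized, so magnitudes
#' scale with segment length and variance; set `normalized = TRUE` for a
#' scale-free variant, which is never the default).
#'
#' @param a,b Numeric vectors (missing values dropped); both non-empty.
#' @param normalized Divide by `sqrt(sum(a^2) * sum(b^2))`.
#' @return Maximum cross-correlation value (over all lags).
#' @export
max_residual_xcorr <- function(a, b, normalized = FALSE) {
  a <- as.numeric(a); a <- a[!is.na(a)]
  b <- as.numeric(b); b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("cross-correlation needs non-empty inputs")
  # convolve() correlates (it conjugates the second argument), so this is
  # the sliding dot product of a against b across all lags
  cc <- stats::convolve(a, b, type = "open")
  m <- max(cc)
  if (normalized) m <- m / sqrt(sum(a^2) * sum(b^2))
  m
}

new_detection_result <- function(windows, series, flags_by_sample,
                                 truth = NULL, config) {
  detected <- artifact_mask(series$time, flags_by_sample, "detected")
  out <- list(windows = windows, detected = detected, config = config,
              success_rate = NA_real_, false_positive_count = NA_integer_)
  if (!is.null(truth)) {
    ev <- evaluate_detection(detected, truth)
    out$success_rate <- ev$success_rate
    out$false_positive_count <- ev$false_positive_count
  }
  structure(out, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: %d/%d windows flagged",
              x$config$kind, sum(x$windows$flagged), nrow(x$windows)))
  if (!is.na(x$success_rate))
    cat(sprintf(", success %.1f%%, %d false positives",
                x$success_rate, x$false_positive_count))
  cat("\n")
  invisible(x)
}

#' Order-deviation sliding-window artifact detector
#'
#' Runs the exhaustive order search within each sliding window and flags
#' the window as artifact-bearing when any fitted order (p or q; d is
#' common) differs from the clean reference model's by more than the
#' order tolerance. The detected mask is exactly the union of flagged
#' windows' samples.
#'
#' @param series An [index_series()] (non-clean data).
#' @param reference An [arima_spec()]: the clean-data optimal model
#'   (per-patient by default; a population median model may be passed
#'   instead).
#' @param config A [detector_config()] (kind `"order_deviation"`).
#' @param truth Optional ground-truth [artifact_mask()] for evaluation.
#' @return A `detection_result`.
#' @export
detect_order_deviation <- function(series, reference,
                                   config = detector_config("order_deviation"),
                                   truth = NULL) {
  n <- length(series$values)
  starts <- window_starts(n, config$window, config$step)
  flags_by_sample <- rep(FALSE, n)
  rows <- list()
  for (s in starts) {
    idx <- s:(s + config$window - 1L)
    g <- tryCatch(
      grid_search(series$values[idx], p_max = config$p_max,
                  q_max = config$q_max, d = reference$d,
                  refine_k = config$refine_k),
      error = function(e) NULL)
    if (is.null(g)) {
      rows[[length(rows) + 1]] <- data.frame(start = s, end = idx[length(idx)],
                                             p = NA, q = NA, flagged = FALSE)
      next
    }
    dev <- max(abs(g$spec$p - reference$p), abs(g$spec$q - reference$q))
    fl <- dev > config$order_tolerance
    if (fl) flags_by_sample[idx] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(start = s, end = idx[length(idx)],
                                           p = g$spec$p, q = g$spec$q,
                                           flagged = fl)
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), p = integer(0),
               q = integer(0), flagged = logical(0))
  new_detection_result(windows, series, flags_by_sample, truth, config)
}

#' Residual-variance sliding-window artifact detector
#'
#' Computes residuals of the whole (non-clean) series under the clean
#' median optimal model, then flags every window whose residual variance
#' strictly exceeds the reference variance — by default the median of the
#' per-window residual variances of the recording (`reference_variance`
#' overrides it, e.g. with a population value). On purely clean data this
#' rule flags about half the windows by the definition of the median, a
#' false-positive propensity the evaluation reports rather than hides.
#'
#' @param series An [index_series()] (non-clean data).
#' @param reference An [arima_spec()]: clean median optimal model.
#' @param config A [detector_config()] (kind `"residual_variance"`),
#'   typically window 50 / step 25.
#' @param truth Optional ground-truth [artifact_mask()].
#' @param reference_variance Optional externally supplied threshold.
#' @return A `detection_result`.
#' @export
detect_residual_variance <- function(series, reference,
                                     config = detector_config(
                                       "residual_variance", window = 50,
                                       step = 25),
                                     truth = NULL,
                                     reference_variance = NULL) {
  res <- residuals_on_time_base(series, reference)
  n <- length(series$values)
  starts <- window_starts(n, config$window, config$step)
  vars <- vapply(starts, function(s) {
    r <- res[s:(s + config$window - 1L)]
    if (mean(is.na(r)) > 0.5) return(NA_real_)
    stats::var(r, na.rm = TRUE)
  }, numeric(1))
  threshold <- if (is.null(reference_variance))
    stats::median(vars, na.rm = TRUE) else reference_variance
  flagged <- !is.na(vars) & vars > threshold
  flags_by_sample <- rep(FALSE, n)
  for (i in which(flagged))
    flags_by_sample[starts[i]:(starts[i] + config$window - 1L)] <- TRUE
  windows <- data.frame(start = starts,
                        end = starts + config$window - 1L,
                        residual_variance = vars, flagged = flagged)
  new_detection_result(windows, series, flags_by_sample, truth, config)
}

# Residuals of `series` under `reference`, re-expanded onto the series'
# own sample positions (missing samples and the d differenced-away leading
# positions carry NA), so window indexing stays aligned to the time base.
residuals_on_time_base <- function(series, reference) {
  x <- series_values(series)
  ok <- which(!is.na(x))
  res <- residuals_under_reference(x[ok], reference)
  if (identical(res, "insufficient_data"))
    stop("series too short for residuals under the reference model")
  out <- rep(NA_real_, length(x))
  pos <- if (reference$d > 0) ok[-seq_len(reference$d)] else ok
  pos <- pos[seq_along(res)]
  out[pos[!is.na(pos)]] <- res[!is.na(pos)]
  out
}

#' Residual cross-correlation sliding-window artifact detector
#'
#' Computes residuals of the index series (RAP) and one of its parent
#' signals (AMP recommended; ICP proved unreliable for this purpose) under
#' their respective clean median models, then flags every window whose
#' maximum residual cross-correlation falls strictly below the median of
#' the per-window maxima of the recording (or an externally supplied
#' threshold). Identical residual streams therefore never flag: no window
#' is strictly below the median of equal values.
#'
#' @param rap_series An [index_series()] (non-clean RAP).
#' @param parent_series An [index_series()] (non-clean AMP or ICP) whose
#'   time base contains the RAP one.
#' @param rap_reference,parent_reference [arima_spec()] clean median
#'   models for the two signals.
#' @param config A [detector_config()] (kind `"cross_correlation"`).
#' @param truth Optional ground-truth [artifact_mask()] on the RAP base.
#' @param reference_xcorr Optional externally supplied threshold.
#' @return A `detection_result` (mask on the RAP time base).
#' @export
detect_xcorr <- function(rap_series, parent_series, rap_reference,
                         parent_reference,
                         config = detector_config("cross_correlation",
                                                  window = 50, step = 25),
                         truth = NULL, reference_xcorr = NULL) {
  step_s <- resolution_seconds(rap_series$resolution)
  keep <- vapply(parent_series$time, function(t)
    any(abs(rap_series$time - t) <= step_s / 2), logical(1))
  if (sum(keep) != length(rap_series$time))
    stop("parent series does not cover the RAP time base")
  parent_aligned <- rap_series
  parent_aligned$values <- parent_series$values[keep]
  res_rap <- residuals_on_time_base(rap_series, rap_reference)
  res_par <- residuals_on_time_base(parent_aligned, parent_reference)
  n <- length(rap_series$values)
  starts <- window_starts(n, config$window, config$step)
  vals <- vapply(starts, function(s) {
    i <- s:(s + config$window - 1L)
    a <- res_rap[i]; b <- res_par[i]
    ok <- !is.na(a) & !is.na(b)
    if (mean(ok) < 0.5) return(NA_real_)
    max_residual_xcorr(a[ok], b[ok])
  }, numeric(1))
  threshold <- if (is.null(reference_xcorr)) stats::median(vals, na.rm = TRUE)
  else reference_xcorr
  flagged <- !is.na(vals) & vals < threshold
  flags_by_sample <- rep(FALSE, n)
  for (i in which(flagged))
    flags_by_sample[starts[i]:(starts[i] + config$window - 1L)] <- TRUE
  windows <- data.frame(start = starts,
                        end = starts + config$window - 1L,
                        max_xcorr = vals, flagged = flagged)
  new_detection_result(windows, rap_series, flags_by_sample, truth, config)
}

#' Success rate and false positives of a detected mask
#'
#' Success rate is `(captured artifacts / true artifacts) * 100`, where a
#' true artifact sample counts as captured when the detected mask covers
#' it (`mode = "sample"`, default) or when its maximal artifact segment
#' overlaps at least one detected sample (`mode = "segment"`). False
#' positives are detected samples that are not true artifacts; they are
#' reported even when the truth mask is empty (success rate then `NA`).
#'
#' @param detected,truth Aligned [artifact_mask()] objects.
#' @param mode `"sample"` or `"segment"` capture granularity.
#' @return List with `success_rate` (percent, `NA` if no true artifacts),
#'   `false_positive_count`, `captured`, `total_true`.
#' @export
evaluate_detection <- function(detected, truth, mode = c("sample", "segment")) {
  mode <- match.arg(mode)
  if (length(detected$flags) != length(truth$flags))
    stop("masks must be aligned")
  fp <- sum(detected$flags & !truth$flags)
  if (mode == "sample") {
    total <- sum(truth$flags)
    captured <- sum(truth$flags & detected$flags)
  } else {
    runs <- true_runs(truth$flags)
    total <- nrow(runs)
    captured <- if (total == 0) 0 else
      sum(vapply(seq_len(total), function(r)
        any(detected$flags[runs[r, 1]:runs[r, 2]]), logical(1)))
  }
  list(success_rate = if (total == 0) NA_real_ else 100 * captured / total,
       false_positive_count = fp, captured = captured, total_true = total)
}
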