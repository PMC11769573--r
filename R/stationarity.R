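# Augmented Dickey-Fuller and KPSS tests.
#
# Both tests are implemented directly on their defining regressions.
# ADF p-values use the MacKinnon (1994) response-surface polynomials for
# the constant-only (no trend) case; KPSS p-values are interpolated from
# the Kwiatkowski et al. (1992) asymptotic critical-value table. Outside
# the tabulated ranges p-values are clamped and flagged as bounded.

# MacKinnon (1994) polynomial coefficients, constant-only regression.
.adf_tau_star <- -1.61
.adf_tau_min <- -18.83
.adf_tau_max <- 2.74
.adf_smallp <- c(2.1659, 1.4412, 0.038269)
.adf_largep <- c(1.7339, 0.93202, -0.12745, -0.010368)

adf_pvalue <- function(stat) {
  if (stat > .adf_tau_max) return(list(p = 1, bounded = TRUE))
  if (stat < .adf_tau_min) return(list(p = 0, bounded = TRUE))
  cf <- if (stat <= .adf_tau_star) .adf_smallp else .adf_largep
  p <- stats::pnorm(sum(cf * stat^(seq_along(cf) - 1)))
  list(p = p, bounded = FALSE)
}

#' Augmented Dickey-Fuller unit-root test (constant, no trend)
#'
#' Regresses the first difference on the lagged level, a constant, and
#' `lags` lagged differences; the t statistic of the lagged level is
#' compared against the MacKinnon (1994) response surface to obtain an
#' approximate p-value. The null hypothesis is a unit root, so small
#' p-values indicate stationarity.
#'
#' @param x Numeric vector (missing values removed).
#' @param lags Number of augmenting lags; default `trunc((n - 1)^(1/3))`.
#' @return List with `statistic`, `p_value`, `lags`, `bounded`.
#' @export
adf_test <- function(x, lags = NULL) {
  x <- as.numeric(stats::na.omit(x))
  n <- length(x)
  if (n < 10) stop("series too short for the ADF regression")
  if (is.null(lags)) lags <- trunc((n - 1)^(1 / 3))
  lags <- max(0L, as.integer(lags))
  dx <- diff(x)
  m <- length(dx)
  idx <- (lags + 1):m
  yl <- x[idx]                    # level at t-1
  X <- cbind(yl, 1)
  if (lags > 0)
    for (i in seq_len(lags)) X <- cbind(X, dx[idx - i])
  y <- dx[idx]
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[1, 1])
  stat <- fit$coefficients[1] / se
  pv <- adf_pvalue(unname(stat))
  list(statistic = unname(stat), p_value = pv$p, lags = lags,
       bounded = pv$bounded)
}

# KPSS asymptotic critical values for level stationarity.
.kpss_cv <- c(0.347, 0.463, 0.574, 0.739)
.kpss_p <- c(0.10, 0.05, 0.025, 0.01)

#' KPSS level-stationarity test
#'
#' Tests the null of stationarity around a constant level. The statistic
#' is the scaled sum of squared partial sums of the demeaned series, with
#' a Bartlett-window long-run variance using `trunc(3 * sqrt(n) / 13)`
#' lags. The p-value is linearly interpolated from the asymptotic table
#' and clamped to \[0.01, 0.10\] outside it (`bounded` flags clamping).
#' Large statistics (small p-values) indicate non-stationarity.
#'
#' @param x Numeric vector (missing values removed).
#' @param lags Bartlett truncation lag; default `trunc(3 * sqrt(n) / 13)`.
#' @return List with `statistic`, `p_value`, `lags`, `bounded`.
#' @export
kpss_test <- function(x, lags = NULL) {
  x <- as.numeric(stats::na.omit(x))
  n <- length(x)
  if (n < 10) stop("series too short for the KPSS statistic")
  if (is.null(lags)) lags <- trunc(3 * sqrt(n) / 13)
  lags <- max(0L, as.integer(lags))
  e <- x - mean(x)
  s_t <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0) for (l in seq_len(lags)) {
    w <- 1 - l / (lags + 1)
    lrv <- lrv + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
  }
  if (lrv <= 0) lrv <- .Machine$double.eps
  stat <- sum(s_t^2) / (n^2 * lrv)
  if (stat <= .kpss_cv[1]) {
    p <- 0.10; bounded <- stat < .kpss_cv[1]
  } else if (stat >= .kpss_cv[4]) {
    p <- 0.01; bounded <- stat > .kpss_cv[4]
  } else {
    p <- stats::approx(.kpss_cv, .kpss_p, xout = stat)$y
    bounded <- FALSE
  }
  list(statistic = stat, p_value = p, lags = lags, bounded = bounded)
}

#' Joint stationarity verdict from ADF and KPSS
#'
#' A series is judged stationary when the ADF test rejects its unit-root
#' null (p < alpha) *and* the KPSS test fails to reject its stationarity
#' null (p > alpha). The two tests have complementary nulls, so requiring
#' both guards against trend- and level-non-stationarity at once. A series
#' with fewer than 20 non-missing samples yields an `"insufficient_data"`
#' marker and a constant series a `"degenerate"` marker, not an error.
#'
#' @param series An [index_series()] or numeric vector.
#' @param alpha Decision threshold for both tests.
#' @return A list of class `stationarity_result` with `adf_p`, `kpss_p`,
#'   `stationary`, `status` (`"ok"`, `"insufficient_data"`, or
#'   `"degenerate"`), and the bounded-p flags.
#' @export
test_stationarity <- function(series, alpha = 0.05) {
  x <- as.numeric(stats::na.omit(series_values(series)))
  out <- structure(list(adf_p = NA_real_, kpss_p = NA_real_,
                        stationary = NA, status = "ok",
                        adf_bounded = NA, kpss_bounded = NA),
                   class = "stationarity_result")
  if (length(x) < 20) { out$status <- "insufficient_data"; return(out) }
  if (stats::sd(x) < 1e-12) { out$status <- "degenerate"; return(out) }
  adf <- adf_test(x)
  kp <- kpss_test(x)
  out$adf_p <- adf$p_value
  out$kpss_p <- kp$p_value
  out$adf_bounded <- adf$bounded
  out$kpss_bounded <- kp$bounded
  out$stationary <- (adf$p_value < alpha) && (kp$p_value > alpha)
  out
}

#' @export
print.stationarity_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<stationarity_result> %s\n", x$status))
  } else {
    cat(sprintf("<stationarity_result> ADF p=%.4g, KPSS p=%.4g -> %s\n",
                x$adf_p, x$kpss_p,
                if (isTRUE(x$stationary)) "stationary" else "non-stationary"))
  }
  invisible(x)
}

#' First-order differencing of a series
#'
#' `y_t = x_t - x_(t-1)`, applied `order` times; the series shortens by
#' `order` samples. Differencing is applied after temporal resampling,
#' never before, so stationarity tests and model fits see the same series.
#'
#' @param series An [index_series()] or numeric vector.
#' @param order Differencing order (>= 1).
#' @return Same container type as the input.
#' @export
difference_series <- function(series, order = 1) {
  if (order < 1) stop("'order' must be >= 1")
  if (inherits(series, "index_series")) {
    if (length(series$values) < order + 1)
      stop("series too short to difference")
    out <- series
    out$values <- diff(series$values, differences = order)
    out$time <- series$time[-seq_len(order)]
    out
  } else {
    if (length(series) < order + 1) stop("series too short to difference")
    diff(as.numeric(series), differences = order)
  }
}
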