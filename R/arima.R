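# ARIMA structure analysis: maximum-likelihood fits, exhaustive order
# search under information criteria, population median models, and
# residual diagnostics.

# Long-AR residuals for Hannan-Rissanen initialization.
hr_innovations <- function(x) {
  ord <- min(20L, max(1L, length(x) %/% 4))
  fit <- stats::ar(x, order.max = ord, aic = FALSE, method = "yule-walker")
  e <- fit$resid
  e[is.na(e)] <- 0
  e
}

# Hannan-Rissanen two-stage regression start values for arima(): lagged
# levels and lagged long-AR innovations regressed on the level, plus an
# intercept. Wild values are clamped so optim starts inside a sane region.
hr_start <- function(x, p, q, e_long, include_const = TRUE) {
  n <- length(x)
  m <- max(15L, p, q)
  if (n - m < p + q + 2) return(NULL)
  if (p == 0 && q == 0) return(if (include_const) mean(x) else numeric(0))
  idx <- (m + 1):n
  X <- NULL
  if (p > 0) for (i in seq_len(p)) X <- cbind(X, x[idx - i])
  if (q > 0) for (j in seq_len(q)) X <- cbind(X, e_long[idx - j])
  if (include_const) X <- cbind(X, 1)
  cf <- tryCatch(stats::lm.fit(X, x[idx])$coefficients,
                 error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  cf[is.na(cf)] <- 0
  ncoef <- p + q
  cf[seq_len(ncoef)] <- pmax(pmin(cf[seq_len(ncoef)], 2), -2)
  cf
}

#' Fit an ARIMA model of fixed order
#'
#' Maximum-likelihood fit of the ARMA recursion with constant
#' `X_t = c + e_t + sum(phi_i X_(t-i)) + sum(theta_j e_(t-j))`.
#' When `spec` carries `d = 1`, the series is differenced first and the
#' ARMA part fitted to the differenced series (reported against the
#' original series as a d = 1 model); stationarity testing and fitting
#' thereby always operate on the same series. Non-convergence is flagged,
#' never raised; a series shorter than `p + q + 2` (after differencing)
#' yields an `"insufficient_data"` marker.
#'
#' @param series An [index_series()] or numeric vector.
#' @param spec An [arima_spec()].
#' @param include_const Include the constant `c` (default TRUE).
#' @param method `"CSS-ML"` (exact likelihood, CSS-initialised; default),
#'   `"ML"`, or `"CSS"` (conditional sum of squares; its log-likelihood is
#'   the Gaussian conditional likelihood at the optimum).
#' @param init Optional start values passed to [stats::arima()].
#' @param n_cond For CSS, the number of burn-in observations conditioned
#'   on; fixing it across a model grid makes conditional likelihoods
#'   comparable.
#' @param optim_control Control list for the inner optimiser.
#' @return A list of class `rap_arima_fit`: `spec`, `const`, `ar`, `ma`,
#'   `sigma2`, `loglik`, `aic`, `bic`, `k` (parameter count including the
#'   innovation variance), `n_used`, `residuals`, `converged`, `status`.
#' @export
fit_arima <- function(series, spec, include_const = TRUE,
                      method = c("CSS-ML", "ML", "CSS"), init = NULL,
                      n_cond = NULL, optim_control = list()) {
  method <- match.arg(method)
  if (!inherits(spec, "arima_spec")) spec <- do.call(arima_spec, as.list(spec))
  x <- as.numeric(series_values(series))
  x <- x[!is.na(x)]
  if (spec$d > 0) {
    if (length(x) < spec$d + 1)
      return(insufficient_fit(spec, "insufficient_data"))
    x <- diff(x, differences = spec$d)
  }
  n <- length(x)
  if (n < spec$p + spec$q + 2)
    return(insufficient_fit(spec, "insufficient_data"))
  if (spec$p == 0 && spec$q == 0) {
    # closed-form Gaussian MLE: no optimisation, residuals are exactly the
    # (de)meaned series
    const <- if (include_const) mean(x) else 0
    res <- x - const
    s2 <- sum(res^2) / n
    ll <- -0.5 * n * (log(2 * pi * s2) + 1)
    k <- as.integer(include_const) + 1L
    return(structure(list(
      spec = spec, const = const, ar = numeric(0), ma = numeric(0),
      sigma2 = s2, loglik = ll, aic = 2 * k - 2 * ll,
      bic = k * log(n) - 2 * ll, k = k, n_used = n, residuals = res,
      converged = TRUE, status = "ok", method = method),
      class = "rap_arima_fit"))
  }
  warned <- FALSE
  args <- list(x, order = c(spec$p, 0L, spec$q),
               include.mean = include_const, method = method,
               optim.control = optim_control)
  if (!is.null(init)) args$init <- init
  if (method == "CSS" && !is.null(n_cond)) args$n.cond <- n_cond
  f <- tryCatch(withCallingHandlers(
    do.call(stats::arima, args),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }), error = function(e) NULL)
  if (is.null(f)) return(insufficient_fit(spec, "failed"))
  k <- spec$p + spec$q + as.integer(include_const) + 1L  # + sigma2
  if (method == "CSS") {
    n_used <- f$nobs
    ll <- -0.5 * n_used * (log(2 * pi * f$sigma2) + 1)
  } else {
    n_used <- f$nobs
    ll <- f$loglik
  }
  cf <- stats::coef(f)
  structure(list(
    spec = spec,
    const = if (include_const) unname(cf["intercept"]) else 0,
    ar = unname(cf[grep("^ar", names(cf))]),
    ma = unname(cf[grep("^ma", names(cf))]),
    sigma2 = f$sigma2,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(n_used) - 2 * ll,
    k = k,
    n_used = n_used,
    residuals = as.numeric(f$residuals),
    converged = (is.null(f$code) || f$code == 0) && !warned,
    status = "ok",
    method = method), class = "rap_arima_fit")
}

insufficient_fit <- function(spec, status) {
  structure(list(spec = spec, const = NA_real_, ar = numeric(0),
                 ma = numeric(0), sigma2 = NA_real_, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_, k = NA_integer_,
                 n_used = 0L, residuals = numeric(0), converged = FALSE,
                 status = status, method = NA_character_),
            class = "rap_arima_fit")
}

#' @export
print.rap_arima_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<rap_arima_fit> ARIMA%s: %s\n", format(x$spec), x$status))
  } else {
    cat(sprintf("<rap_arima_fit> ARIMA%s %s loglik=%.2f aic=%.2f%s\n",
                format(x$spec), x$method, x$loglik, x$aic,
                if (x$converged) "" else " (not converged)"))
  }
  invisible(x)
}

# Criterion column and sense (smaller-is-better after sign flip).
criterion_value <- function(tab, criterion) {
  switch(criterion, aic = tab$aic, bic = tab$bic, ll = -tab$loglik)
}

#' Exhaustive ARIMA order search under an information criterion
#'
#' Evaluates every (p, q) combination with p, q in 0..`p_max`/`q_max` at
#' d = 0 on the (optionally pre-differenced) series and returns the
#' criterion-minimising order. Fitting runs in two stages: a fast
#' conditional-sum-of-squares screen of all cells (Hannan-Rissanen start
#' values, a fixed conditioning length of `p_max` so conditional
#' likelihoods are comparable across orders), followed by exact-likelihood
#' refits of the `refine_k` leading candidates, among which the final
#' argmin is taken. Ties break towards smaller `p + q`, then smaller `p`.
#' Cells whose fit fails carry an explicit non-convergence marker; they are
#' excluded from the argmin. Failed convergence of every cell is an error.
#'
#' @param series An [index_series()] or numeric vector.
#' @param p_max,q_max Grid bounds (default 10).
#' @param d Differencing order applied before the search (default 1); the
#'   returned spec reports this `d`.
#' @param criterion `"aic"` (default), `"bic"`, or `"ll"`.
#' @param refine_k Number of leading candidates refit by exact likelihood;
#'   0 skips refinement and selects on the screened criterion directly.
#' @param include_const Include the ARMA constant.
#' @return A list of class `arima_grid`: `spec` (optimal [arima_spec()]),
#'   `fit` (its exact-likelihood refit), `table` (one row per grid cell
#'   with `p`, `q`, `loglik`, `aic`, `bic`, `converged`, `refined`), and
#'   `criterion`.
#' @export
grid_search <- function(series, p_max = 10, q_max = 10, d = 1,
                        criterion = c("aic", "bic", "ll"), refine_k = 6,
                        include_const = TRUE) {
  criterion <- match.arg(criterion)
  x <- as.numeric(series_values(series))
  x <- x[!is.na(x)]
  if (d > 0) {
    if (length(x) < d + 1) stop("series too short to difference")
    x <- diff(x, differences = d)
  }
  n <- length(x)
  if (n < 20) stop("series too short for an order search")
  e_long <- hr_innovations(x)
  tab <- expand.grid(p = 0:p_max, q = 0:q_max)
  tab$loglik <- NA_real_; tab$aic <- NA_real_; tab$bic <- NA_real_
  tab$converged <- FALSE; tab$refined <- FALSE
  n_cond <- p_max
  fits <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$p[i]; q <- tab$q[i]
    if (n - n_cond < p + q + 2) next
    f <- if (p == 0 && q == 0) {
      # same conditioning window as the CSS cells so criteria are comparable
      fit_arima(x[(n_cond + 1):n], arima_spec(0, 0, 0),
                include_const = include_const, method = "CSS")
    } else {
      fit_arima(x, arima_spec(p, 0, q), include_const = include_const,
                method = "CSS", init = hr_start(x, p, q, e_long,
                                                include_const),
                n_cond = n_cond,
                optim_control = list(maxit = 60, reltol = 1e-4))
    }
    if (f$status != "ok") next
    tab$loglik[i] <- f$loglik; tab$aic[i] <- f$aic; tab$bic[i] <- f$bic
    tab$converged[i] <- TRUE
    fits[[i]] <- f
  }
  if (!any(tab$converged)) stop("no (p, q) combination converged")
  val <- criterion_value(tab, criterion)
  val[!tab$converged] <- Inf
  ord <- order(val, tab$p + tab$q, tab$p)
  cand <- ord[seq_len(min(max(refine_k, 1), sum(tab$converged)))]
  # the conditional-likelihood screen is biased towards complex models (it
  # omits the initial-condition terms that the exact likelihood charges),
  # so always carry the parsimony frontier into the exact refit: the best
  # screened cell at each small total order
  for (m in 0:min(6, p_max + q_max)) {
    at_m <- which(tab$p + tab$q == m & tab$converged)
    if (length(at_m)) cand <- union(cand, at_m[which.min(val[at_m])])
  }
  if (refine_k > 0) {
    for (i in cand) {
      f <- fit_arima(x, arima_spec(tab$p[i], 0, tab$q[i]),
                     include_const = include_const, method = "CSS-ML")
      if (f$status == "ok" && is.finite(f$loglik)) {
        tab$loglik[i] <- f$loglik; tab$aic[i] <- f$aic; tab$bic[i] <- f$bic
        tab$refined[i] <- TRUE
        fits[[i]] <- f
      }
    }
    pool <- cand[tab$refined[cand]]
    if (length(pool) == 0) pool <- cand
  } else pool <- cand
  valp <- criterion_value(tab, criterion)[pool]
  best <- pool[order(valp, tab$p[pool] + tab$q[pool], tab$p[pool])][1]
  best_spec <- arima_spec(tab$p[best], d, tab$q[best])
  structure(list(spec = best_spec, fit = fits[[best]], table = tab,
                 criterion = criterion, d = d), class = "arima_grid")
}

#' @export
print.arima_grid <- function(x, ...) {
  cat(sprintf("<arima_grid> optimal ARIMA%s by %s over %d cells (%d converged)\n",
              format(x$spec), toupper(x$criterion), nrow(x$table),
              sum(x$table$converged)))
  invisible(x)
}

#' Population median optimal model
#'
#' Componentwise median of the p- and q-orders across per-patient optimal
#' models; a half-integer median rounds to the nearest even integer
#' (round-half-even). The d-order is passed through (its median, which in
#' practice is the common value).
#'
#' @param specs A list of [arima_spec()] objects (at least one).
#' @return An [arima_spec()].
#' @export
median_model <- function(specs) {
  if (length(specs) < 1) stop("need at least one spec")
  specs <- lapply(specs, function(s)
    if (inherits(s, "arima_spec")) s else do.call(arima_spec, as.list(s)))
  med <- function(v) as.integer(round(stats::median(v)))  # round() is half-even
  arima_spec(med(vapply(specs, `[[`, 0, "p")),
             med(vapply(specs, `[[`, 0, "d")),
             med(vapply(specs, `[[`, 0, "q")))
}

#' Residual diagnostics for an ARIMA specification
#'
#' Refits `spec` on the series and reports the magnitude and variance of
#' the residuals together with significant-spike counts in the residual
#' ACF and PACF over lags 1..`n_lags`, a spike being any value exceeding
#' the 95% white-noise band `1.96 / sqrt(N)`. Calling this with
#' `arima_spec(0, 0, 0)` yields the raw-data baseline (residuals are then
#' exactly the demeaned series), against which a candidate model's
#' residual reduction is judged.
#'
#' @param series An [index_series()] or numeric vector.
#' @param spec An [arima_spec()].
#' @param n_lags ACF/PACF horizon (default 30).
#' @param ci Confidence level for the spike band (default 0.95).
#' @return A list of class `diagnostics_report`: `median_abs_residual`,
#'   `residual_variance`, `data_variance`, `acf_spike_count`,
#'   `pacf_spike_count`, `acf`, `pacf`, `ci_bound`, `n_lags`, `fit`.
#' @export
arima_diagnostics <- function(series, spec, n_lags = 30, ci = 0.95) {
  x <- as.numeric(series_values(series))
  x <- x[!is.na(x)]
  fit <- fit_arima(x, spec)
  if (fit$status != "ok")
    stop("cannot compute diagnostics: ", fit$status)
  res <- fit$residuals[!is.na(fit$residuals)]
  nl <- min(n_lags, length(res) - 1)
  a <- as.numeric(stats::acf(res, lag.max = nl, plot = FALSE)$acf)[-1]
  p <- as.numeric(stats::pacf(res, lag.max = nl, plot = FALSE)$acf)
  bound <- stats::qnorm(1 - (1 - ci) / 2) / sqrt(length(res))
  structure(list(
    median_abs_residual = stats::median(abs(res)),
    residual_variance = stats::var(res),
    data_variance = stats::var(x),
    acf_spike_count = sum(abs(a) > bound),
    pacf_spike_count = sum(abs(p) > bound),
    acf = a, pacf = p, ci_bound = bound, n_lags = nl,
    n_residuals = length(res), fit = fit),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf(
    "<diagnostics_report> ARIMA%s: median|res|=%.4g var(res)=%.4g var(data)=%.4g\n",
    format(x$fit$spec), x$median_abs_residual, x$residual_variance,
    x$data_variance))
  cat(sprintf("  spikes beyond +/-%.3f over %d lags: ACF %d, PACF %d\n",
              x$ci_bound, x$n_lags, x$acf_spike_count, x$pacf_spike_count))
  invisible(x)
}

#' @export
plot.diagnostics_report <- function(x, main = NULL, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  lags <- seq_len(x$n_lags)
  for (panel in c("acf", "pacf")) {
    v <- x[[panel]]
    graphics::plot(lags, v, type = "h", ylim = range(c(v, x$ci_bound,
                                                       -x$ci_bound)),
                   xlab = "lag", ylab = toupper(panel),
                   main = main %||% sprintf("Residual %s", toupper(panel)))
    graphics::abline(h = c(-1, 1) * x$ci_bound, lty = 2, col = "blue")
    graphics::abline(h = 0)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
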