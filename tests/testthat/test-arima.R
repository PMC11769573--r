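test_that("white-noise fits reduce to the demeaned series", {
  set.seed(21)
  x <- rnorm(400)
  f <- fit_arima(x, arima_spec(0, 0, 0))
  expect_equal(f$residuals, x - mean(x))
  expect_equal(f$const, mean(x))
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-9)
})

test_that("maximum likelihood recovers AR(1) coefficients", {
  s <- simulate_arma(arima_spec(1, 0, 0), ar = 0.8, n = 5000, seed = 22)
  f <- fit_arima(s, arima_spec(1, 0, 0))
  expect_true(f$ar >= 0.75 && f$ar <= 0.85)
  expect_true(f$converged)
})

test_that("the AIC identity holds for every fit in a small grid", {
  s <- simulate_arma(arima_spec(1, 0, 1), ar = 0.6, ma = 0.3, n = 400,
                     seed = 23)
  for (p in 0:2) for (q in 0:2) {
    f <- fit_arima(s, arima_spec(p, 0, q))
    if (f$status == "ok") {
      expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-6)
      expect_equal(f$bic, f$k * log(f$n_used) - 2 * f$loglik,
                   tolerance = 1e-6)
    }
  }
})

test_that("d = 1 specs difference before fitting", {
  s <- simulate_arma(arima_spec(1, 1, 0), ar = 0.7, n = 2000, seed = 24)
  f <- fit_arima(s, arima_spec(1, 1, 0))
  expect_equal(f$spec$d, 1)
  expect_equal(f$ar, 0.7, tolerance = 0.07)
})

test_that("short series yield insufficient-data markers, not errors", {
  f <- fit_arima(rnorm(5), arima_spec(3, 0, 3))
  expect_equal(f$status, "insufficient_data")
  expect_false(f$converged)
})

test_that("the order grid is complete and selects parsimonious models", {
  set.seed(26)
  w <- rnorm(1200)
  g <- grid_search(w, d = 0)
  expect_equal(nrow(g$table), 121)
  expect_true(all(c("p", "q", "loglik", "aic", "bic", "converged") %in%
                    names(g$table)))
  # every cell is either converged or an explicit marker
  expect_false(any(is.na(g$table$converged)))
  # white noise: optimal is (0,.,0) or within 2 exact AIC of it (refined
  # cells carry exact likelihoods; the screened cells are conditional)
  aic00 <- g$table$aic[g$table$p == 0 & g$table$q == 0]
  if (!(g$spec$p == 0 && g$spec$q == 0)) {
    best_refined <- min(g$table$aic[g$table$refined])
    expect_lte(aic00 - best_refined, 2)
  } else succeed()
})

test_that("grid search tracks a known ARMA(2,2) structure", {
  co <- reference_arma_coefficients("arma22")
  s <- simulate_arma(co$spec, co$ar, co$ma, n = 3000, seed = 27)
  g <- grid_search(s, d = 0)
  # mechanics: the true-order cell converged, and the winner is at least
  # as good as it under the refined (exact) criterion when both refined
  true_cell <- g$table[g$table$p == 2 & g$table$q == 2, ]
  expect_true(true_cell$converged)
  best_cell <- g$table[g$table$p == g$spec$p & g$table$q == g$spec$q, ]
  if (true_cell$refined && best_cell$refined)
    expect_lte(best_cell$aic, true_cell$aic)
  # the fit behind the winner is usable
  expect_equal(g$fit$status, "ok")
  expect_equal(g$fit$spec$p, g$spec$p)
})

test_that("median model takes componentwise medians with half-even rounding", {
  expect_equal(unclass(median_model(list(arima_spec(3, 1, 3))))[c("p", "d", "q")],
               list(p = 3L, d = 1L, q = 3L))
  specs <- list(arima_spec(1, 1, 0), arima_spec(3, 1, 2),
                arima_spec(5, 1, 9))
  expect_equal(median_model(specs)$p, 3L)
  # {2, 3} -> 2.5 -> 2 under round-half-even
  expect_equal(median_model(list(arima_spec(2, 1, 1),
                                 arima_spec(3, 1, 1)))$p, 2L)
  expect_error(median_model(list()), "at least one")
})

test_that("diagnostics quantify the residual reduction of a good model", {
  co <- reference_arma_coefficients("arma22")
  s <- simulate_arma(co$spec, co$ar, co$ma, n = 2000, seed = 28)
  d_fit <- arima_diagnostics(s, arima_spec(2, 0, 2))
  d_base <- arima_diagnostics(s, arima_spec(0, 0, 0))
  # well-specified model: spikes within the binomial null upper bound
  expect_lte(d_fit$acf_spike_count, 4)
  expect_lte(d_fit$pacf_spike_count, 4)
  # residual variance drops below the data variance
  expect_lt(d_fit$residual_variance, d_fit$data_variance)
  # and below the no-model baseline's
  expect_lt(d_fit$median_abs_residual, d_base$median_abs_residual)
  # baseline residuals are exactly the demeaned series
  x <- s$values
  expect_equal(d_base$median_abs_residual, median(abs(x - mean(x))))
})
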