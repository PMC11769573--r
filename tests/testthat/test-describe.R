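test_that("summary statistics match the direct two-pass computation", {
  s <- summarize_series(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  const <- summarize_series(rep(4, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$min, const$max)
  set.seed(12)
  v <- rnorm(500)
  s2 <- summarize_series(v)
  expect_equal(s2$mean, sum(v) / 500, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / 499), tolerance = 1e-12)
  expect_equal(s2$median, unname(quantile(v, 0.5)), tolerance = 1e-12)
  expect_error(summarize_series(c(NA_real_, NA_real_)), "non-missing")
})

test_that("time in RAP states partitions the samples", {
  expect_equal(as.numeric(time_in_ranges(rep(0.7, 20))),
               c(100, 0, 0))
  tr <- time_in_ranges(c(-0.5, 0.2, 0.7, 0.9))
  expect_equal(as.numeric(tr), c(50, 25, 25))
  # boundary assignment: 0.4 -> impaired, 0 -> exhausted
  b <- time_in_ranges(c(0.4, 0))
  expect_equal(as.numeric(b), c(50, 0, 50))
  # percentages always total 100% of non-missing samples
  set.seed(3)
  for (i in 1:5) {
    x <- pmin(1, pmax(-1, rnorm(100, 0.3, 0.5)))
    x[sample(100, 10)] <- NA
    expect_equal(sum(time_in_ranges(x)), 100)
  }
})

test_that("two-group comparisons use the Mann-Whitney U test", {
  # identical groups: no location shift
  g <- rep(c("a", "b"), each = 30)
  v <- rep(seq_len(30), 2)
  cmp <- compare_groups(v, g)
  expect_equal(cmp$test, "mann-whitney")
  expect_gt(cmp$p_value, 0.9)
  # 3 SD separation at n = 100: decisive
  set.seed(9)
  v2 <- c(rnorm(100, 0, 1), rnorm(100, 3, 1))
  cmp2 <- compare_groups(v2, g <- rep(c("lo", "hi"), each = 100))
  expect_lt(cmp2$p_value, 0.001)
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("multi-group comparisons use one-way ANOVA with correct size", {
  set.seed(10)
  rejections <- vapply(1:400, function(i) {
    v <- rnorm(45)
    compare_groups(v, rep(c("a", "b", "c"), each = 15))$p_value < 0.05
  }, logical(1))
  # type-I error within the binomial 95% band around 5%
  expect_gt(mean(rejections), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rejections), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("threshold grouping excludes the dual-threshold dead zone", {
  x <- c(15, 21, 25, NA, 19)
  g <- group_by_threshold(x, c(20, 22))
  expect_equal(g, c("low", NA, "high", NA, "low"))
  g1 <- group_by_threshold(c(-0.1, 0, 0.1), 0)
  expect_equal(g1, c("low", NA, "high"))
})

test_that("cohort RAP ordering follows the coupling by Marshall grade", {
  balanced <- function(n) rep(c("II", "III", "IV"), length.out = n)
  co <- make_cohort(9, seed = 33,
                    covariate_sampler = list(marshall = balanced),
                    waveform_params_sampler = function(i, cov) {
                      base <- c(II = 0.1, III = 0.45, IV = 0.8)
                      waveform_params(duration = 900,
                                      coupling = base[[cov$marshall_grade]],
                                      seed = 900 + i)
                    })
  cmp <- compare_cohort_groups(co, "RAP", "marshall_grade")
  m <- cmp$groups$mean[match(c("II", "III", "IV"), cmp$groups$group)]
  expect_true(all(diff(m) > 0))
  expect_equal(cmp$test, "anova")
})
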