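#' RAP state threshold ranges
#'
#' RAP partitions into three clinical states: impaired compensatory
#' reserve (RAP in \[0.4, 1\]), intact reserve (RAP in (0, 0.4)), and
#' exhausted reserve (RAP in \[-1, 0\]). The boundary 0.4 is assigned to
#' the impaired state and exactly 0 to the exhausted state, so the three
#' ranges partition \[-1, 1\].
#'
#' @param impaired_lower Lower bound of the impaired range.
#' @param exhausted_upper Upper bound of the exhausted range.
#' @return A list of class `rap_state_ranges`.
#' @export
rap_state_ranges <- function(impaired_lower = 0.4, exhausted_upper = 0) {
  if (!(exhausted_upper < impaired_lower))
    stop("ranges must partition [-1, 1]")
  structure(list(impaired_lower = impaired_lower,
                 exhausted_upper = exhausted_upper),
            class = "rap_state_ranges")
}

#' Summary statistics of a series
#'
#' Count, mean, sample SD, minimum, quartiles, and maximum over the
#' non-missing values.
#'
#' @param series An [index_series()] or numeric vector.
#' @return A named list of class `summary_stats`.
#' @export
summarize_series <- function(series) {
  x <- as.numeric(stats::na.omit(series_values(series)))
  if (length(x) == 0) stop("no non-missing values to summarize")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x),
                 min = min(x), q25 = q[1], median = q[2], q75 = q[3],
                 max = max(x)), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d mean=%.4g sd=%.4g min=%.4g q25=%.4g median=%.4g q75=%.4g max=%.4g\n",
    x$n, x$mean, x$sd, x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}

#' Percentage of time spent in each RAP state
#'
#' Classifies every non-missing RAP sample into the impaired, intact, or
#' exhausted range and returns the percentage of time in each; the three
#' percentages always sum to 100% of the non-missing samples.
#'
#' @param rap An [index_series()] (values in \[-1, 1\] or missing) or
#'   numeric vector.
#' @param ranges A [rap_state_ranges()].
#' @return Named numeric vector with elements `impaired`, `intact`,
#'   `exhausted` (percent), plus attribute `n` (samples classified).
#' @export
time_in_ranges <- function(rap, ranges = rap_state_ranges()) {
  x <- as.numeric(stats::na.omit(series_values(rap)))
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12))
    stop("RAP values outside [-1, 1]")
  n <- length(x)
  if (n == 0)
    return(structure(c(impaired = NA_real_, intact = NA_real_,
                       exhausted = NA_real_), n = 0L))
  impaired <- sum(x >= ranges$impaired_lower)
  exhausted <- sum(x <= ranges$exhausted_upper)
  intact <- n - impaired - exhausted
  structure(100 * c(impaired = impaired, intact = intact,
                    exhausted = exhausted) / n, n = n)
}

#' Compare an index between patient subgroups
#'
#' Two groups are compared with the two-sided Mann-Whitney U test (normal
#' approximation with continuity correction, as the group sizes here make
#' exact enumeration impractical and ties are common); more than two
#' groups with one-way ANOVA (classic equal-variance F test). Every group
#' needs at least two values.
#'
#' @param values Numeric vector of observations (per-patient means or
#'   pooled samples, as chosen by the caller).
#' @param groups Factor or vector of group labels, same length as
#'   `values`.
#' @return A list of class `group_comparison`: `test` (`"mann-whitney"`
#'   or `"anova"`), `p_value`, `groups` (per-group n/mean/sd/median/IQR
#'   data frame), `statistic`.
#' @export
compare_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(sizes)[which(sizes < 2)[1]]))
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               iqr_low = unname(stats::quantile(v, 0.25)),
               iqr_high = unname(stats::quantile(v, 0.75)))
  }))
  if (nlevels(groups) == 2) {
    g <- levels(groups)
    ht <- suppressWarnings(stats::wilcox.test(
      values[groups == g[1]], values[groups == g[2]],
      alternative = "two.sided", exact = FALSE, correct = TRUE))
    test <- "mann-whitney"
  } else {
    ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    test <- "anova"
  }
  structure(list(test = test, p_value = unname(ht$p.value),
                 statistic = unname(ht$statistic), groups = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, p = %.4g\n", x$test, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Assign samples to groups by a physiologic threshold
#'
#' Maps each sample of a grouping series to `"low"`/`"high"` relative to a
#' threshold. With a dual threshold (e.g. ICP below 20 vs above 22 mmHg),
#' samples falling in the dead zone between the two bounds are excluded
#' (`NA`), since neither side claims them.
#'
#' @param series An [index_series()] or numeric vector to threshold.
#' @param thresholds One number (single cut: low `<` t, high `>` t, equal
#'   values excluded) or two (dual cut: low `<` t1, high `>` t2, dead zone
#'   \[t1, t2\] excluded).
#' @return Character vector of `"low"`, `"high"`, or `NA`.
#' @export
group_by_threshold <- function(series, thresholds) {
  x <- series_values(series)
  out <- rep(NA_character_, length(x))
  if (length(thresholds) == 1) {
    out[!is.na(x) & x < thresholds] <- "low"
    out[!is.na(x) & x > thresholds] <- "high"
  } else if (length(thresholds) == 2) {
    if (thresholds[1] > thresholds[2]) stop("thresholds must be ordered")
    out[!is.na(x) & x < thresholds[1]] <- "low"
    out[!is.na(x) & x > thresholds[2]] <- "high"
  } else stop("'thresholds' must have length 1 or 2")
  out
}

#' Cohort-level subgroup analysis of a derived index
#'
#' Convenience wrapper: derives per-patient mean index values from a
#' [make_cohort()] result and compares them across a covariate. The unit
#' of analysis is the per-patient mean by default; `pooled = TRUE` pools
#' minute-level samples instead (both modes are reported in practice since
#' archival analyses differ on this choice).
#'
#' @param cohort A `synthetic_cohort`.
#' @param index Which derived index to compare (e.g. `"RAP"`).
#' @param covariate Covariate column name (e.g. `"marshall_grade"`).
#' @param pooled Pool minute-level samples instead of per-patient means.
#' @param derived Optional pre-computed list of `index_set`s (as returned
#'   by [derive_indices()]), one per patient, to avoid re-derivation.
#' @return A [compare_groups()] result with the per-group table.
#' @export
compare_cohort_groups <- function(cohort, index = "RAP",
                                  covariate = "marshall_grade",
                                  pooled = FALSE, derived = NULL) {
  if (is.null(derived))
    derived <- lapply(cohort$patients,
                      function(p) derive_indices(p$recording))
  vals <- list(); labs <- list()
  for (i in seq_along(cohort$patients)) {
    v <- derived[[i]][[index]]$values
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    g <- cohort$patients[[i]]$covariates[[covariate]]
    if (pooled) {
      vals[[length(vals) + 1]] <- v
      labs[[length(labs) + 1]] <- rep(g, length(v))
    } else {
      vals[[length(vals) + 1]] <- mean(v)
      labs[[length(labs) + 1]] <- g
    }
  }
  compare_groups(unlist(vals), unlist(labs))
}
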