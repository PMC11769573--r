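# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure in their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed for patient `index` under a master seed; kept
# below 2^31 so it is a valid R integer seed.
derive_subseed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 1e5 * 19997 +
                as.numeric(index) * 7919 + 104729) %% 2147483647)
}

# Values of `x` as a plain numeric vector whatever the container.
series_values <- function(x) {
  if (inherits(x, "index_series")) x$values else as.numeric(x)
}

# Non-overlapping block means of `x` with blocks of `k` samples; a trailing
# partial block is dropped. Blocks whose missing fraction exceeds
# `max_missing` yield NA; otherwise the mean of the non-missing samples.
block_means <- function(x, k, max_missing = 0.5) {
  n_blocks <- length(x) %/% k
  if (n_blocks == 0) return(numeric(0))
  m <- matrix(x[seq_len(n_blocks * k)], nrow = k)
  miss <- colMeans(is.na(m))
  out <- colMeans(m, na.rm = TRUE)
  out[miss > max_missing | miss == 1] <- NA_real_
  out
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# (start, end) indices; zero rows when there are none.
true_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
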