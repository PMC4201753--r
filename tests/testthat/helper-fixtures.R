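# Small fixtures shared across test files. All data are generated in code.

# brute-force Mann-Whitney U: count pairs favouring x, ties as 1/2
bf_u <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s
}

# brute-force exact two-sided permutation p for the U statistic
bf_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  mu <- n1 * length(y) / 2
  obs <- abs(bf_u(x, y) - mu)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2L, function(i) bf_u(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= obs - 1e-12)
}

# reduced cohort: the full marker panel on few spots, for fast tests
small_config <- function(seed = 1L, n_spots = 40L, ...) {
  spots <- default_planted_spots()
  for (i in seq_along(spots)) spots[[i]]$spot_id <- i
  cohort_config(n_spots = n_spots, planted_effects = spots, seed = seed, ...)
}
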