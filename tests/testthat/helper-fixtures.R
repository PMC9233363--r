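# Shared fixtures, generated in code. Small genomes keep the suite fast;
# the same configurations are reused across test files.

small_config <- function(...) {
  args <- modifyList(
    list(genome_length = 1200L, n_control = 12L, n_drug = 6L,
         n_ba_sites = 10L, n_age_sites = 8L, n_du_sites = 6L,
         missing_pfc_fraction = 0, seed = 42L),
    list(...)
  )
  do.call(simulation_config, args)
}

# One small dataset shared by IO/matrix tests (lazy, computed once).
.fixture_env <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(small_config())
  }
  .fixture_env$sim
}

# Brute-force paired signed-rank p-value by enumerating all 2^n sign
# assignments of the observed absolute-difference ranks (two-sided,
# symmetric-tail convention). Independent of the package implementation.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force Mann-Whitney p-value by enumerating all choose(m+n, m)
# assignments of the pooled ranks to the first sample.
enumerate_mann_whitney_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  lower <- mean(u_all <= u_obs + 1e-9)
  upper <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
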