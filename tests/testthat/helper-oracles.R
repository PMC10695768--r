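# Independent oracles and tiny fixtures used across the suite.

# Brute-force Cliff's delta: enumerate every pair.
brute_cliffs <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# Exhaustive two-sided permutation p for the mean difference.
exhaustive_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- mean(a) - mean(b)
  splits <- utils::combn(length(pooled), n1)
  stats <- apply(splits, 2, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# Brute-force Euler integration of the three-state synaptic resource model,
# independent of the closed-form propagators in the package.
euler_stp <- function(times_s, params, dt_ms = 0.002) {
  x <- 1; y <- 0; z <- 0; u <- 0
  t_ms <- 0
  releases <- numeric(length(times_s))
  for (i in seq_along(times_s)) {
    target <- times_s[i] * 1000
    while (t_ms < target - 1e-9) {
      h <- min(dt_ms, target - t_ms)
      dx <- z / params$tau_rec
      dy <- -y / params$tau_syn
      dz <- y / params$tau_syn - z / params$tau_rec
      du <- if (params$tau_fac > 0) -u / params$tau_fac else 0
      x <- x + h * dx; y <- y + h * dy; z <- z + h * dz; u <- u + h * du
      if (params$tau_fac == 0) u <- 0
      t_ms <- t_ms + h
    }
    u <- u + params$u_base * (1 - u)
    rel <- u * x
    x <- x - rel; y <- y + rel
    releases[i] <- rel
  }
  list(releases = releases, x = x, y = y, z = z, u = u)
}

# Spike-train container for hand-built fixtures.
make_trains <- function(neuron_id, time, n_neurons, duration,
                        population = "CA3") {
  msbnet:::new_spike_trains(
    tibble::tibble(neuron_id = as.integer(neuron_id), time = time),
    n_neurons, duration, population)
}

# Two straight branches running parallel at separation `sep`, both children
# of the soma, each of length `len` (node spacing 0.5 um).
parallel_branch_tree <- function(sep = 3, len = 20, spacing = 0.5) {
  s <- seq(spacing, len, by = spacing)
  n <- length(s)
  tibble::tibble(
    id = 1:(2 * n + 1),
    type = c(1L, rep(3L, 2 * n)),
    x = c(0, s, s),
    y = c(0, rep(0, n), rep(sep, n)),
    z = 0,
    radius = c(1, rep(0.4, 2 * n)),
    parent = c(-1L, 1L, 1L + seq_len(n - 1L), 1L, n + 1L + seq_len(n - 1L))
  )
}

# A deliberately tiny network spec for fast simulations.
small_spec <- function(...) {
  network_spec(sim_duration = 6, analysis_window = 5, ...)
}
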