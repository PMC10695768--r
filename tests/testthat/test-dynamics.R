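test_that("Poisson source trains have the right rate and ISI statistics", {
  expect_equal(nrow(generate_poisson_trains(5, 10, 0)), 0L)
  set.seed(21)
  tr <- generate_poisson_trains(100, 10, 50)
  # total count ~ Poisson(50,000): SE ~ 224
  expect_equal(nrow(tr), 50000, tolerance = 0.02)
  expect_true(all(diff(tr$time[tr$neuron_id == 1]) > 0))
  isi <- unlist(tapply(tr$time, tr$neuron_id, diff))
  expect_equal(sd(isi) / mean(isi), 1, tolerance = 0.03)
})

test_that("Bernoulli thinning keeps the right fraction and order", {
  train <- sort(runif(10000, 0, 100))
  expect_identical(thin_train(train, 1), train)
  expect_length(thin_train(train, 0), 0)
  set.seed(31)
  kept <- thin_train(train, 0.3)
  expect_false(is.unsorted(kept))
  expect_equal(length(kept) / length(train), 0.3, tolerance = 0.05)
  expect_error(thin_train(train, 1.5), class = "msbnet_config_error")
})

test_that("synaptic resource trace matches hand-evaluated first events", {
  tr <- stp_event_trace(c(0.1), stp_facilitating())
  expect_equal(tr$events$u, 0.03)
  expect_equal(tr$events$release, 0.03)
  expect_equal(tr$events$psc_peak, 1540 * 0.03)  # 46.2 pA

  # depressing synapse recovers fully between widely spaced spikes
  tr2 <- stp_event_trace(c(1, 50, 100), stp_depressing())
  expect_equal(tr2$events$release, rep(0.5, 3), tolerance = 1e-6)

  expect_error(stp_event_trace(c(2, 1), stp_facilitating()),
               class = "msbnet_input_error")
})

test_that("closed-form state evolution agrees with brute-force integration", {
  set.seed(41)
  times <- sort(runif(30, 0, 2))
  for (params in list(stp_facilitating(), stp_depressing())) {
    trace <- stp_event_trace(times, params)
    oracle <- euler_stp(times, params, dt_ms = 0.002)
    expect_equal(trace$events$release, oracle$releases, tolerance = 1e-3)
    n <- length(times)
    expect_equal(trace$events$x[n], oracle$x, tolerance = 1e-3)
    expect_equal(trace$events$u[n], oracle$u, tolerance = 1e-3)
  }
})

test_that("resources are conserved and the periodic steady state is reached", {
  set.seed(42)
  times <- cumsum(rexp(2000, 10))
  for (params in list(stp_facilitating(), stp_depressing())) {
    tr <- stp_event_trace(times, params,
                          sample_times = sort(runif(200, 0, max(times))))
    expect_true(all(abs(tr$events$x + tr$events$y + tr$events$z - 1) < 1e-9))
    expect_true(all(abs(tr$samples$x + tr$samples$y + tr$samples$z - 1) < 1e-9))
    expect_true(all(tr$events$u >= 0 & tr$events$u <= 1))

    # periodic drive converges to the analytic fixed point
    per <- stp_event_trace((1:500) * 0.1, params)
    fp <- stp_fixed_point(params, 100)
    expect_equal(per$events$u[500], fp$u_star, tolerance = 1e-6)
    # x* ignores the finite PSC decay time; agreement to O(tau_syn/tau_rec)
    expect_equal(per$events$release[500], fp$u_star * fp$x_star,
                 tolerance = 0.01)
  }
})

test_that("a quiet network stays quiet and decays to rest", {
  spec <- network_spec(n_ca1 = 3, n_ca3 = 1, boutons_per_neuron = 1,
                       boutons_so = 1, boutons_sr = 0, sim_duration = 1,
                       analysis_window = 0.5)
  g <- build_connectivity(spec, "ssb_all")
  silent <- make_trains(integer(0), numeric(0), 1, 1)
  ca1 <- simulate_ca1(g, silent, noise = noise_params(mu_b = 0, sigma_b = 0),
                      record = 1)
  expect_equal(nrow(ca1), 0L)
  expect_true(all(abs(attr(ca1, "v_trace")) < 1e-12))
})

test_that("constant-current firing matches the closed-form LIF period", {
  spec <- network_spec(n_ca1 = 1, n_ca3 = 1, boutons_per_neuron = 1,
                       boutons_so = 1, boutons_sr = 0, sim_duration = 5,
                       analysis_window = 1)
  g <- build_connectivity(spec, "ssb_all")
  silent <- make_trains(integer(0), numeric(0), 1, 5)
  for (current in c(25, 30, 40)) {
    ca1 <- simulate_ca1(g, silent,
                        noise = noise_params(mu_b = current, sigma_b = 0))
    periods <- diff(ca1$time) * 1000
    t_theory <- 2 + 60 * log((current - 10) / (current - 20))
    expect_true(all(abs(periods - t_theory) <= 0.1 + 1e-9))
  }
})

test_that("a single transmitted spike injects the analytic exponential PSC", {
  spec <- network_spec(n_ca1 = 1, n_ca3 = 1, boutons_per_neuron = 1,
                       boutons_so = 1, boutons_sr = 0, sim_duration = 0.1,
                       analysis_window = 0.05)
  g <- build_connectivity(spec, "ssb_all")
  tr <- make_trains(1L, 0.01, 1, 0.1)
  ca1 <- simulate_ca1(g, tr, noise = noise_params(mu_b = 0, sigma_b = 0),
                      record = 1)
  it <- attr(ca1, "i_trace")
  s0 <- round((0.01 * 1000 + 1) / 0.1)   # arrival step (1 ms delay)
  k <- 0:100
  analytic <- 200 * exp(-((k + 1) * 0.1) / 1.5)
  expect_equal(it[s0 + 1 + k], analytic, tolerance = 1e-12)
  expect_true(all(it[seq_len(s0 - 1)] == 0))
})

test_that("firing rate can never exceed the refractory bound", {
  spec <- network_spec(n_ca1 = 2, n_ca3 = 1, boutons_per_neuron = 1,
                       boutons_so = 1, boutons_sr = 0, sim_duration = 2,
                       analysis_window = 1)
  g <- build_connectivity(spec, "ssb_all")
  silent <- make_trains(integer(0), numeric(0), 1, 2)
  ca1 <- simulate_ca1(g, silent,
                      noise = noise_params(mu_b = 5000, sigma_b = 100))
  rate <- max(table(ca1$neuron_id)) / 2
  expect_lte(rate, 500)
})

test_that("simulation is bit-identical under the same seed", {
  spec <- small_spec()
  run_once <- function() {
    set.seed(77)
    g <- assign_stp_types(
      sample_release_probabilities(build_connectivity(spec, "msb_all")),
      "independent")
    tr <- generate_poisson_trains(spec$n_ca3, 10, spec$sim_duration)
    simulate_ca1(g, tr)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_gt(nrow(a), 0)
})

test_that("transmitted rate at an active zone is p times the source rate", {
  set.seed(55)
  train <- cumsum(rexp(5000, 10))  # ~500 s at 10 Hz
  kept <- thin_train(train, 0.3)
  rate <- length(kept) / max(train)
  expect_equal(rate, 3, tolerance = 0.07)
})

test_that("spike trains round-trip through TSV", {
  set.seed(9)
  tr <- generate_poisson_trains(5, 10, 2)
  path <- file.path(withr::local_tempdir(), "spikes.tsv")
  write_spike_trains(tr, path)
  tr2 <- read_spike_trains(path, 5, 2)
  expect_equal(tibble::as_tibble(tr2), tibble::as_tibble(tr))
})
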