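test_that("PSP kernel follows the closed form and its shape", {
  expect_identical(psp_kernel(0, 9), 0)
  expect_identical(psp_kernel(-3, 9), 0)
  expect_identical(psp_kernel(9, 9), 1)
  expect_equal(psp_kernel(4.5, 9), 0.5 * exp(0.5), tolerance = 1e-15)
  # strictly increasing on (0, tau], strictly decreasing after, max 1 at tau
  for (tau in c(2, 9, 17)) {
    up <- psp_kernel(seq(tau / 200, tau, length.out = 200), tau)
    down <- psp_kernel(seq(tau, 6 * tau, length.out = 200), tau)
    expect_true(all(diff(up) > 0))
    expect_true(all(diff(down) < 0))
    expect_equal(max(c(up, down)), 1)
    expect_true(all(c(up, down) >= 0 & c(up, down) <= 1))
  }
  expect_error(psp_kernel(1, tau = 0), "positive")
  expect_error(psp_kernel(1, tau = -2), "positive")
})

test_that("membrane potential is a linear sum of delayed PSPs", {
  expect_identical(membrane_potential(5, numeric(0), numeric(0), numeric(0)),
                   0)
  expect_equal(membrane_potential(10, 1, 2, 0.5, tau = 9),
               2 * psp_kernel(8.5, 9))
  # duplicating a synapse doubles the contribution (linearity)
  one <- membrane_potential(12, 1, 2, 0.5)
  two <- membrane_potential(12, c(1, 1), c(2, 2), c(0.5, 0.5))
  expect_equal(two, 2 * one)
  # linearity in the weight vector on random configurations
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    ts <- runif(n, 0, 9); d <- runif(n, 0, 5)
    w1 <- runif(n, -5, 5); w2 <- runif(n, -5, 5)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    t <- runif(1, 0, 20)
    expect_equal(membrane_potential(t, ts, a * w1 + b * w2, d),
                 a * membrane_potential(t, ts, w1, d) +
                   b * membrane_potential(t, ts, w2, d))
  }
  # non-firing presynaptic neurons (NA spike time) contribute nothing
  expect_equal(membrane_potential(10, c(1, NA), c(2, 50), c(0.5, 0.1)),
               membrane_potential(10, 1, 2, 0.5))
  expect_error(membrane_potential(1, 1, 1, -0.5), "non-negative")
})

test_that("first spike time is the earliest grid threshold crossing", {
  p <- srm_params(tau = 9, theta = 1, t_end = 20, dt = 0.01)
  # unit weight: kernel peaks at exactly theta = 1 at t_i + tau
  expect_equal(first_spike_time(0, 1, 0, p), 9)
  expect_true(is.na(first_spike_time(0, 0, 0, p)))       # zero weight
  expect_true(is.na(first_spike_time(0, -5, 0, p)))      # inhibitory only
  expect_true(is.na(first_spike_time(0, 0.999, 0, p)))   # just subthreshold
  # agrees with a 10x-finer brute-force oracle within one dt
  set.seed(42)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    ts <- runif(n, 0, 9)
    w <- runif(n, -3, 6)
    d <- runif(n, 0.01, 10)
    got <- first_spike_time(ts, w, d, p)
    ref <- oracle_first_spike(ts, w, d, p$tau, p$theta, 0, p$t_end,
                              p$dt / 10)
    if (is.na(ref)) expect_true(is.na(got))
    else expect_lte(abs(got - ref), p$dt)
  }
})

test_that("stronger excitation never delays a single-synapse spike", {
  p <- srm_params(t_end = 20)
  set.seed(7)
  w <- sort(runif(30, 1, 50))
  times <- sapply(w, function(wi) first_spike_time(0.5, wi, 0.2, p))
  expect_true(all(diff(times) <= 0))
})

test_that("network simulation composes per-neuron spike searches", {
  p <- srm_params(tau = 9, theta = 1, t_end = 20, dt = 0.01,
                  decision_start = 10)
  top <- snn_topology(1, list(list(presyn = 0L, weight = 2, delay = 0.5,
                                   out_weight = 2, out_delay = 1)))
  sim <- simulate_network(top, 0.01, p)
  h_ref <- first_spike_time(0.01, 2, 0.5, p, search_from = 0)
  o_ref <- first_spike_time(h_ref, 2, 1, p, search_from = p$decision_start)
  expect_equal(sim$hidden, h_ref)
  expect_equal(sim$output, o_ref)
  # all-zero weights: output never fires
  z <- snn_topology(1, list(list(presyn = 0L, weight = 0, delay = 0.5,
                                 out_weight = 0, out_delay = 1)))
  expect_true(is.na(simulate_network(z, 0.01, p)$output))
  # silent hidden neurons contribute no PSP to the output
  mixed <- snn_topology(1, list(
    list(presyn = 0L, weight = 2, delay = 0.5, out_weight = 2, out_delay = 1),
    list(presyn = 0L, weight = -1, delay = 0.5, out_weight = 500,
         out_delay = 0.1)))
  expect_equal(simulate_network(mixed, 0.01, p)$output, sim$output)
  # purity: identical inputs give bit-identical outputs
  expect_identical(simulate_network(top, 0.01, p),
                   simulate_network(top, 0.01, p))
  expect_error(simulate_network(top, c(1, 2), p), "dimensionality")
})

test_that("output spikes are only admitted from the decision start", {
  p <- srm_params(t_end = 20, decision_start = 10)
  # an output that would cross early is read out no earlier than 10 ms
  top <- snn_topology(1, list(list(presyn = 0L, weight = 900, delay = 0.01,
                                   out_weight = 900, out_delay = 0.01)))
  out <- simulate_network(top, 0.01, p)$output
  expect_gte(out, 10)
})
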