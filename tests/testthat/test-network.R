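exc_params <- function() ktz_params(K = 0.6, T = 0.35, delta = 0.001,
                                    lambda = 0.001, xR = -0.5)
bs_params <- function() ktz_params(K = 0.6, T = 0.3, delta = 0.001,
                                   lambda = 0.001, xR = -0.2)

test_that("gap-junction currents are antisymmetric and vanish when equal", {
  cfgp <- network_config(2, "pair_undirected", G = 0.1, params = exc_params())
  x <- c(0.3, -0.7)
  I <- gap_currents(x, cfgp)
  expect_identical(I[1], -I[2])
  expect_identical(I[1], 0.1 * (x[2] - x[1]))
  cfgc <- network_config(5, "complete", G = 0.2, params = exc_params())
  expect_equal(sum(gap_currents(runif(5, -1, 1), cfgc)), 0,
               tolerance = 1e-15)
  expect_identical(gap_currents(rep(0.4, 5), cfgc), rep(0, 5))
  # directed chain: i feeds i+1 only, N-1 synapses
  Ic <- gap_currents(c(1, 0, 0), network_config(3, "chain_directed", G = 1,
                                                params = exc_params()))
  expect_identical(Ic, c(0, 1, 0))
})

test_that("compiled network step matches the R reference step", {
  set.seed(3)
  init <- cbind(runif(6, -1, 1), runif(6, -1, 1), runif(6, -0.1, 0.1))
  for (topo in c("chain_directed", "complete")) {
    cfg <- network_config(6, topo, G = 0.07, params = bs_params(),
                          init = init)
    run <- simulate_network(cfg, n_steps = 2)
    ref <- step_network(init, cfg)
    expect_equal(unname(run$x[2, ]), unname(ref[, 1]), tolerance = 1e-14)
  }
})

test_that("the synchronized manifold is exactly invariant", {
  init <- matrix(rep(c(0.3, -0.2, 0.01), each = 8), nrow = 8)
  cfg <- network_config(8, "complete", G = 0.2, params = bs_params(),
                        init = init)
  run <- simulate_network(cfg, n_steps = 500)
  expect_true(all(run$x == run$x[, 1]))
  expect_identical(synchrony_order(run)$order, 1)
})

test_that("activity propagates along a chain above the conductance threshold", {
  cfg <- network_config(20, "chain_directed", G = 0.25, params = exc_params())
  run <- simulate_network(cfg, n_steps = 2e4, kick = stim_delta(1, 0))
  sp_last <- detect_spikes(run$x[, 20])
  expect_gt(length(sp_last), 0)
  # no coupling, no propagation
  cfg0 <- network_config(20, "chain_directed", G = 0, params = exc_params())
  run0 <- simulate_network(cfg0, n_steps = 2e4, kick = stim_delta(1, 0))
  expect_identical(detect_spikes(run0$x[, 20]), integer(0))
  # propagation speed is constant along the chain after the first few units:
  # total crossing time matches the per-synapse median lag (small jitter ok)
  first_spike <- apply(run$x[, 5:20], 2, function(v) detect_spikes(v)[1])
  lags <- diff(first_spike)
  expect_lt(abs((first_spike[16] - first_spike[1]) - 15 * median(lags)), 10)
  expect_lte(median(lags), 3)
})

test_that("the propagation threshold brackets and is size-independent", {
  cfg20 <- network_config(20, "chain_directed", G = 0.1,
                          params = exc_params())
  th20 <- find_propagation_threshold(cfg20, c(0.15, 0.3),
                                     kick = stim_delta(1, 0),
                                     horizon = 3e4, tol = 1e-6)
  expect_lt(diff(th20$bracket), 1.0000001e-6)
  cfg50 <- network_config(50, "chain_directed", G = 0.1,
                          params = exc_params())
  th50 <- find_propagation_threshold(cfg50, c(0.15, 0.3),
                                     kick = stim_delta(1, 0),
                                     horizon = 5e4, tol = 1e-6)
  expect_lt(abs(th50$threshold_G - th20$threshold_G) / th20$threshold_G,
            0.01)
  expect_error(find_propagation_threshold(cfg20, c(0.3, 0.5),
                                          kick = stim_delta(1, 0)),
               "already propagates")
})

test_that("bursting units on a complete graph synchronize; uncoupled do not", {
  cfg <- network_config(10, "complete", G = 0.01, params = bs_params(),
                        init = "random", seed = 42)
  run <- simulate_network(cfg, n_steps = 2e4, discard = 3e4)
  expect_gt(synchrony_order(run)$order, 0.95)
  cfg0 <- network_config(10, "complete", G = 0, params = bs_params(),
                         init = "random", seed = 42)
  run0 <- simulate_network(cfg0, n_steps = 2e4, discard = 3e4)
  expect_lt(synchrony_order(run0)$order, 0.5)
  # recorded seed makes random initial conditions reproducible
  run0b <- simulate_network(cfg0, n_steps = 10, discard = 0)
  run0c <- simulate_network(cfg0, n_steps = 10, discard = 0)
  expect_identical(run0b$x, run0c$x)
})
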