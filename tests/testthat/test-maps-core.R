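test_that("logistic gain and its derivative match their closed forms", {
  expect_identical(logistic_gain(0), 0)
  expect_identical(logistic_gain(1), 0.5)
  expect_identical(logistic_gain(-3), -0.75)
  expect_true(all(abs(logistic_gain(seq(-50, 50, by = 0.37))) < 1))
  # odd and strictly increasing
  u <- seq(-5, 5, by = 0.01)
  expect_equal(logistic_gain(-u), -logistic_gain(u))
  expect_true(all(diff(logistic_gain(u)) > 0))
  expect_identical(gain_derivative(0), 1)
  expect_identical(gain_derivative(1), 0.25)
  # central finite-difference oracle at u = 0.37
  h <- 1e-6
  fd <- (logistic_gain(0.37 + h) - logistic_gain(0.37 - h)) / (2 * h)
  expect_equal(gain_derivative(0.37), fd, tolerance = 1e-6)
  expect_error(logistic_gain(Inf), "finite")
  expect_error(gain_derivative(NaN), "finite")
})

test_that("one map step follows the synchronous update exactly", {
  p <- ktz_params(K = 0.6, T = 0.35)
  s <- ktz_step(ktz_state(1, 1, 0), p)
  # u = (1 - 0.6)/0.35 = 8/7, f(8/7) = 8/15
  expect_equal(s[["x"]], 8 / 15)
  expect_identical(s[["y"]], 1)
  expect_identical(s[["z"]], 0)
  # origin is a fixed point when H = 0
  s0 <- ktz_step(ktz_state(0, 0, 0), ktz_params(K = 0.7, T = 0.2))
  expect_identical(as.numeric(s0), c(0, 0, 0))
  # slow-current update: z' = (1-delta) z - lambda (x - xR)
  p2 <- p_case2(T = 0.35, xR = -0.5)
  s2 <- ktz_step(ktz_state(0, 0, 0), p2)
  expect_equal(s2[["z"]], -0.001 * (0 - (-0.5)))  # = -5e-4
  expect_equal(s2[["z"]], -5e-4)
  expect_error(ktz_step(ktz_state(0, 0, 0), p, I = NA), "finite")
})

test_that("compiled simulation matches the R step and is deterministic", {
  p <- p_case2(T = 0.26, xR = -0.2)
  init <- ktz_state(0.3, -0.1, 0.05)
  tr <- simulate_ktz(p, init, n_steps = 200)
  s <- init
  for (t in 1:200) {
    expect_equal(unname(tr$states[t, ]), as.numeric(s), tolerance = 0)
    s <- ktz_step(s, p)
  }
  tr2 <- simulate_ktz(p, init, n_steps = 200)
  expect_identical(tr$states, tr2$states)
})

test_that("trajectories are bounded, y lags x by one step, FPs persist", {
  tr <- simulate_ktz(p_chaosB(), ktz_state(1, 1), n_steps = 5e4)
  x <- tr$states[, "x"]
  expect_true(all(abs(x[-1]) < 1))  # gain range is open (-1, 1) for t >= 1
  expect_identical(tr$states[-1, "y"], x[-length(x)])
  # a stable fixed point stays put
  p <- ktz_params(K = 0.6, T = 0.7)
  trf <- simulate_ktz(p, ktz_state(0, 0, 0), n_steps = 100)
  expect_true(all(trf$states == 0))
})

test_that("dynamics are odd under the (H, xR, state) sign flip", {
  for (case in 1:2) {
    p <- if (case == 1) ktz_params(K = 0.6, T = 0.3, H = 0.02)
      else p_case2(T = 0.26, xR = -0.2)
    pm <- ktz_params(K = p$K, T = p$T, H = -p$H, delta = p$delta,
                     lambda = p$lambda, xR = -p$xR)
    init <- ktz_state(0.4, -0.2, 0.01)
    a <- simulate_ktz(p, init, n_steps = 500)
    b <- simulate_ktz(pm, ktz_state(-0.4, 0.2, -0.01), n_steps = 500)
    expect_identical(a$states, -b$states)
  }
})

test_that("logistic and tanh gains agree to second order for small inputs", {
  # both gains have unit slope at the origin; the logistic gain departs at
  # second order (its expansion is u - u|u| + ..., the tanh's u - u^3/3)
  u <- seq(-0.01, 0.01, length.out = 41)
  expect_lt(max(abs(logistic_gain(u) - tanh(u))), 1.1 * max(abs(u))^2)
  expect_lt(max(abs(logistic_gain(u) - u)), 1.1 * max(abs(u))^2)
  # tanh option runs the same step contract
  p <- ktz_params(K = 0.6, T = 0.35, gain = "tanh")
  s <- ktz_step(ktz_state(1, 1, 0), p)
  expect_equal(s[["x"]], tanh(8 / 7))
  # overflow guard: huge argument stays finite
  p2 <- ktz_params(K = 0.6, T = 1e-8, gain = "tanh")
  expect_true(is.finite(ktz_step(ktz_state(1, -1, 0), p2)[["x"]]))
})

test_that("stimulus protocols materialise as specified", {
  expect_identical(stim_as_series(stim_none(), 10), numeric(0))
  s <- stim_as_series(stim_delta(0.5, 3), 6)
  expect_identical(s, c(0, 0, 0, 0.5, 0, 0))
  s <- stim_as_series(stim_dc(-0.2, 2, 4), 6)
  expect_identical(s, c(0, 0, -0.2, -0.2, 0, 0))
  s <- stim_as_series(stim_pulse_train(1, 0, 10, period = 4, width = 2), 8)
  expect_identical(s, c(1, 1, 0, 0, 1, 1, 0, 0))
  s <- stim_as_series(stim_ramp(0.1, 2, 5), 6)
  expect_equal(s, c(0, 0, 0, 0.1, 0.2, 0))
  expect_error(stim_as_series(stim_series(1:3), 10), "cyclic")
  expect_identical(stim_as_series(stim_series(1:3, cyclic = TRUE), 5),
                   c(1, 2, 3, 1, 2))
})
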