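test_that("stable-FP Lyapunov estimates match the analytic contraction rate", {
  # criterion: at a stable FP the exponent equals ln max|Lambda|
  p <- ktz_params(K = 0.6, T = 0.7)
  lam_ref <- log(max(Mod(eigenvalues_case1(0, p))))  # = log(sqrt(K/T)) < 0
  dv <- lyapunov_divergence(p, ktz_state(0.01, 0.01), horizon = 2000)
  expect_true(dv$shrinking)
  expect_lt(abs(dv$lambda_max - lam_ref) / abs(lam_ref), 0.05)
  er <- lyapunov_eckmann_ruelle(p, ktz_state(0, 0), n_steps = 1e6,
                                discard = 0)
  expect_lt(max(abs(er$spectrum - log(Mod(eigenvalues_case1(0, p))))),
            1e-6)
})

test_that("divergence and tangent-space exponents agree on chaotic orbits", {
  dv <- lyapunov_divergence(p_chaosB(), ktz_state(1, 1))
  er <- lyapunov_eckmann_ruelle(p_chaosB(), ktz_state(1, 1),
                                n_steps = 5e5, discard = 1e5)
  expect_gt(er$lambda_max, 0)
  expect_lt(abs(dv$lambda_max - er$lambda_max), 0.02)
  # spectrum sum equals the orbit average of ln|det J| (= ln(KT/p^2))
  p <- p_chaosB()
  tr <- simulate_ktz(p, ktz_state(1, 1), n_steps = 1e4, discard = 1e5)
  u <- (tr$states[, "x"] - p$K * tr$states[, "y"] + p$H) / p$T
  mean_logdet <- mean(log(p$K * gain_derivative(u) / p$T))
  er2 <- lyapunov_eckmann_ruelle(p, ktz_state(1, 1), n_steps = 1e4,
                                 discard = 1e5)
  expect_equal(sum(er2$spectrum), mean_logdet, tolerance = 1e-8)
})

test_that("periodic orbits have non-positive exponents from the cycle product", {
  # 5-cycle window of the slow model: lambda_max = (1/Q) ln(spectral radius)
  p5 <- ktz_params(K = 1.5, T = 0.2, delta = 0.001, lambda = 0.001,
                   xR = -0.5)
  er <- lyapunov_eckmann_ruelle(p5, ktz_state(0.5, 0.5, 0),
                                n_steps = 1e5, discard = 2e5)
  expect_true(all(er$spectrum <= 1e-6))
  # direct product over one period as oracle
  tr <- simulate_ktz(p5, ktz_state(0.5, 0.5, 0), n_steps = 5, discard = 2e5)
  J <- diag(3)
  for (t in 1:5) {
    s <- tr$states[t, ]
    a <- gain_derivative((s[1] - p5$K * s[2] + s[3]) / p5$T) / p5$T
    Jt <- rbind(c(a, -p5$K * a, a), c(1, 0, 0),
                c(-p5$lambda, 0, 1 - p5$delta))
    J <- Jt %*% J
  }
  lam_ref <- log(max(Mod(eigen(J)$values))) / 5
  expect_lt(abs(er$lambda_max - lam_ref), 1e-4)
})

test_that("box-counting dimension: finite sets, curves, degenerate input", {
  # a finite point set has dimension 0
  pts <- matrix(rep(c(0.1, -0.3, 0.5, 0.2, -0.6, 0.4), 500),
                ncol = 2, byrow = TRUE)
  expect_lt(abs(suppressWarnings(capacity_dimension(pts))$dimension), 0.05)
  # a smooth closed curve has dimension 1
  th <- seq(0, 2 * pi, length.out = 2e5)
  circ <- cbind(cos(th), sin(th))
  cd <- capacity_dimension(circ)
  expect_equal(cd$dimension, 1, tolerance = 0.05)
  expect_true(capacity_dimension(circ[1:100, ])$low_count)
})

test_that("Kaplan-Yorke dimension follows the interpolation formula", {
  expect_identical(lyapunov_dimension(c(-0.1, -0.5)), 0)
  expect_equal(lyapunov_dimension(c(0.1258, -0.796)), 1 + 0.1258 / 0.796)
  expect_equal(lyapunov_dimension(c(0.1258, -0.796)), 1.158, tolerance = 1e-3)
  expect_identical(lyapunov_dimension(c(0.2, 0.1)), 2)  # no contraction left
  expect_equal(lyapunov_dimension(c(0.3, -0.1, -0.5)), 2 + 0.2 / 0.5)
})

test_that("power-law fitting recovers an exact law and rejects thin data", {
  d <- 10^seq(-3, -1, length.out = 10)
  pw <- suppressWarnings(ktzlog:::power_law_fit(d, 3 * d^(-0.5)))
  expect_equal(pw$exponent, -0.5, tolerance = 1e-10)
  expect_lt(pw$stderr, 1e-10)
  p <- p_case2(0.2, -0.3)
  expect_error(
    fit_scaling(p, "xR", -0.4, "mean_ISI", values = -0.4 + c(0.05, 0.06),
                config = classifier_config(transient = 1e3, window = 1e4)),
    "8 valid points")
})

test_that("bisection locates transitions and rejects bad brackets", {
  cfg <- classifier_config(transient = 1e5, window = 5e5)
  # blue-sky point of the bursting slice
  b <- locate_bifurcation(p_case2(0.275, -0.2), "xR", c(-0.12, -0.05),
                          "burst_duration_divergence", cfg, tol = 1e-5)
  expect_lt(abs(b$critical_value - (-0.072)), 0.005)
  expect_error(
    locate_bifurcation(p_case2(0.275, -0.2), "xR", c(-0.2, -0.15),
                       "burst_duration_divergence", cfg),
    "straddle")
})

test_that("burst statistics split trains at the interburst gap", {
  sp <- c(10, 20, 30, 500, 510, 520, 1000, 1010, 1020, 1500)
  bd <- ktzlog:::burst_durations(sp, gap = 100)
  expect_identical(bd, c(20, 20))  # interior bursts only
  expect_identical(ktzlog:::burst_durations(c(1, 2), 100), numeric(0))
})
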