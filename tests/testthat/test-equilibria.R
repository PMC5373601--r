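test_that("case-I fixed points match closed form and the scan oracle", {
  fps <- fixed_points_case1(ktz_params(K = 0.6, T = 0.3))
  xs <- vapply(fps, `[[`, numeric(1), "x_star")
  expect_equal(xs, c(-0.25, 0, 0.25))
  # only the origin survives at larger T (branch sign condition)
  fps2 <- fixed_points_case1(ktz_params(K = 0.6, T = 0.7))
  expect_equal(vapply(fps2, `[[`, numeric(1), "x_star"), 0)
  # scan oracle agreement on a few parameter sets, including H != 0
  for (par in list(ktz_params(K = 0.6, T = 0.3), ktz_params(K = 0.6, T = 0.7),
                   ktz_params(K = 0.3, T = 0.4), ktz_params(K = 1.5, T = 0.2),
                   ktz_params(K = 0.6, T = 0.12, H = -0.05),
                   ktz_params(K = 1, T = 0.3, H = 0.1))) {
    got <- sort(vapply(fixed_points_case1(par), `[[`, numeric(1), "x_star"))
    want <- fp_scan_oracle(par)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("fixed points satisfy the map identity and odd symmetry", {
  for (par in list(ktz_params(K = 0.6, T = 0.3),
                   ktz_params(K = 0.6, T = 0.12, H = -0.05))) {
    for (r in fixed_points_case1(par)) expect_lt(r$residual, 1e-12)
  }
  # H = 0 set symmetric under x* -> -x*
  xs <- vapply(fixed_points_case1(ktz_params(K = 0.8, T = 0.1)),
               `[[`, numeric(1), "x_star")
  expect_equal(sort(xs), sort(-xs))
})

test_that("case-I eigenvalues solve their quadratic; NS line is marginal", {
  p <- ktz_params(K = 0.7, T = 0.7)   # T = K, K > 0.5
  ev <- eigenvalues_case1(0, p)
  expect_equal(Mod(ev), c(1, 1), tolerance = 1e-12)
  # characteristic-polynomial residual
  for (par in list(ktz_params(K = 0.6, T = 0.3), ktz_params(K = 1.5, T = 0.2))) {
    for (r in fixed_points_case1(par)) {
      pp <- r$p
      res <- r$eigenvalues^2 - (par$T / pp^2) * r$eigenvalues +
        par$K * par$T / pp^2
      expect_lt(max(Mod(res)), 1e-10)
    }
  }
  # stable above the NS line
  ev2 <- eigenvalues_case1(0, ktz_params(K = 0.6, T = 0.7))
  expect_lt(max(Mod(ev2)), 1)
})

test_that("case-II fixed points match the contraction-map oracle", {
  p <- p_case2(T = 0.35, xR = -0.5)
  fps <- fixed_points_case2(p)
  expect_length(fps, 1)
  # alpha = 1 makes z* = xR - x*, so x* solves x = f((xR - K x)/T)
  x <- 0
  for (i in 1:500) x <- logistic_gain((p$xR - p$K * x) / p$T)
  expect_equal(fps[[1]]$x_star, x, tolerance = 1e-10)
  expect_equal(fps[[1]]$z_star, p$xR - fps[[1]]$x_star, tolerance = 1e-12)
  expect_lt(fps[[1]]$residual, 1e-12)
  # xR = 0 keeps the origin
  fps0 <- fixed_points_case2(p_case2(T = 0.35, xR = 0))
  expect_true(any(vapply(fps0, `[[`, numeric(1), "x_star") == 0))
  # xR -> -xR negates the set
  a <- vapply(fixed_points_case2(p_case2(T = 0.3, xR = -0.4)),
              `[[`, numeric(1), "x_star")
  b <- vapply(fixed_points_case2(p_case2(T = 0.3, xR = 0.4)),
              `[[`, numeric(1), "x_star")
  expect_equal(sort(a), sort(-b), tolerance = 1e-12)
  # quadratic-formula closed form agrees with the solver roots
  cf <- fixed_points_case2_closed_form(p)
  expect_true(min(abs(cf$x - fps[[1]]$x_star), na.rm = TRUE) < 1e-10)
  expect_error(fixed_points_case2(
    ktz_params(K = 0.6, T = 0.3, delta = 0, lambda = 0.001, xR = -0.2)),
    "alpha")
})

test_that("case-II eigenvalues: residuals, closed form, case-I limit", {
  p <- p_case2(T = 0.3, xR = -0.4)
  fp <- fixed_points_case2(p)[[1]]
  e <- eigenvalues_case2(fp$x_star, fp$z_star, p)
  # each root satisfies the cubic to 1e-10
  pp <- p$T + abs((1 - p$K) * fp$x_star + fp$z_star)
  res <- pp^2 * e$values^3 - (p$T + (1 - p$delta) * pp^2) * e$values^2 +
    p$T * (p$K + p$lambda + 1 - p$delta) * e$values -
    p$K * p$T * (1 - p$delta)
  expect_lt(max(Mod(res)), 1e-10)
  # closed form vs numeric roots
  expect_lt(e$detail$cross_error, 1e-8)
  # delta = lambda = 0 limit: {1} + case-I pair
  p0 <- ktz_params(K = 0.6, T = 0.3)
  e0 <- eigenvalues_case2(0.25, 0, p0)
  ref <- c(1 + 0i, eigenvalues_case1(0.25, p0))
  expect_equal(sort(Mod(e0$values)), sort(Mod(ref)), tolerance = 1e-10)
  expect_lt(min(Mod(e0$values - 1)), 1e-10)
})

test_that("analytic stability limits intersect and vanish as derived", {
  bc <- boundary_curves_case1(c(0.5, 0.75, 1))
  at05 <- bc[bc$K == 0.5, ]
  expect_equal(at05$T, rep(0.5, nrow(at05)))
  expect_setequal(at05$kind, c("pitchfork", "NS_super", "NS_sub"))
  expect_equal(bc$T[bc$K == 1 & bc$kind == "NS_sub"], 0)
  # T-H limit curves: H = 0 at T = K and at T = (1-K)^2/K for K >= 0.5
  th <- boundary_curves_TH(0.6, c((1 - 0.6)^2 / 0.6, 0.6))
  expect_true(all(abs(th$H) < 1e-12))
  # the nonzero-x* zero-H point reproduces the 2FP branch value
  x2 <- th$x_star[abs(th$T - (1 - 0.6)^2 / 0.6) < 1e-9]
  expect_equal(sort(x2), c(-1 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("quasi-static boundary is +-(K-T) and matches slow-z onset", {
  expect_equal(quasistatic_boundary(0.6, 0.2), c(-0.4, 0.4))
  expect_equal(quasistatic_boundary(0.5, 0.5), c(0, 0))
  pq <- ktz_params(K = 0.6, T = 0.2, delta = 1e-4, lambda = 1e-4)
  b <- locate_bifurcation(pq, "xR", c(-0.42, -0.38), "spike_onset",
                          classifier_config(transient = 2e5, window = 5e5),
                          tol = 1e-4)
  expect_lt(abs(b$critical_value - (-0.4)), 0.01)
})

test_that("stability classification agrees with simulation", {
  p_stable <- ktz_params(K = 0.6, T = 0.7)
  p_unstable <- ktz_params(K = 0.6, T = 0.3)
  fs <- fixed_points_case1(p_stable)[[1]]
  expect_identical(fs$stability, "stable")
  fu <- Filter(function(r) r$x_star == 0, fixed_points_case1(p_unstable))[[1]]
  # inside the oscillatory region the origin is non-attracting (its real
  # spectrum straddles 1, so it is a saddle in the modulus convention)
  expect_true(fu$stability %in% c("unstable", "saddle"))
  # the origin between two stable FPs is a saddle (real spectrum straddling 1)
  f0 <- Filter(function(r) r$x_star == 0,
               fixed_points_case1(ktz_params(K = 0.6, T = 0.25)))[[1]]
  expect_identical(f0$stability, "saddle")
  # simulation verification contract
  cs <- classify_stability(fs$eigenvalues,
                           simulate_check = list(params = p_stable, fp = fs))
  expect_true(cs$sim_agrees)
  cu <- classify_stability(fu$eigenvalues,
                           simulate_check = list(params = p_unstable,
                                                 fp = fu))
  expect_true(cu$sim_agrees)
  # marginal case flagged on the NS line
  evm <- eigenvalues_case1(0, ktz_params(K = 0.7, T = 0.7))
  expect_true(classify_stability(evm)$marginal)
  expect_identical(classify_stability(c(0 + 0i, 0 + 0i))$stability, "stable")
})
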