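test_that("spike detection, amplitude and ISI statistics behave", {
  expect_identical(detect_spikes(rep(0.5, 100)), integer(0))
  expect_identical(amplitude(rep(0.5, 100)), 0)
  # synthetic sawtooth with period 20: every ISI equals 20
  x <- rep(c(rep(-0.5, 10), rep(0.5, 10)), 10)
  sp <- detect_spikes(x)
  expect_true(all(diff(sp) == 20))
  # hysteresis: ripple inside the dead band does not retrigger
  x2 <- c(-0.5, 0.5, -0.05, 0.5, -0.5, 0.5)
  expect_identical(detect_spikes(x2), c(2L, 6L))
  # bounded amplitude for any run
  tr <- simulate_ktz(p_chaosB(), ktz_state(1, 1), n_steps = 1e4)
  expect_lt(amplitude(tr), 2)
})

test_that("regime labels match the known points of the parameter plane", {
  cfg <- classifier_config(transient = 5e4, window = 2e5, cv_th = 0.005)
  lab_at <- function(T, xR) {
    tr <- simulate_ktz(p_case2(T, xR), ktz_state(0.5, 0.5, 0),
                       n_steps = cfg$window, discard = cfg$transient)
    as.character(classify_phase(tr, cfg))
  }
  expect_identical(lab_at(0.2, -0.5), "FP")       # beyond the FP boundary
  expect_identical(lab_at(0.2, -0.2), "CS")       # regular cardiac spiking
  expect_identical(lab_at(0.26, -0.2), "BS")      # bursting wedge
  expect_identical(lab_at(0.5, -0.05), "FS")      # fast spiking
  expect_identical(lab_at(0.2, -0.395), "ACS")    # aperiodic cardiac band
  expect_identical(lab_at(0.57, -0.028), "SO")    # subthreshold sliver
  # no spikes and zero amplitude is a fixed point
  s <- oscillation_summary(rep(0.1, 1000), cfg)
  expect_identical(as.character(classify_phase(s, cfg)), "FP")
})

test_that("classification is stable under doubling the window", {
  pts <- list(c(0.2, -0.2), c(0.26, -0.2), c(0.5, -0.05), c(0.2, -0.5))
  for (q in pts) {
    l1 <- l2 <- NULL
    cfg1 <- classifier_config(transient = 5e4, window = 2e5, cv_th = 0.005)
    cfg2 <- classifier_config(transient = 5e4, window = 4e5, cv_th = 0.005)
    tr1 <- simulate_ktz(p_case2(q[1], q[2]), ktz_state(0.5, 0.5, 0),
                        n_steps = cfg1$window, discard = cfg1$transient)
    tr2 <- simulate_ktz(p_case2(q[1], q[2]), ktz_state(0.5, 0.5, 0),
                        n_steps = cfg2$window, discard = cfg2$transient)
    expect_identical(as.character(classify_phase(tr1, cfg1)),
                     as.character(classify_phase(tr2, cfg2)))
  }
})

test_that("ISI statistics are invariant under the sign-flip symmetry", {
  cfg <- classifier_config(transient = 5e4, window = 1e5)
  a <- simulate_ktz(p_case2(0.26, -0.2), ktz_state(0.5, 0.5, 0),
                    n_steps = cfg$window, discard = cfg$transient)
  b <- simulate_ktz(p_case2(0.26, 0.2), ktz_state(-0.5, -0.5, 0),
                    n_steps = cfg$window, discard = cfg$transient)
  expect_equal(amplitude(a), amplitude(b), tolerance = 1e-12)
  # spikes of the flipped run from the flipped trace (downward crossings)
  sa <- detect_spikes(a$states[, "x"])
  sb <- detect_spikes(-b$states[, "x"])
  expect_identical(sa, sb)
})

test_that("compiled sweep summaries agree with the R classifier path", {
  cfg <- classifier_config(transient = 5e4, window = 2e5, cv_th = 0.005)
  pts <- data.frame(xR = c(-0.2, -0.2, -0.05, -0.5),
                    T = c(0.2, 0.26, 0.5, 0.2))
  d <- phase_diagram(p_case2(0.3, -0.2), c("xR", "T"),
                     range(pts$xR), range(pts$T), 2, 2, config = cfg)
  for (i in seq_len(nrow(d))) {
    tr <- simulate_ktz(p_case2(d$T[i], d$xR[i]), ktz_state(0.5, 0.5, 0),
                       n_steps = cfg$window, discard = cfg$transient)
    s <- oscillation_summary(tr, cfg)
    expect_equal(d$amplitude[i], s$amplitude_A, tolerance = 1e-12)
    if (s$n_isi > 1) {
      expect_equal(d$mean_isi[i], s$mean_isi, tolerance = 1e-12)
      expect_equal(d$var_isi[i], s$var_isi, tolerance = 1e-9)
    }
    expect_identical(d$label[i], as.character(classify_phase(s, cfg)))
  }
})

test_that("winding numbers: closed form, limits and measured estimates", {
  expect_identical(winding_number_analytic(0.5), 0)
  expect_equal(winding_number_analytic(1), 1 / 6)
  expect_equal(winding_number_analytic(1e9), 0.25, tolerance = 1e-8)
  expect_error(winding_number_analytic(0.4), "0.5")
  # property: measured winding matches the closed form on the NS line
  for (K in c(0.6, 0.7, 1.0, 1.6)) {
    p <- ktz_params(K = K, T = K - 1e-4)
    tr <- simulate_ktz(p, ktz_state(0.01, 0), n_steps = 2e4, discard = 1e5)
    w <- winding_number_measured(tr, maxQ = 50)
    expect_equal(w$w, winding_number_analytic(K), tolerance = 1e-3)
  }
  # exact rational for a periodic window: the 5-cycle of the slow model
  p5 <- ktz_params(K = 1.5, T = 0.2, delta = 0.001, lambda = 0.001,
                   xR = -0.5)
  tr5 <- simulate_ktz(p5, ktz_state(0.5, 0.5, 0), n_steps = 2000,
                      discard = 2e5)
  w5 <- winding_number_measured(tr5, maxQ = 40)
  expect_true(w5$exact)
  expect_identical(w5$Q, 5L)
  expect_error(winding_number_measured(
    simulate_ktz(ktz_params(K = 0.6, T = 0.7), ktz_state(0, 0),
                 n_steps = 100)), "non-oscillatory")
})
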