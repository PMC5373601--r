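## Lyapunov exponents, attractor dimensions, bifurcation location and
## power-law scaling fits near the infinite-period / blue-sky transitions.

#' Largest Lyapunov exponent by twin-trajectory divergence
#'
#' Iterates the map from `init` and from a copy perturbed by `perturbation`
#' in `x`, and fits `log(dx)` against `t` by least squares over the initial
#' divergence, i.e. from `t = 0` until `dx` first exceeds the `saturation`
#' guard (the separation of bounded trajectories saturates around 2, which
#' must be excluded from the fit).  The slope is the exponent per time
#' step.
#'
#' @param params a [ktz_params()].
#' @param init initial [ktz_state()].
#' @param perturbation initial separation, in `[1e-12, 1e-4]`
#'   (default 1e-8).
#' @param horizon maximum steps to follow (default 5000; in a chaotic
#'   regime saturation is reached long before).
#' @param saturation fit cut-off on `dx` (default 1e-2).
#' @return A list of class `ktz_lyapunov`: `method`, `lambda_max`,
#'   `fit_window`, `r_squared`, and `shrinking = TRUE` when the separation
#'   never grew (stable regime; the slope is then a contraction-rate fit).
#' @examples
#' \donttest{
#' p <- ktz_params(K = 0.89, T = 0.009)
#' lyapunov_divergence(p, ktz_state(1, 1))$lambda_max  # about 0.126
#' }
#' @export
lyapunov_divergence <- function(params, init, perturbation = 1e-8,
                                horizon = 5000, saturation = 1e-2) {
  stopifnot(perturbation >= 1e-12, perturbation <= 1e-4)
  dx <- twin_div_cpp(par_vec(params), gain_code(params), as.numeric(init),
                     perturbation, as.integer(horizon))
  t <- seq_along(dx) - 1L
  cut <- which(dx > saturation)[1]
  shrinking <- is.na(cut)
  last <- if (shrinking) length(dx) else cut - 1L
  use <- which(t <= t[last] & dx > 0)
  if (length(use) < 3) stop("divergence window too short to fit")
  fit <- stats::lm(log(dx[use]) ~ t[use])
  structure(list(method = "divergence_fit",
                 lambda_max = unname(stats::coef(fit)[2]),
                 fit_window = c(t[use][1], t[use][length(use)]),
                 r_squared = summary(fit)$r.squared,
                 shrinking = shrinking),
            class = "ktz_lyapunov")
}

#' Lyapunov spectrum by the Eckmann-Ruelle method
#'
#' Accumulates products of the analytic Jacobian of the map along the orbit
#' with periodic Gram-Schmidt re-orthonormalisation of the tangent frame
#' (the map is known, so no embedding/neighbour reconstruction is needed).
#' Returns the full spectrum: 2 exponents for the fast subsystem, 3 for the
#' full model, sorted descending.
#'
#' @param params a [ktz_params()].
#' @param init initial [ktz_state()].
#' @param n_steps orbit length used for the product (default 1e6).
#' @param discard transient steps before accumulating (default 1e5).
#' @param renorm_every steps between re-orthonormalisations (default 10).
#' @return A `ktz_lyapunov` list: `method`, `lambda_max`, `spectrum`
#'   (sorted descending), `n_steps`.
#' @export
lyapunov_eckmann_ruelle <- function(params, init = ktz_state(0.5, 0.5, 0),
                                    n_steps = 1e6, discard = 1e5,
                                    renorm_every = 10) {
  r <- lyap_er_cpp(par_vec(params), gain_code(params), as.numeric(init),
                   as.integer(n_steps), as.integer(discard),
                   as.integer(renorm_every))
  sp <- sort(r$exponents, decreasing = TRUE)
  structure(list(method = "eckmann_ruelle", lambda_max = sp[1],
                 spectrum = sp, n_steps = r$n_steps),
            class = "ktz_lyapunov")
}

#' @export
print.ktz_lyapunov <- function(x, ...) {
  cat(sprintf("Lyapunov estimate (%s): lambda_max = %.5g per ts\n",
              x$method, x$lambda_max))
  if (!is.null(x$spectrum))
    cat("  spectrum:", paste(sprintf("%.5g", x$spectrum), collapse = ", "),
        "\n")
  invisible(x)
}

#' Capacity (box-counting) dimension of a planar point set
#'
#' Counts occupied boxes of side `eps` (fractions of the attractor's
#' bounding box) over a geometric range of sizes and reports the slope of
#' `log N(eps)` against `log(1/eps)` with its standard error.
#'
#' @param points a two-column matrix of `(x, y)` points or a
#'   `ktz_trajectory` (its `(x, y)` states are used).  1e6 points or more
#'   are needed for the quoted uncertainties; fewer are allowed but the
#'   result is flagged.
#' @param eps box sides as fractions of the bounding box (default
#'   `2^-(4:12)`, geometric steps).
#' @return List of class `ktz_dimension`: `dimension`, `stderr`,
#'   `n_points`, `fit` data (`eps`, `N`), `low_count` flag.
#' @export
capacity_dimension <- function(points, eps = 2^-(4:12)) {
  if (inherits(points, "ktz_trajectory")) points <- points$states[, 1:2]
  stopifnot(is.matrix(points), ncol(points) >= 2)
  N <- box_count_cpp(points[, 1], points[, 2], eps)
  fit <- stats::lm(log(N) ~ log(1 / eps))
  sm <- summary(fit)
  structure(list(dimension = unname(stats::coef(fit)[2]),
                 stderr = sm$coefficients[2, 2],
                 n_points = nrow(points),
                 fit = data.frame(eps = eps, N = N),
                 low_count = nrow(points) < 1e6),
            class = "ktz_dimension")
}

#' Capacity dimension from a subdivision box cover of the attractor
#'
#' Box-counting an orbit sample under-covers a strongly multifractal
#' attractor: filaments carrying very little natural measure are visited too
#' rarely to register, so the orbit-sample slope approaches the capacity
#' dimension of the *set* only at astronomically many points.  This
#' estimator instead covers the attractor closure directly: starting from a
#' coarse orbit cover on a dyadic grid, it repeats (i) a selection sweep
#' `S <- image(S) /\ S` until stable — for this map the image cover of a
#' grid box is an exact cell interval, because the potential update is
#' monotone in `x` and `y` and the recovery update maps a box onto exactly
#' one grid row — and (ii) subdivision of every kept box into four children.
#' The per-level counts `N_m` converge from below to the capacity scaling of
#' the closure; the estimate is the local slope over the finest octave,
#' `log2(N_m1 / N_{m1-1})`.
#'
#' Only the 2-D fast subsystem (case I) is supported.
#'
#' @param params a case-I [ktz_params()].
#' @param init initial state for the seeding orbit.
#' @param m0,m1 coarsest and finest dyadic levels (box side `2^-m` of the
#'   fixed domain `[-1.02, 1.02]^2`); defaults 4 and 15.
#' @param n_orbit seeding orbit length (default 1e6).
#' @param discard transient before seeding (default 1e5).
#' @param max_sweeps selection-sweep cap per level (default 400).
#' @return A `ktz_dimension` list: `dimension` (finest-octave slope),
#'   `stderr` (half the difference of the last two local slopes, a
#'   convergence-gap indicator), `levels` (data frame `m`, `N`, local
#'   slopes).
#' @export
capacity_dimension_cover <- function(params, init = ktz_state(1, 1),
                                     m0 = 4, m1 = 15, n_orbit = 1e6,
                                     discard = 1e5, max_sweeps = 400) {
  stopifnot(model_case(params) == "I")
  r <- attractor_cover_cpp(par_vec(params), gain_code(params),
                           as.numeric(init), as.integer(m0), as.integer(m1),
                           n_orbit, as.integer(discard),
                           as.integer(max_sweeps), 0L)
  N <- r$counts
  local <- c(NA, diff(log(N)) / log(2))
  k <- length(N)
  structure(list(dimension = local[k],
                 stderr = abs(local[k] - local[k - 1]) / 2,
                 levels = data.frame(m = r$m, N = N, local = local),
                 n_points = NA_real_, low_count = FALSE),
            class = "ktz_dimension")
}

#' Kaplan-Yorke (Lyapunov) dimension
#'
#' From a sorted Lyapunov spectrum, the largest `j` with
#' \eqn{\sum_{i\le j}\lambda_i \ge 0} gives
#' \eqn{D = j + \sum_{i\le j}\lambda_i / |\lambda_{j+1}|}; 0 when every
#' exponent is negative.
#'
#' @param spectrum numeric vector, sorted descending (resorted otherwise).
#' @return The dimension estimate (a single number).
#' @examples
#' lyapunov_dimension(c(0.1258, -0.796))  # about 1.158
#' @export
lyapunov_dimension <- function(spectrum) {
  sp <- sort(spectrum, decreasing = TRUE)
  cs <- cumsum(sp)
  j <- suppressWarnings(max(which(cs >= 0)))
  if (!is.finite(j)) return(0)
  if (j == length(sp))
    return(as.numeric(length(sp)))  # no contracting direction left
  j + cs[j] / abs(sp[j + 1])
}

# ---- bifurcation location ------------------------------------------------

# built-in side predicates for locate_bifurcation; each returns TRUE on the
# "lower bracket" side
bifurcation_criteria <- function(criterion, config) {
  force(config)
  switch(criterion,
    spike_onset = function(params) {
      tr <- simulate_ktz(params, ktz_state(0.5, 0.5, 0),
                         n_steps = config$window,
                         discard = config$transient)
      length(detect_spikes(tr, config$threshold, config$hysteresis)) == 0
    },
    burst_duration_divergence = function(params) {
      # bursting (finite bursts separated by IBIs) vs a single unbounded
      # spike train: presence of any long ISI marks the bursting side
      tr <- simulate_ktz(params, ktz_state(0.5, 0.5, 0),
                         n_steps = config$window,
                         discard = config$transient)
      sp <- detect_spikes(tr, config$threshold, config$hysteresis)
      isis <- diff(sp)
      length(isis) > 0 && max(isis) > config$isi_th
    },
    stop("unknown criterion: ", criterion)
  )
}

#' Locate a bifurcation point by bisection
#'
#' Bisects a control parameter between `bracket[1]` and `bracket[2]` on a
#' regime predicate, classifying each probe by simulation.  Built-in
#' criteria: `"spike_onset"` (quiescent vs spiking, e.g. the FP boundary)
#' and `"burst_duration_divergence"` (bursting with interburst gaps vs a
#' single endless spike train — the blue-sky transition from bursting to
#' fast spiking).  A custom criterion may be given as a
#' `function(params) -> logical`, TRUE on the `bracket[1]` side.
#'
#' @param params base [ktz_params()].
#' @param control parameter name, e.g. `"xR"` or `"T"`.
#' @param bracket numeric `c(lo, hi)` straddling the transition.
#' @param criterion criterion name or predicate function.
#' @param config a [classifier_config()] used by the built-in criteria
#'   (default: `transient = 1e5`, `window = 1e6`).
#' @param tol bisection tolerance on the control parameter (default 1e-6).
#' @return List with `critical_value`, the final `bracket`, and `n_probes`.
#' @export
locate_bifurcation <- function(params, control, bracket, criterion,
                               config = classifier_config(),
                               tol = 1e-6) {
  pred <- if (is.function(criterion)) criterion
    else bifurcation_criteria(criterion, config)
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- pred(set_par(params, control, lo))
  f_hi <- pred(set_par(params, control, hi))
  if (identical(f_lo, f_hi))
    stop("bracket does not straddle the transition (both sides ",
         if (f_lo) "TRUE" else "FALSE", ")")
  n <- 0L
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (identical(pred(set_par(params, control, mid)), f_lo)) lo <- mid
    else hi <- mid
    n <- n + 1L
  }
  list(critical_value = (lo + hi) / 2, bracket = c(lo, hi), n_probes = n)
}

# ---- scaling fits --------------------------------------------------------

# log-log least squares: value ~ c * distance^exponent
power_law_fit <- function(distance, value) {
  fit <- stats::lm(log10(value) ~ log10(distance))
  sm <- summary(fit)
  list(exponent = unname(stats::coef(fit)[2]),
       stderr = sm$coefficients[2, 2], r_squared = sm$r.squared)
}

# observables measured from a spike train
scaling_observable <- function(name, config) {
  switch(name,
    mean_ISI = function(isis) if (length(isis)) mean(isis) else NA_real_,
    var_ISI = function(isis) if (length(isis) > 1) stats::var(isis)
      else NA_real_,
    IBI = function(isis) {
      long <- isis[isis > config$isi_th]
      if (length(long)) mean(long) else NA_real_
    },
    burst_duration = function(isis) NA_real_,  # handled from spike times
    stop("unknown observable: ", name)
  )
}

# mean duration of complete bursts: spikes split where the gap exceeds
# `gap`; duration = last spike - first spike of each interior burst
burst_durations <- function(spike_times, gap) {
  if (length(spike_times) < 2) return(numeric(0))
  brk <- which(diff(spike_times) > gap)
  if (length(brk) < 2) return(numeric(0))
  starts <- c(1, brk + 1); ends <- c(brk, length(spike_times))
  keep <- seq_along(starts)[-c(1, length(starts))]  # interior bursts only
  if (!length(keep)) return(numeric(0))
  spike_times[ends[keep]] - spike_times[starts[keep]]
}

#' Power-law scaling fit near a bifurcation
#'
#' Measures an observable of the spike train at each value of a control
#' parameter and fits the log-log slope against the distance
#' `|control - critical_value|`.  Points farther than `max_distance` from
#' the critical point are excluded (the power law only holds close to the
#' bifurcation); at least 8 valid points are required and the fit range
#' should span >= 1.5 decades.
#'
#' @param params base [ktz_params()].
#' @param control parameter name.
#' @param critical_value located bifurcation point (e.g. from
#'   [locate_bifurcation()]).
#' @param observable one of `"mean_ISI"`, `"var_ISI"`, `"IBI"`,
#'   `"burst_duration"`.
#' @param values control-parameter sample values.
#' @param config a [classifier_config()] (spike detection + windows).
#' @param max_distance exclusion radius (default 0.1).
#' @param burst_gap gap (ts) separating bursts for `burst_duration`
#'   (default `config$isi_th`).
#' @return List of class `ktz_scaling_fit`: `exponent`, `stderr`,
#'   `critical_value`, `control`, `observable`, `data` (distance, value),
#'   `decades`, `r_squared`.
#' @examples
#' \donttest{
#' p <- ktz_params(K = 0.6, T = 0.275, delta = 0.001, lambda = 0.001)
#' ## mean ISI diverges ~ |xR - xRc|^(-1/2) near the infinite-period point
#' }
#' @export
fit_scaling <- function(params, control, critical_value, observable, values,
                        config = classifier_config(), max_distance = 0.1,
                        burst_gap = config$isi_th) {
  obs_fun <- scaling_observable(observable, config)
  rows <- lapply(values, function(v) {
    d <- abs(v - critical_value)
    if (d > max_distance || d == 0) return(NULL)
    tr <- simulate_ktz(set_par(params, control, v), ktz_state(0.5, 0.5, 0),
                       n_steps = config$window, discard = config$transient)
    sp <- detect_spikes(tr, config$threshold, config$hysteresis)
    val <- if (observable == "burst_duration") {
      bd <- burst_durations(sp, burst_gap)
      if (length(bd)) mean(bd) else NA_real_
    } else obs_fun(diff(sp))
    if (!is.finite(val) || val <= 0) return(NULL)
    data.frame(control = v, distance = d, value = val)
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 8)
    stop("fewer than 8 valid points for the scaling fit")
  pw <- power_law_fit(d$distance, d$value)
  structure(list(control = control, observable = observable,
                 critical_value = critical_value,
                 exponent = pw$exponent, stderr = pw$stderr,
                 r_squared = pw$r_squared,
                 decades = diff(range(log10(d$distance))),
                 data = d),
            class = "ktz_scaling_fit")
}

#' @export
print.ktz_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "scaling fit: %s ~ |%s - %.6g|^(%.3f +- %.3f)  [%d pts, %.2f decades]\n",
    x$observable, x$control, x$critical_value, x$exponent, x$stderr,
    nrow(x$data), x$decades))
  invisible(x)
}
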