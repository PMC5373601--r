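## Gap-junction coupled networks of identical KTz units: directed chains
## (signal propagation) and complete graphs (synchronisation).

#' Network configuration
#'
#' Homogeneous networks of map units coupled by gap junctions: the synaptic
#' input into unit `i` is \eqn{I_i = \sum_j G (x_j - x_i)} over its
#' presynaptic neighbours.  Topologies: `"chain_directed"` (unit `i` feeds
#' `i+1` only; `N - 1` synapses), `"complete"` (all-to-all, no
#' self-coupling; `N(N-1)` synapses) and `"pair_undirected"` (two mutually
#' coupled units, for exactness checks).
#'
#' @param N number of units (>= 2).
#' @param topology one of `"chain_directed"`, `"complete"`,
#'   `"pair_undirected"`.
#' @param G gap-junction conductance (> 0, excitatory).
#' @param params shared [ktz_params()] of every unit.
#' @param init `"rest"` (all units at the stable FP / origin),
#'   `"random"` (x, y uniform on `[-1, 1]`, `z = 0`; set `seed`), or an
#'   `N x 3` matrix of states.
#' @param seed RNG seed recorded and used for `"random"` initial states.
#' @return A list of class `ktz_network_config`.
#' @export
network_config <- function(N, topology = c("chain_directed", "complete",
                                           "pair_undirected"),
                           G, params, init = "rest", seed = 1L) {
  topology <- match.arg(topology)
  N <- as.integer(N)
  stopifnot(N >= 2, G >= 0, inherits(params, "ktz_params"))
  if (topology == "pair_undirected" && N != 2)
    stop("pair_undirected requires N = 2")
  structure(list(N = N, topology = topology, G = G, params = params,
                 init = init, seed = as.integer(seed)),
            class = "ktz_network_config")
}

topology_code <- function(topology) {
  match(topology, c("chain_directed", "complete", "pair_undirected")) - 1L
}

# resolve the initial N x 3 state matrix
network_init_states <- function(config) {
  N <- config$N
  if (is.matrix(config$init)) {
    stopifnot(nrow(config$init) == N, ncol(config$init) == 3)
    return(config$init)
  }
  if (identical(config$init, "rest")) {
    fps <- tryCatch({
      f <- if (model_case(config$params) == "I")
        fixed_points_case1(config$params)
      else fixed_points_case2(config$params)
      stable <- Filter(function(r) r$stability == "stable", f)
      if (length(stable)) stable[[1]] else f[[1]]
    }, error = function(e) NULL)
    st <- if (is.null(fps)) c(0, 0, 0)
      else c(fps$x_star, fps$y_star, fps$z_star)
    return(matrix(st, nrow = N, ncol = 3, byrow = TRUE))
  }
  if (identical(config$init, "random")) {
    set.seed(config$seed)
    return(cbind(stats::runif(N, -1, 1), stats::runif(N, -1, 1), 0))
  }
  stop("init must be 'rest', 'random' or an N x 3 matrix")
}

#' Gap-junction currents for a set of states (reference implementation)
#'
#' Computes every synaptic current from the *old* membrane potentials.
#' Exact antisymmetry holds on undirected topologies: the pairwise currents
#' sum to zero.
#'
#' @param x numeric vector of membrane potentials.
#' @param config a [network_config()].
#' @return Numeric vector of per-unit summed input currents.
#' @export
gap_currents <- function(x, config) {
  N <- length(x); G <- config$G
  switch(config$topology,
    chain_directed = c(0, G * (x[-N] - x[-1])),
    complete = G * (sum(x) - N * x),
    pair_undirected = c(G * (x[2] - x[1]), G * (x[1] - x[2])))
}

#' One synchronous network step (reference implementation)
#'
#' The network update follows the standard three-stage scheme: (1) every
#' synaptic signal is computed from the old potentials, (2) inputs are
#' summed per unit, (3) every unit advances one map step with its summed
#' current.  [simulate_network()] runs the identical update in compiled
#' code.
#'
#' @param states `N x 3` matrix of unit states.
#' @param config a [network_config()].
#' @param I_ext external input added to unit 1 (default 0).
#' @return The new `N x 3` state matrix.
#' @export
step_network <- function(states, config, I_ext = 0) {
  I <- gap_currents(states[, 1], config)
  I[1] <- I[1] + I_ext
  t(vapply(seq_len(nrow(states)), function(i) {
    as.numeric(ktz_step(ktz_state(states[i, 1], states[i, 2], states[i, 3]),
                        config$params, I[i]))
  }, numeric(3)))
}

#' Simulate a coupled network
#'
#' @param config a [network_config()].
#' @param n_steps steps to record after the transient.
#' @param discard transient steps (default 0).
#' @param kick optional [stimulus] injected into unit 1 (e.g. a delta pulse
#'   to start a propagating wave).
#' @return List of class `ktz_network_run`: `x` (`n_steps x N` matrix of
#'   membrane potentials), `config`, `t0`.
#' @export
simulate_network <- function(config, n_steps, discard = 0,
                             kick = stim_none()) {
  init <- network_init_states(config)
  I <- stim_as_series(kick, as.integer(n_steps) + as.integer(discard))
  x <- network_cpp(par_vec(config$params), gain_code(config$params),
                   topology_code(config$topology), config$G, init,
                   as.integer(n_steps), as.integer(discard), I)
  structure(list(x = x, config = config, t0 = as.integer(discard)),
            class = "ktz_network_run")
}

#' Minimal conductance for chain propagation
#'
#' Bisects the gap-junction conductance `G` for the propagation predicate:
#' a kick into unit 1 of a chain of excitable units elicits at least one
#' spike in unit `N` within the horizon.
#'
#' @param config a chain [network_config()] (its `G` is ignored).
#' @param bracket `c(G_lo, G_hi)` straddling the propagation threshold.
#' @param kick stimulus into unit 1 (default: delta pulse of amplitude 1 at
#'   t = 0).
#' @param horizon simulation length per probe (default 2e4 ts).
#' @param threshold,hysteresis spike detection for the last unit.
#' @param tol bisection tolerance (default 1e-6).
#' @return List with `threshold_G`, `bracket`, `n_probes`.
#' @export
find_propagation_threshold <- function(config, bracket,
                                       kick = stim_delta(1, 0),
                                       horizon = 2e4,
                                       threshold = 0, hysteresis = 0.1,
                                       tol = 1e-6) {
  stopifnot(config$topology == "chain_directed")
  propagates <- function(G) {
    cfg <- config; cfg$G <- G
    run <- simulate_network(cfg, n_steps = horizon, kick = kick)
    length(detect_spikes(run$x[, config$N], threshold, hysteresis)) > 0
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (propagates(lo)) stop("bracket lower end already propagates")
  if (!propagates(hi))
    stop("propagation fails even at the bracket top")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (propagates(mid)) hi <- mid else lo <- mid
  }
  list(threshold_G = (lo + hi) / 2, bracket = c(lo, hi))
}

#' Synchrony order parameter
#'
#' `1 - mean_t Var_pop(x(t)) / Var_t(x_1)`: one minus the time-averaged
#' population variance normalised by the temporal variance of a reference
#' unit (unit 1).  Identical trajectories give 1; independent units of
#' identical statistics give about 0.  Degenerate (constant) references are
#' flagged.
#'
#' @param run a `ktz_network_run` (transient already discarded) or an
#'   `n_steps x N` matrix of potentials.
#' @return List with `order` (clamped to `[0, 1]`), `raw`, and `degenerate`
#'   flag.
#' @export
synchrony_order <- function(run) {
  x <- if (inherits(run, "ktz_network_run")) run$x else run
  pop_var <- apply(x, 1L, stats::var)
  ref_var <- stats::var(x[, 1])
  if (ref_var < 1e-20) {
    identical_all <- all(abs(x - x[, 1]) < 1e-12)
    return(list(order = if (identical_all) 1 else NA_real_,
                raw = NA_real_, degenerate = TRUE))
  }
  raw <- 1 - mean(pop_var) / ref_var
  list(order = min(max(raw, 0), 1), raw = raw, degenerate = FALSE)
}
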