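#' Logistic gain function and its derivative
#'
#' The logistic gain \eqn{f(u) = u/(1+|u|)} maps the real line onto the open
#' interval (-1, 1); it is odd, strictly increasing and C^1 with derivative
#' \eqn{f'(u) = 1/(1+|u|)^2}.  It agrees with `tanh` to third order at the
#' origin and, unlike `tanh`, needs no overflow guard.
#'
#' @param u numeric vector of finite values.
#' @param gain `"logistic"` or `"tanh"`.
#' @return `logistic_gain(u)` in (-1, 1); `gain_derivative(u)` in (0, 1].
#' @examples
#' logistic_gain(c(0, 1, -3))   # 0, 0.5, -0.75
#' gain_derivative(c(0, 1))     # 1, 0.25
#' @export
logistic_gain <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u))) stop("u must be finite")
  u / (1 + abs(u))
}

#' @rdname logistic_gain
#' @export
gain_derivative <- function(u, gain = c("logistic", "tanh")) {
  gain <- match.arg(gain)
  if (!is.numeric(u) || any(!is.finite(u))) stop("u must be finite")
  if (gain == "logistic") 1 / (1 + abs(u))^2 else 1 - tanh(u)^2
}

# internal: gain function by name (vectorised)
gain_fun <- function(u, gain) {
  if (gain == "logistic") logistic_gain(u) else tanh(pmin(pmax(u, -350), 350))
}

#' One synchronous step of the map
#'
#' Advances a state by one time step.  All three components are computed from
#' the *old* state (synchronous update): first the gain argument
#' \eqn{u = (x - Ky + z + H + I)/T}, then \eqn{x' = f(u)}, \eqn{y' = x},
#' \eqn{z' = (1-\delta)z - \lambda(x - x_R)}.
#'
#' This is the plain-R reference implementation; [simulate_ktz()] runs the
#' identical update in compiled code.
#'
#' @param state a [ktz_state()].
#' @param params a [ktz_params()].
#' @param I external input potential at this step (default 0).
#' @return The new `ktz_state`.
#' @examples
#' p <- ktz_params(K = 0.6, T = 0.35)
#' ktz_step(ktz_state(1, 1, 0), p)  # x' = f(8/7) = 8/15
#' @export
ktz_step <- function(state, params, I = 0) {
  stopifnot(inherits(params, "ktz_params"))
  if (!all(is.finite(state))) stop("state must be finite")
  if (!is.finite(I)) stop("I must be finite")
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  u <- (x - params$K * y + z + params$H + I) / params$T
  ktz_state(x = gain_fun(u, params$gain),
            y = x,
            z = (1 - params$delta) * z - params$lambda * (x - params$xR))
}

#' Simulate a trajectory of the map
#'
#' Iterates the map from `init` for `discard + n_steps` steps and returns the
#' last `n_steps` states.  Time is counted from 0 at `init`; the stimulus
#' series covers the whole run including the discarded transient, so a
#' stimulus with `onset = 0` acts on the very first update.  Runs are
#' bit-exactly reproducible: identical inputs give identical state sequences.
#'
#' @param params a [ktz_params()].
#' @param init initial [ktz_state()] (default: the origin).
#' @param n_steps number of states to return (>= 1).
#' @param stimulus a [stimulus] object (default none).
#' @param discard transient steps to drop before recording (>= 0).
#' @return A `ktz_trajectory`: list with `states` (an `n_steps` x 3 matrix
#'   with columns `x, y, z`), `I` (the applied series, `numeric(0)` if none),
#'   `params`, `stimulus`, and `t0` = `discard` (the time of the first
#'   recorded state).
#' @examples
#' p <- ktz_params(K = 0.89, T = 0.009)
#' tr <- simulate_ktz(p, ktz_state(1, 1), n_steps = 1000)
#' range(tr$states[, "x"])
#' @export
simulate_ktz <- function(params, init = ktz_state(0, 0, 0), n_steps,
                         stimulus = stim_none(), discard = 0) {
  stopifnot(inherits(params, "ktz_params"), inherits(stimulus, "ktz_stimulus"))
  n_steps <- as.integer(n_steps); discard <- as.integer(discard)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (discard < 0) stop("discard must be >= 0")
  I <- stim_as_series(stimulus, n_steps + discard)
  states <- sim_cpp(par_vec(params), gain_code(params), as.numeric(init),
                    n_steps, discard, I)
  colnames(states) <- c("x", "y", "z")
  structure(list(states = states, I = I, params = params,
                 stimulus = stimulus, t0 = discard),
            class = "ktz_trajectory")
}

#' @export
print.ktz_trajectory <- function(x, ...) {
  cat(sprintf("ktz_trajectory: %d steps (t = %d..%d), case %s\n",
              nrow(x$states), x$t0, x$t0 + nrow(x$states) - 1L,
              model_case(x$params)))
  cat(sprintf("  x range [%.4g, %.4g]\n",
              min(x$states[, "x"]), max(x$states[, "x"])))
  invisible(x)
}

#' @export
as.data.frame.ktz_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  t <- x$t0 + seq_len(n) - 1L
  I <- if (length(x$I)) x$I[t + 1L] else numeric(n)
  data.frame(t = t, x = x$states[, "x"], y = x$states[, "y"],
             z = x$states[, "z"], I = I)
}

#' @export
plot.ktz_trajectory <- function(x, what = "x", ...) {
  d <- as.data.frame(x)
  graphics::plot(d$t, d[[what]], type = "l", xlab = "t (ts)", ylab = what, ...)
  invisible(x)
}
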