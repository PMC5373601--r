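#' Parameter set for the KTLog / KTzLog map
#'
#' Bundles the six model parameters and the gain-function choice.  The map is
#'
#' \deqn{x(t+1) = f\big((x(t) - K y(t) + z(t) + H + I(t))/T\big)}
#' \deqn{y(t+1) = x(t)}
#' \deqn{z(t+1) = (1-\delta) z(t) - \lambda (x(t) - x_R)}
#'
#' with gain \eqn{f(u) = u/(1+|u|)} (logistic) or \eqn{f(u)=\tanh(u)}.
#' Two canonical sub-families are distinguished:
#' * **case I** (the 2-D fast subsystem, "KTLog"): `delta = lambda = 0`,
#'   so `z` is frozen at its initial value (0 by convention) and `H` acts
#'   as a bias;
#' * **case II** (the full 3-D model, "KTzLog"): `H = 0` with `delta`,
#'   `lambda` free; the slow current `z` then plays the role of a
#'   dynamical bias relaxing towards \eqn{(x_R - x)\lambda/\delta}.
#'
#' @param K gain coupling to the recovery variable (> 0).
#' @param T gain scale ("temperature", > 0); small `T` means a steep gain.
#' @param H bias membrane potential (case I only; must be 0 when
#'   `delta` or `lambda` is nonzero).
#' @param delta inverse recovery time of the slow current, in `[0, 1]`.
#' @param lambda slow-current coupling (>= 0); damps oscillations.
#' @param xR reversal-like parameter in `[-1, 1]`; sets burst duration.
#' @param gain `"logistic"` (default) or `"tanh"`.
#'
#' @return An object of class `ktz_params` (a named list).
#' @examples
#' p <- ktz_params(K = 0.6, T = 0.35)
#' model_case(p)
#' @export
ktz_params <- function(K, T, H = 0, delta = 0, lambda = 0, xR = 0,
                       gain = c("logistic", "tanh")) {
  gain <- match.arg(gain)
  for (nm in c("K", "T", "H", "delta", "lambda", "xR")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter `", nm, "` must be a single finite number")
    assign(nm, as.numeric(v))
  }
  if (K <= 0) stop("K must be > 0")
  if (T <= 0) stop("T must be > 0")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (abs(xR) > 1) stop("xR must lie in [-1, 1]")
  if (H != 0 && (delta != 0 || lambda != 0))
    stop("H must be 0 when the slow current is active (case II)")
  structure(list(K = K, T = T, H = H, delta = delta, lambda = lambda,
                 xR = xR, gain = gain),
            class = "ktz_params")
}

#' Which canonical sub-family a parameter set belongs to
#'
#' @param params a [ktz_params()] object.
#' @return `"I"` if `delta = lambda = 0` (2-D fast subsystem), else `"II"`.
#' @export
model_case <- function(params) {
  stopifnot(inherits(params, "ktz_params"))
  if (params$delta == 0 && params$lambda == 0) "I" else "II"
}

#' @export
print.ktz_params <- function(x, ...) {
  cat(sprintf("KT%s map parameters (case %s, %s gain)\n",
              if (model_case(x) == "II") "z" else "", model_case(x), x$gain))
  cat(sprintf("  K = %g, T = %g, H = %g\n", x$K, x$T, x$H))
  cat(sprintf("  delta = %g, lambda = %g, xR = %g\n",
              x$delta, x$lambda, x$xR))
  invisible(x)
}

# internal: parameter vector in the order the compiled kernels expect
par_vec <- function(params) {
  c(params$K, params$T, params$H, params$delta, params$lambda, params$xR)
}

gain_code <- function(params) if (params$gain == "tanh") 1L else 0L

# internal: index of a parameter name in par_vec order
par_index <- function(name) {
  i <- match(name, c("K", "T", "H", "delta", "lambda", "xR"))
  if (is.na(i)) stop("unknown parameter name: ", name)
  i - 1L
}

# internal: return params with one named parameter replaced (no case check,
# used by sweeps that deliberately cross the case-I/II boundary)
set_par <- function(params, name, value) {
  params[[name]] <- value
  params
}

#' Model state
#'
#' A single `(x, y, z)` point: membrane potential, recovery variable and slow
#' ionic current.  After any update with bounded input, `|x| < 1` because the
#' gain range is the open interval (-1, 1), and `y(t+1) = x(t)` exactly.
#'
#' @param x membrane potential (arbitrary units).
#' @param y recovery variable (defaults to `x`, a point on the `y = x`
#'   diagonal where all fixed points live).
#' @param z slow ionic current (default 0, the conventional initial value).
#' @return A named numeric vector of class `ktz_state`.
#' @export
ktz_state <- function(x, y = x, z = 0) {
  v <- c(x = x, y = y, z = z)
  if (!all(is.finite(v))) stop("state components must be finite")
  structure(v, class = "ktz_state")
}
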