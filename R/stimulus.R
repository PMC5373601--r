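#' Stimulus protocols
#'
#' A stimulus is an external potential series \eqn{I(t)} added inside the
#' gain argument of the map, exactly as the model equation reads: excitatory
#' input is positive, inhibitory input is a negative amplitude.  `I(t) = 0`
#' outside the `[onset, offset)` window.  Times are integer time steps (ts)
#' counted from 0 at the start of the simulation (including any discarded
#' transient).
#'
#' Constructors:
#' * `stim_none()` — no input.
#' * `stim_delta(amplitude, at)` — a single 1-ts pulse at time `at`.
#' * `stim_dc(amplitude, onset, offset)` — a DC step.
#' * `stim_pulse_train(amplitude, onset, offset, period, width)` —
#'   pulses of `width` ts every `period` ts.
#' * `stim_ramp(slope, onset, offset)` — linear ramp, `I = slope * (t - onset)`.
#' * `stim_series(values, cyclic)` — arbitrary series, recycled if `cyclic`.
#'
#' @param amplitude stimulus amplitude (arbitrary units).
#' @param at,onset,offset time steps; the window is `[onset, offset)`.
#' @param period,width pulse-train period and pulse width, in ts.
#' @param slope ramp slope per ts.
#' @param values numeric vector for `stim_series`.
#' @param cyclic recycle `values` beyond their length (else error if short).
#' @return An object of class `ktz_stimulus`.
#' @name stimulus
NULL

new_stim <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "ktz_stimulus")
}

#' @rdname stimulus
#' @export
stim_none <- function() new_stim("none")

#' @rdname stimulus
#' @export
stim_delta <- function(amplitude, at = 0L) {
  new_stim("delta_pulse", amplitude = amplitude, onset = as.integer(at),
           offset = as.integer(at) + 1L)
}

#' @rdname stimulus
#' @export
stim_dc <- function(amplitude, onset = 0L, offset = Inf) {
  new_stim("dc_step", amplitude = amplitude, onset = as.integer(onset),
           offset = offset)
}

#' @rdname stimulus
#' @export
stim_pulse_train <- function(amplitude, onset, offset, period, width = 1L) {
  stopifnot(period >= 1, width >= 1, width <= period)
  new_stim("pulse_train", amplitude = amplitude, onset = as.integer(onset),
           offset = offset, period = as.integer(period),
           width = as.integer(width))
}

#' @rdname stimulus
#' @export
stim_ramp <- function(slope, onset = 0L, offset = Inf) {
  new_stim("ramp", slope = slope, onset = as.integer(onset), offset = offset)
}

#' @rdname stimulus
#' @export
stim_series <- function(values, cyclic = FALSE) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  new_stim("custom_series", values = as.numeric(values), cyclic = cyclic)
}

#' Materialise a stimulus into a numeric series
#'
#' @param stim a [stimulus] object.
#' @param n total number of time steps (t = 0, ..., n-1).
#' @return Numeric vector of length `n` (or `numeric(0)` for `stim_none`,
#'   which the simulator treats as identically zero).
#' @export
stim_as_series <- function(stim, n) {
  stopifnot(inherits(stim, "ktz_stimulus"))
  n <- as.integer(n)
  if (stim$kind == "none") return(numeric(0))
  t <- seq_len(n) - 1L
  I <- numeric(n)
  if (stim$kind == "custom_series") {
    if (length(stim$values) >= n) return(stim$values[seq_len(n)])
    if (!isTRUE(stim$cyclic))
      stop("custom series shorter than simulation and not cyclic")
    return(rep_len(stim$values, n))
  }
  on <- t >= stim$onset & t < stim$offset
  if (stim$kind == "delta_pulse" || stim$kind == "dc_step") {
    I[on] <- stim$amplitude
  } else if (stim$kind == "pulse_train") {
    phase <- (t - stim$onset) %% stim$period
    I[on & phase < stim$width] <- stim$amplitude
  } else if (stim$kind == "ramp") {
    I[on] <- stim$slope * (t[on] - stim$onset)
  } else stop("unknown stimulus kind: ", stim$kind)
  I
}
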