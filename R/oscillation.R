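## ISI-based regime analysis: spike detection, oscillation summaries,
## phase labels (FP / SO / FS / CS / ACS / BS / SB / MIXED_DUST / BI),
## phase-diagram sweeps and winding numbers.

#' Classifier configuration
#'
#' All thresholds of the ISI-distribution regime classifier.  None of them
#' comes from a closed form; they formalise the qualitative taxonomy of the
#' model's oscillatory regimes and every diagram reports the configuration
#' it used.
#'
#' @param threshold spike threshold on `x` (default 0: the potential
#'   oscillates inside (-1, 1) around ~0).
#' @param hysteresis re-arming depth: a new spike requires `x` to have been
#'   below `threshold - hysteresis` since the last one (default 0.1).
#' @param isi_th ISI threshold (ts) separating fast spiking (mean ISI below)
#'   from cardiac spiking (above); default 100, between typical FS ISIs
#'   (~10 ts) and CS ISIs (~10^3 ts).
#' @param cv_th coefficient-of-variation threshold separating periodic
#'   cardiac spiking (sharp ISI peak) from aperiodic cardiac spiking
#'   (broad skewed distribution); default 0.1.
#' @param ibi_th interburst-interval threshold (ts) separating bursting
#'   from slow bursting; the split is conventional, default 500.
#' @param A_so,A_spike amplitude cut-offs: below `A_so` a spikeless
#'   trajectory is a fixed point, between `A_so` and above it is
#'   subthreshold oscillation; `A_spike` is the nominal full-spike
#'   amplitude (defaults 0.05 and 1.0).
#' @param transient time steps discarded before measuring (default 1e5).
#' @param window measurement window in ts (default 1e6).
#' @param min_isi_count below this many ISIs a slow-regime label carries a
#'   `low_count` flag (default 20).
#' @return A list of class `ktz_classifier_config`.
#' @export
classifier_config <- function(threshold = 0, hysteresis = 0.1,
                              isi_th = 100, cv_th = 0.1, ibi_th = 500,
                              A_so = 0.05, A_spike = 1.0,
                              transient = 1e5, window = 1e6,
                              min_isi_count = 20) {
  structure(list(threshold = threshold, hysteresis = hysteresis,
                 isi_th = isi_th, cv_th = cv_th, ibi_th = ibi_th,
                 A_so = A_so, A_spike = A_spike,
                 transient = as.integer(transient),
                 window = as.integer(window),
                 min_isi_count = min_isi_count),
            class = "ktz_classifier_config")
}

#' Detect spikes in a trajectory
#'
#' A spike time is each upward crossing of `x` through `threshold` after `x`
#' has been below `threshold - hysteresis` since the previous spike (or the
#' start).  Deterministic; an empty result is valid (quiescent cell).
#'
#' @param traj a `ktz_trajectory` or a numeric `x` series.
#' @param threshold,hysteresis see [classifier_config()].
#' @return Integer vector of spike times, indexed from the first trajectory
#'   sample (position 1).
#' @export
detect_spikes <- function(traj, threshold = 0, hysteresis = 0.1) {
  x <- if (inherits(traj, "ktz_trajectory")) traj$states[, "x"] else traj
  above <- x >= threshold
  low <- x < threshold - hysteresis
  # event-sequence formulation of the hysteresis state machine: looking only
  # at samples that are above threshold (A) or below the re-arming level
  # (B), a spike is every A whose preceding event is a B; the initial state
  # is armed only if the first sample is a B
  idx <- which(above | low)
  if (!length(idx)) return(integer(0))
  v <- above[idx]
  prev <- c(!low[1], v[-length(v)])   # TRUE = "as if after a spike"
  idx[v & !prev]
}

#' Oscillation amplitude
#'
#' `max(x) - min(x)` over the (transient-free) trajectory; 0 for a constant
#' trajectory and always below 2 for the logistic gain.
#'
#' @param traj a `ktz_trajectory` or numeric `x` series.
#' @return A single number in `[0, 2)`.
#' @export
amplitude <- function(traj) {
  x <- if (inherits(traj, "ktz_trajectory")) traj$states[, "x"] else traj
  max(x) - min(x)
}

# ---- ISI histogram modes (R mirror of the compiled kernel) ---------------
# quarter-octave log2 bins; a mode is a run of bins with count >= 2% of the
# total mass, separated by sub-threshold bins, holding >= 5% of the mass.
isi_modes <- function(isis) {
  n <- length(isis)
  if (n == 0)
    return(list(n_modes = 0L, mode_means = numeric(0)))
  b <- pmin(pmax(floor(4 * log2(isis)), 0), 95)
  cnt <- tabulate(b + 1L, nbins = 96)
  smm <- vapply(seq_len(96) - 1L,
                function(bb) sum(isis[b == bb]), numeric(1))
  occupied <- cnt > 0.02 * n
  runs <- rle(occupied)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  means <- numeric(0)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    mass <- sum(cnt[idx])
    if (mass >= 0.05 * n) means <- c(means, sum(smm[idx]) / mass)
  }
  list(n_modes = length(means), mode_means = means)
}

#' Summarise the oscillation of a trajectory
#'
#' Collects everything the regime classifier needs: spike times, ISIs and
#' their moments, amplitude, ISI-histogram modes, and the same statistics
#' for each half of the window (label stability across halves is what
#' defines the chaotic CS/BS switching regime).
#'
#' @param traj a transient-free `ktz_trajectory`.
#' @param config a [classifier_config()].
#' @return A list of class `ktz_oscillation_summary` with fields
#'   `spike_times`, `isis`, `amplitude_A`, `mean_isi`, `var_isi`,
#'   `n_isi_peaks`, `mode_means`, and `halves` (the two sub-summaries).
#' @export
oscillation_summary <- function(traj, config = classifier_config()) {
  x <- if (inherits(traj, "ktz_trajectory")) traj$states[, "x"] else traj
  n <- length(x)
  half <- n %/% 2
  sp <- detect_spikes(x, config$threshold, config$hysteresis)
  mk <- function(idx0, spikes) {
    isis <- diff(spikes)
    m <- isi_modes(isis)
    list(amplitude_A = if (length(idx0)) max(x[idx0]) - min(x[idx0]) else 0,
         n_isi = length(isis),
         mean_isi = if (length(isis)) mean(isis) else NA_real_,
         var_isi = if (length(isis) > 1) stats::var(isis) else NA_real_,
         max_isi = if (length(isis)) max(isis) else NA_real_,
         n_isi_peaks = m$n_modes, mode_means = m$mode_means)
  }
  full <- mk(seq_len(n), sp)
  h1 <- mk(seq_len(half), sp[sp <= half])
  h2 <- mk((half + 1):n, sp[sp > half])
  structure(c(list(spike_times = sp, isis = diff(sp)), full,
              list(halves = list(h1, h2), config = config)),
            class = "ktz_oscillation_summary")
}

# classify one window's statistics (shared by the R and compiled paths)
classify_stats <- function(st, config) {
  if (st$n_isi == 0) {
    if (st$amplitude_A < config$A_so) return("FP")
    return("SO")
  }
  if (st$n_isi_peaks >= 2) {
    long_mode <- st$mode_means[length(st$mode_means)]
    return(if (long_mode > config$ibi_th) "SB" else "BS")
  }
  if (st$mean_isi < config$isi_th) return("FS")
  cv <- if (st$n_isi > 1) sqrt(st$var_isi) / st$mean_isi else 0
  if (cv < config$cv_th) "CS" else "ACS"
}

#' Classify the dynamical regime of a trajectory
#'
#' Implements the ISI-distribution taxonomy: no spikes and tiny amplitude is
#' a fixed point (`FP`); no spikes with sub-spike oscillation is
#' subthreshold oscillation (`SO`); a unimodal ISI distribution is fast
#' spiking (`FS`) when the mean ISI is short, periodic cardiac spiking
#' (`CS`) when long and narrow, aperiodic cardiac spiking (`ACS`) when long
#' and broad; a bimodal distribution is bursting (`BS`), or slow bursting
#' (`SB`) when the interburst mode exceeds `ibi_th`.  If the two window
#' halves disagree on a CS/BS-type label the regime is the chaotic
#' switching band (`MIXED_DUST`).  `BI` is only emitted by
#' [probe_bistability()].
#'
#' @param summary a [oscillation_summary()] (or a `ktz_trajectory`, which is
#'   summarised first).
#' @param config a [classifier_config()].
#' @return A character label with attributes `low_count` (logical) and
#'   `half_labels`.
#' @export
classify_phase <- function(summary, config = classifier_config()) {
  if (inherits(summary, "ktz_trajectory"))
    summary <- oscillation_summary(summary, config)
  lab <- classify_stats(summary, config)
  h <- vapply(summary$halves, classify_stats, character(1), config = config)
  # halves see half the ISIs; only trust a disagreement when both halves
  # actually measured something
  both_measured <- all(vapply(summary$halves,
                              function(s) s$n_isi > 0 || s$amplitude_A > 0,
                              logical(1)))
  if (both_measured && h[1] != h[2] &&
      any(c("CS", "BS", "SB", "ACS", "MIXED") %in% h))
    lab <- "MIXED_DUST"
  low <- lab %in% c("CS", "ACS", "BS", "SB") &&
    summary$n_isi < config$min_isi_count
  structure(lab, low_count = low, half_labels = h)
}

# classify one row of the compiled sweep summary matrix (24 columns:
# 3 windows x [amp, n, mean, var, max, n_modes, mode1, modeL])
classify_sweep_row <- function(row, config) {
  st_of <- function(o) list(amplitude_A = row[o + 1], n_isi = row[o + 2],
                            mean_isi = row[o + 3], var_isi = row[o + 4],
                            max_isi = row[o + 5], n_isi_peaks = row[o + 6],
                            mode_means = c(row[o + 7], row[o + 8])[
                              !is.na(c(row[o + 7], row[o + 8]))])
  full <- st_of(0); h1 <- st_of(8); h2 <- st_of(16)
  # mode_means here carries only (first, last); classify_stats uses the last
  lab <- classify_stats(full, config)
  l1 <- classify_stats(h1, config); l2 <- classify_stats(h2, config)
  both <- (h1$n_isi > 0 || h1$amplitude_A > 0) &&
    (h2$n_isi > 0 || h2$amplitude_A > 0)
  if (both && l1 != l2 && any(c("CS", "BS", "SB", "ACS") %in% c(l1, l2)))
    lab <- "MIXED_DUST"
  lab
}

#' Phase diagram over a 2-D parameter grid
#'
#' Classifies the attractor reached from `init` on every cell of a grid in
#' two model parameters (all others fixed).  The sweep runs in compiled
#' code; classification applies [classify_phase()]'s rules to each cell.
#' Optionally each cell is probed from the 8 corners of the state cube
#' `[-1,1]^3` and marked `BI` when distinct labels coexist.
#'
#' @param params base [ktz_params()].
#' @param plane character 2-vector naming the swept parameters, e.g.
#'   `c("xR", "T")`.
#' @param range1,range2 numeric `c(min, max)` for each axis.
#' @param n1,n2 grid resolution.
#' @param config a [classifier_config()]; for diagram-scale work a reduced
#'   window (e.g. `window = 2e5, transient = 5e4`) is usual.
#' @param init initial state (default `ktz_state(0.5, 0.5, 0)`, off the
#'   symmetric origin so either attractor basin can be reached).
#' @param probe_bistability also sweep from the corner states and relabel
#'   cells with conflicting outcomes as `"BI"`.
#' @return A data frame with columns `p1`, `p2`, `label`, `mean_isi`,
#'   `var_isi`, `amplitude`; the configuration used is attached as
#'   attribute `config`.
#' @export
phase_diagram <- function(params, plane, range1, range2, n1, n2,
                          config = classifier_config(transient = 5e4,
                                                     window = 2e5),
                          init = ktz_state(0.5, 0.5, 0),
                          probe_bistability = FALSE) {
  stopifnot(length(plane) == 2)
  v1 <- seq(range1[1], range1[2], length.out = n1)
  v2 <- seq(range2[1], range2[2], length.out = n2)
  g <- expand.grid(p1 = v1, p2 = v2)
  run_from <- function(st) {
    m <- sweep_cpp(par_vec(params), gain_code(params),
                   par_index(plane[1]), g$p1, par_index(plane[2]), g$p2,
                   as.numeric(st), config$window, config$transient,
                   config$threshold, config$hysteresis)
    apply(m, 1L, classify_sweep_row, config = config)
  }
  m <- sweep_cpp(par_vec(params), gain_code(params),
                 par_index(plane[1]), g$p1, par_index(plane[2]), g$p2,
                 as.numeric(init), config$window, config$transient,
                 config$threshold, config$hysteresis)
  labels <- apply(m, 1L, classify_sweep_row, config = config)
  if (probe_bistability) {
    corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                     z = c(-1, 1)))
    if (model_case(params) == "I") {
      corners[, "z"] <- 0
      corners <- unique(corners)
    }
    lab_mat <- vapply(seq_len(nrow(corners)),
                      function(i) run_from(corners[i, ]),
                      character(nrow(g)))
    n_distinct <- apply(cbind(labels, lab_mat), 1L,
                        function(r) length(unique(r)))
    labels[n_distinct >= 2] <- "BI"
  }
  out <- data.frame(p1 = g$p1, p2 = g$p2, label = labels,
                    mean_isi = m[, 3], var_isi = m[, 4], amplitude = m[, 1])
  names(out)[1:2] <- plane
  attr(out, "config") <- config
  attr(out, "params") <- params
  out
}

#' Probe a parameter point for bistability
#'
#' Runs the classifier from the 8 corners of `[-1, 1]^3` (4 corners with
#' `z = 0` for case I) plus the supplied default initial state; the point is
#' bistable when at least two distinct labels are found.
#'
#' @param params a [ktz_params()].
#' @param config a [classifier_config()].
#' @return List with `bistable` flag and the vector of `labels` found.
#' @export
probe_bistability <- function(params, config = classifier_config(
                                transient = 5e4, window = 2e5)) {
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                   z = c(-1, 1)))
  if (model_case(params) == "I") { corners[, "z"] <- 0; corners <- unique(corners) }
  labs <- vapply(seq_len(nrow(corners)), function(i) {
    tr <- simulate_ktz(params, ktz_state(corners[i, 1], corners[i, 2],
                                         corners[i, 3]),
                       n_steps = config$window, discard = config$transient)
    as.character(classify_phase(tr, config))
  }, character(1))
  list(bistable = length(unique(labs)) >= 2, labels = labs)
}

#' Winding number on the supercritical Neimark-Sacker line
#'
#' On the oscillation-onset line `T = K_c` (`K_c > 0.5`, `H = 0`) the
#' eigenvalue pair sits on the unit circle with rotation angle
#' \eqn{\theta = \arccos(1/2K_c)}, so the Arnold-tongue label (winding
#' number) born there is \eqn{w = \arccos(1/2K_c)/2\pi}.
#'
#' @param Kc coupling on the bifurcation line, `>= 0.5`.
#' @return Winding number in `[0, 1/4)`.
#' @examples
#' winding_number_analytic(1)  # 1/6
#' @export
winding_number_analytic <- function(Kc) {
  if (any(Kc < 0.5)) stop("Kc must be >= 0.5 (arccos argument must be <= 1)")
  acos(1 / (2 * Kc)) / (2 * pi)
}

#' Measured winding (rotation) number of an orbit
#'
#' Estimates the number of oscillations per time step by accumulating the
#' rotation angle of the orbit around a fixed point in the `(x, y)` plane.
#' If the orbit is Q-periodic with `Q <= maxQ` (state recurrence within
#' `tol`), the exact rational `P/Q` is returned; otherwise a real estimate.
#' On the supercritical Neimark-Sacker line the estimate converges to
#' [winding_number_analytic()].
#'
#' @param traj a transient-free `ktz_trajectory` on an oscillatory
#'   attractor.
#' @param maxQ largest period to report exactly (default 100).
#' @param center the encircled fixed point `c(x, y)`; defaults to the FP of
#'   the trajectory's parameters nearest to the orbit centroid.
#' @param tol recurrence tolerance for periodicity detection (default 1e-9).
#' @return List with `w` (the estimate), and when periodic, integers `P`,
#'   `Q` and `exact = TRUE`.
#' @export
winding_number_measured <- function(traj, maxQ = 100, center = NULL,
                                    tol = 1e-9) {
  s <- traj$states
  if (nrow(s) < 10 || amplitude(traj) < 1e-12)
    stop("non-oscillatory trajectory: winding number undefined")
  if (is.null(center)) {
    fps <- if (model_case(traj$params) == "I")
      fixed_points_case1(traj$params) else fixed_points_case2(traj$params)
    cent <- colMeans(s[, 1:2])
    xs <- vapply(fps, `[[`, numeric(1), "x_star")
    i <- which.min((xs - cent[1])^2 + (xs - cent[2])^2)
    center <- c(xs[i], xs[i])
  }
  dx <- s[, 1] - center[1]; dy <- s[, 2] - center[2]
  # angle increments between consecutive displacement vectors
  cross <- dx[-nrow(s)] * dy[-1] - dy[-nrow(s)] * dx[-1]
  dot <- dx[-nrow(s)] * dx[-1] + dy[-nrow(s)] * dy[-1]
  dtheta <- atan2(cross, dot)
  w <- abs(sum(dtheta)) / (2 * pi * length(dtheta))
  # periodicity: smallest Q <= maxQ with recurrence along the orbit
  n <- nrow(s)
  for (Q in seq_len(min(maxQ, n - 1))) {
    m <- min(n - Q, 4 * Q)
    if (max(abs(s[seq_len(m) + Q, ] - s[seq_len(m), ])) < tol) {
      P <- round(w * Q)
      return(list(w = P / Q, P = as.integer(P), Q = as.integer(Q),
                  exact = TRUE))
    }
  }
  list(w = w, exact = FALSE)
}
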