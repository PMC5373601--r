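## Closed-form equilibria and linear stability for both model cases.
##
## A fixed point satisfies x* = p0/p with p0 the numerator of the gain
## argument evaluated at the FP ((1-K)x* + H in case I, (1-K)x* + z* in
## case II) and p = T + |p0|.  Writing s = sign(p0) turns the FP identity
## into a quadratic per branch s; admissible roots must be real, lie in
## [-1, 1] and have sign(p0) = s.  The degenerate branch p0 = 0 (the origin
## when the bias vanishes) is handled as its own explicit root because s is
## undefined there.

RESIDUAL_TOL <- 1e-12
MARGINAL_TOL <- 1e-3

# residual of the one-step map identity at a candidate FP
fp_residual <- function(x, z, params) {
  u <- (x - params$K * x + z + params$H) / params$T
  abs(x - gain_fun(u, params$gain))
}

solve_quadratic_real <- function(A, B, C) {
  # real roots of A x^2 + B x + C = 0, robust to A ~ 0
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) return(numeric(0))
    return(-C / B)
  }
  disc <- B * B - 4 * A * C
  if (disc < 0) return(numeric(0))
  # Citardauq on the small root to avoid cancellation
  q <- -(B + sign(if (B != 0) B else 1) * sqrt(disc)) / 2
  r <- c(q / A, if (q != 0) C / q else -B / A - q / A)
  unique(r)
}

fp_record <- function(x, z, s, params) {
  p0 <- (1 - params$K) * x + z + params$H
  p <- params$T + abs(p0)
  ev <- if (model_case(params) == "I") {
    eigenvalues_case1(x, params)
  } else {
    eigenvalues_case2(x, z, params)$values
  }
  cls <- classify_stability(ev)
  list(x_star = x, y_star = x, z_star = z, s = s, p0 = p0, p = p,
       alpha = if (params$delta > 0) params$lambda / params$delta else NA_real_,
       eigenvalues = ev, stability = cls$stability, marginal = cls$marginal,
       residual = fp_residual(x, z, params))
}

dedup_roots <- function(xs, tol = RESIDUAL_TOL) {
  keep <- numeric(0)
  for (x in xs) if (!length(keep) || min(abs(keep - x)) > tol)
    keep <- c(keep, x)
  keep
}

#' Fixed points of the 2-D fast subsystem (case I)
#'
#' All equilibria of the KTLog map with frozen slow current.  Per branch
#' sign `s = sign(p0)` the FP identity reduces to the quadratic
#' \deqn{s(1-K)\,x^2 + (K + T + sH - 1)\,x - H = 0,}
#' whose admissible roots (real, `|x*| <= 1`, consistent branch sign) are
#' kept; for `H = 0` the origin is added as the explicit `p0 = 0` root.
#' When `K = 1` the quadratic degenerates to a linear equation, solved
#' directly.
#'
#' @param params a case-I [ktz_params()] (`delta = lambda = 0`).
#' @return An object of class `ktz_fixed_points`: a list of records with
#'   `x_star`, `y_star`, `z_star`, branch `s`, `p0`, `p`, `eigenvalues`,
#'   `stability` and the map-identity `residual` (always <= 1e-12).
#' @examples
#' fps <- fixed_points_case1(ktz_params(K = 0.6, T = 0.3))
#' sapply(fps, `[[`, "x_star")   # 0, +0.25, -0.25
#' @export
fixed_points_case1 <- function(params) {
  stopifnot(inherits(params, "ktz_params"))
  if (model_case(params) != "I")
    stop("fixed_points_case1 requires delta = lambda = 0")
  K <- params$K; T <- params$T; H <- params$H
  xs <- list()
  for (s in c(1, -1)) {
    roots <- solve_quadratic_real(s * (1 - K), K + T + s * H - 1, -H)
    for (x in roots) {
      if (!is.finite(x) || abs(x) > 1 + RESIDUAL_TOL) next
      p0 <- (1 - K) * x + H
      if (sign(p0) != s) next          # branch-sign admissibility
      xs <- c(xs, list(list(x = x, s = s)))
    }
  }
  if (H == 0) xs <- c(xs, list(list(x = 0, s = 0)))  # degenerate p0 = 0 root
  xv <- dedup_roots(vapply(xs, `[[`, numeric(1), "x"))
  recs <- lapply(xv, function(x) {
    s <- xs[[which.min(abs(vapply(xs, `[[`, numeric(1), "x") - x))]]$s
    r <- fp_record(x, 0, s, params)
    if (r$residual > RESIDUAL_TOL)
      stop("fixed-point residual above tolerance: ", r$residual)
    r
  })
  structure(recs[order(vapply(recs, `[[`, numeric(1), "x_star"))],
            class = "ktz_fixed_points")
}

#' Eigenvalues of a case-I fixed point
#'
#' Roots of the characteristic quadratic
#' \eqn{\Lambda^2 - (T/p^2)\Lambda + KT/p^2 = 0} with
#' `p = T + |(1-K)x* + H|`.  The pair is complex for `K > 0.5` at the
#' `H = 0` origin, which is what permits oscillatory attractors.
#'
#' @param x_star fixed-point coordinate (from [fixed_points_case1()]).
#' @param params a case-I [ktz_params()].
#' @return Complex vector of length 2, sorted by decreasing modulus.
#' @export
eigenvalues_case1 <- function(x_star, params) {
  K <- params$K; T <- params$T
  p0 <- (1 - K) * x_star + params$H
  p <- T + abs(p0)
  b <- T / p^2; c <- K * T / p^2
  disc <- as.complex(b * b - 4 * c)
  ev <- c(b + sqrt(disc), b - sqrt(disc)) / 2
  ev[order(-Mod(ev))]
}

#' Fixed points of the full 3-D model (case II)
#'
#' Equilibria of the KTzLog map (`H = 0`).  At a fixed point the slow
#' current settles at \eqn{z^* = (x_R - x^*)\lambda/\delta}; substituting it
#' for the bias in the case-I quadratic gives, with \eqn{\alpha =
#' \lambda/\delta},
#' \deqn{s(1-K-\alpha) x^2 + (T + s x_R \alpha - 1 + K + \alpha)x
#'   - \alpha x_R = 0.}
#' Admissibility is as in case I with `z*` in place of `H`.  The set is
#' exactly negated under `xR -> -xR`.
#'
#' @param params a case-II [ktz_params()] with `delta > 0` (a zero `delta`
#'   with positive `lambda` leaves `z` unbounded and is an error).
#' @return A `ktz_fixed_points` list, as for [fixed_points_case1()].
#' @examples
#' p <- ktz_params(K = 0.6, T = 0.35, delta = 0.001, lambda = 0.001,
#'                 xR = -0.5)
#' fixed_points_case2(p)[[1]]$x_star   # about -0.417
#' @export
fixed_points_case2 <- function(params) {
  stopifnot(inherits(params, "ktz_params"))
  if (params$H != 0) stop("case II requires H = 0")
  if (params$delta == 0) {
    if (params$lambda > 0)
      stop("delta = 0 with lambda > 0: alpha undefined, z* diverges")
    return(fixed_points_case1(params))
  }
  K <- params$K; T <- params$T; xR <- params$xR
  al <- params$lambda / params$delta
  xs <- list()
  for (s in c(1, -1)) {
    roots <- solve_quadratic_real(s * (1 - K - al),
                                  T + s * xR * al - 1 + K + al,
                                  -al * xR)
    for (x in roots) {
      if (!is.finite(x) || abs(x) > 1 + RESIDUAL_TOL) next
      z <- (xR - x) * al
      p0 <- (1 - K) * x + z
      if (sign(p0) != s) next
      xs <- c(xs, list(list(x = x, s = s)))
    }
  }
  if (al * xR == 0) xs <- c(xs, list(list(x = 0, s = 0)))
  xv <- dedup_roots(vapply(xs, `[[`, numeric(1), "x"))
  recs <- lapply(xv, function(x) {
    s <- xs[[which.min(abs(vapply(xs, `[[`, numeric(1), "x") - x))]]$s
    r <- fp_record(x, (xR - x) * al, s, params)
    if (r$residual > RESIDUAL_TOL)
      stop("fixed-point residual above tolerance: ", r$residual)
    r
  })
  structure(recs[order(vapply(recs, `[[`, numeric(1), "x_star"))],
            class = "ktz_fixed_points")
}

#' Closed-form Q2 candidates for the case-II fixed points
#'
#' The explicit quadratic-formula form of the case-II roots,
#' \deqn{x^\pm = \frac{s}{2(1-K-\alpha)}\Big[1-K-T-\alpha(s x_R + 1)
#'  \pm \sqrt{(T+K+\alpha-1)^2 + 2 s x_R \alpha (1-K-\alpha+T)
#'  + \alpha^2 x_R^2}\Big],}
#' kept as an independent cross-check of the coefficient-based solver used
#' by [fixed_points_case2()].  Returns all four candidates (both branches,
#' both signs), without admissibility filtering; `NA` where complex.
#'
#' @param params a case-II [ktz_params()].
#' @return A 4-row data frame with columns `s` and `x`.
#' @keywords internal
#' @export
fixed_points_case2_closed_form <- function(params) {
  K <- params$K; T <- params$T; xR <- params$xR
  al <- params$lambda / params$delta
  out <- expand.grid(s = c(1, -1), pm = c(1, -1))
  out$x <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- out$s[i]; pm <- out$pm[i]
    rad <- (T + K + al - 1)^2 + 2 * s * xR * al * (1 - K - al + T) +
      al^2 * xR^2
    if (rad < 0) next
    out$x[i] <- s / (2 * (1 - K - al)) *
      (1 - K - T - al * (s * xR + 1) + pm * sqrt(rad))
  }
  out[, c("s", "x")]
}

#' Eigenvalues of a case-II fixed point
#'
#' The three roots of the characteristic cubic
#' \deqn{p^2\Lambda^3 - [T + (1-\delta)p^2]\Lambda^2
#'   + T(K+\lambda+1-\delta)\Lambda - KT(1-\delta) = 0,}
#' with `p = T + |(1-K)x* + z*|`.  Roots are computed both by a numeric
#' polynomial solver (authoritative) and by the Cardano closed form
#' (cross-check); away from branch-cut degeneracies the two agree to 1e-8
#' relative.  At `delta = lambda = 0` the cubic factorises as
#' \eqn{(\Lambda-1)(p^2\Lambda^2 - T\Lambda + KT)}, i.e. the case-I pair
#' plus a unit eigenvalue for the frozen `z` direction.
#'
#' @param x_star,z_star fixed-point coordinates.
#' @param params the [ktz_params()] used.
#' @return List with `values` (complex, sorted by decreasing modulus,
#'   numeric roots) and `detail` (class `ktz_eigen_detail`: closed-form
#'   roots, Cardano intermediates `B`, `C`, `D`, `U`, `R`, and the maximum
#'   relative disagreement `cross_error`).
#' @export
eigenvalues_case2 <- function(x_star, z_star, params) {
  K <- params$K; T <- params$T; del <- params$delta; lam <- params$lambda
  p0 <- (1 - K) * x_star + z_star + params$H
  p <- T + abs(p0)
  a3 <- p^2
  a2 <- -(T + (1 - del) * p^2)
  a1 <- T * (K + lam + 1 - del)
  a0 <- -K * T * (1 - del)
  num <- polyroot(c(a0, a1, a2, a3))
  num <- num[order(-Mod(num))]

  # Cardano closed form; U = -(b^2 - 3ac), R = -(2b^3 - 9abc + 27a^2 d)
  U <- 3 * a3 * a1 - a2^2
  R <- -(2 * a2^3 - 9 * a3 * a2 * a1 + 27 * a3^2 * a0)
  B <- -a2 / (3 * a3)
  S <- as.complex((-R + sqrt(as.complex(R^2 + 4 * U^3))) / 2)^(1 / 3)
  w <- exp(2i * pi / 3)
  closed <- if (Mod(S) < 1e-300) {
    rep(as.complex(B), 3)                     # triple root
  } else {
    vapply(0:2, function(k) {
      Sk <- S * w^k
      B - (Sk - U / Sk) / (3 * a3) * 1 + 0i   # Lambda_k
    }, complex(1))
  }
  closed <- closed[order(-Mod(closed))]
  # nearest-neighbour pairing (conjugate pairs sort arbitrarily by modulus)
  scale <- max(Mod(num), 1)
  cross <- max(vapply(num, function(z) min(Mod(closed - z)), numeric(1))) /
    scale
  detail <- structure(list(closed_form = closed, numeric_roots = num,
                           B = B, C = S / (3 * a3), D = U / (3 * a3 * S),
                           U = U, R = R, cross_error = cross,
                           method = "numeric_roots"),
                      class = "ktz_eigen_detail")
  list(values = num, detail = detail)
}

#' Stability classification from eigenvalues
#'
#' A fixed point is `stable` when all eigenvalue moduli are below 1.
#' Otherwise it is a `saddle` when the spectrum is real with moduli
#' straddling 1 (some contracting, some expanding directions), else
#' `unstable`.  Complex pairs are classified by modulus only.  Spectra with
#' `max|Lambda|` within 1e-3 of 1 are flagged `marginal` (linearisation is
#' inconclusive there).
#'
#' @param eigenvalues complex vector.
#' @param simulate_check optionally verify by simulation: perturb the FP by
#'   1e-6 and iterate; stable FPs must re-converge, unstable ones depart.
#'   Supply a list `list(params =, fp =)` to enable.
#' @param n_check iterations for the simulation check.
#' @return List with `stability` (`"stable"`, `"unstable"`, `"saddle"`),
#'   `marginal` flag, and `sim_agrees` (`NA` unless checked).
#' @export
classify_stability <- function(eigenvalues, simulate_check = NULL,
                               n_check = 1e4) {
  m <- Mod(eigenvalues)
  marginal <- abs(max(m) - 1) <= MARGINAL_TOL
  all_real <- all(abs(Im(eigenvalues)) <= 1e-10 * pmax(m, 1))
  stability <- if (max(m) < 1) "stable"
  else if (all_real && min(m) < 1 && max(m) > 1) "saddle"
  else "unstable"
  sim_agrees <- NA
  if (!is.null(simulate_check) && !marginal) {
    params <- simulate_check$params; fp <- simulate_check$fp
    init <- ktz_state(fp$x_star + 1e-6, fp$y_star, fp$z_star)
    tr <- simulate_ktz(params, init, n_steps = 1L, discard = n_check)
    dist <- sqrt(sum((tr$states[1, ] -
                        c(fp$x_star, fp$y_star, fp$z_star))^2))
    sim_agrees <- if (stability == "stable") dist < 1e-6 else dist > 1e-6
  }
  list(stability = stability, marginal = marginal, sim_agrees = sim_agrees)
}

#' Analytic stability-limit curves of the fast subsystem
#'
#' For `H = 0` in the K-T plane the three limits are the supercritical
#' pitchfork `T = 1 - K` (`K <= 0.5`), the supercritical Neimark-Sacker
#' line `T = K` (`K > 0.5`) and the subcritical Neimark-Sacker curve
#' `T = 1/K + K - 2 = (1-K)^2/K` (`0.5 <= K <= 1`).  All three intersect at
#' `(K, T) = (0.5, 0.5)`, and the subcritical curve vanishes at `K = 1`.
#'
#' @param K_range numeric vector of K values (> 0) to sample.
#' @return A data frame with columns `kind` (`"pitchfork"`, `"NS_super"`,
#'   `"NS_sub"`), `K` and `T` (rows outside each curve's K-validity range
#'   are omitted).
#' @examples
#' bc <- boundary_curves_case1(c(0.5, 1))
#' subset(bc, K == 0.5)   # all three kinds give T = 0.5
#' @export
boundary_curves_case1 <- function(K_range) {
  stopifnot(all(K_range > 0))
  K <- sort(unique(as.numeric(K_range)))
  pieces <- list(
    data.frame(kind = "pitchfork", K = K[K <= 0.5], T = 1 - K[K <= 0.5]),
    data.frame(kind = "NS_super", K = K[K >= 0.5], T = K[K >= 0.5]),
    data.frame(kind = "NS_sub", K = K[K >= 0.5 & K <= 1],
               T = 1 / K[K >= 0.5 & K <= 1] + K[K >= 0.5 & K <= 1] - 2)
  )
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fixed-point stability limits in the T-H plane
#'
#' The saddle-node / Neimark-Sacker limit curves for fixed `K`, re-derived
#' from the stability condition `max|Lambda| = 1` applied to the case-I
#' eigenvalue quadratic.  On the limit, `p = T/(1-|x*|)` combines with
#' `p^2 = (1-K)T` (real eigenvalue, `K < 0.5`) or `p^2 = KT` (complex pair,
#' `K >= 0.5`) to give
#' \deqn{x^* = \pm\big(1 - \sqrt{T/(1-K)}\big),\quad
#'   H = \big[\sqrt{(1-K)T} + K - 1\big]x^* \qquad (K < 0.5)}
#' \deqn{x^* = \pm\big(1 - \sqrt{T/K}\big),\quad
#'   H = \big[\sqrt{KT} + K - 1\big]x^* \qquad (K \ge 0.5).}
#' For `H = 0` these reduce to the three curves of
#' [boundary_curves_case1()].
#'
#' @param K fixed gain coupling.
#' @param T_range numeric vector of T values to sample (only values below
#'   the curve's existence limit, `1 - K` or `K`, are kept).
#' @return Data frame with columns `kind` (`"saddle_node"` for `K < 0.5`,
#'   `"NS_sub"` for `K >= 0.5`), `K`, `T`, `H` and `x_star`; both `+/-`
#'   branches are included.
#' @export
boundary_curves_TH <- function(K, T_range) {
  stopifnot(length(K) == 1L, K > 0)
  Tv <- sort(unique(as.numeric(T_range)))
  if (K < 0.5) {
    Tv <- Tv[Tv > 0 & Tv <= 1 - K]
    xs <- 1 - sqrt(Tv / (1 - K))
    H <- (sqrt((1 - K) * Tv) + K - 1) * xs
    kind <- "saddle_node"
  } else {
    Tv <- Tv[Tv > 0 & Tv <= K]
    xs <- 1 - sqrt(Tv / K)
    H <- (sqrt(K * Tv) + K - 1) * xs
    kind <- "NS_sub"
  }
  out <- rbind(data.frame(kind = kind, K = K, T = Tv, H = H, x_star = xs),
               data.frame(kind = kind, K = K, T = Tv, H = -H, x_star = -xs))
  rownames(out) <- NULL
  out
}

#' Quasi-static FP stability limit of the full model
#'
#' Treating the slow current adiabatically (`z` frozen at `z* =
#' (x_R - x*) lambda/delta`) maps the case-II boundary onto the case-I one
#' and yields, for `0 < delta = lambda << 1`, the pair of critical reversal
#' values \eqn{x_R = \pm(K - T)}.  The true supercritical Neimark-Sacker
#' boundary lies within O(delta) of this line.
#'
#' @param K,T model parameters.
#' @return Numeric vector `c(-(K - T), K - T)`.
#' @examples quasistatic_boundary(0.6, 0.2)  # -0.4, 0.4
#' @export
quasistatic_boundary <- function(K, T) c(-(K - T), K - T)

#' @export
print.ktz_fixed_points <- function(x, ...) {
  cat(sprintf("%d fixed point(s):\n", length(x)))
  for (r in x) {
    cat(sprintf("  x* = %+0.6f  z* = %+0.6f  s = %+d  %s%s  max|L| = %.4f\n",
                r$x_star, r$z_star, r$s, r$stability,
                if (r$marginal) " (marginal)" else "",
                max(Mod(r$eigenvalues))))
  }
  invisible(x)
}

#' @export
as.data.frame.ktz_fixed_points <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(x_star = r$x_star, y_star = r$y_star, z_star = r$z_star,
               s = r$s, p0 = r$p0, p = r$p,
               max_mod = max(Mod(r$eigenvalues)),
               stability = r$stability, marginal = r$marginal,
               residual = r$residual)
  }))
}
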