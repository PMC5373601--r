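# shared parameter sets
p_chaosB <- function() ktz_params(K = 0.89, T = 0.009)   # strange attractor
p_chaosA <- function() ktz_params(K = 0.991, T = 0.1, H = -0.259795918367347)
p_case2 <- function(T, xR, delta = 0.001, lambda = 0.001)
  ktz_params(K = 0.6, T = T, delta = delta, lambda = lambda, xR = xR)

# brute-force fixed-point oracle for case I: sign changes of the map-identity
# residual g(x) = x - f(((1-K)x + H)/T) on a fine grid, refined by bisection
fp_scan_oracle <- function(params, n = 20001, tol = 1e-12) {
  g <- function(x) {
    u <- ((1 - params$K) * x + params$H) / params$T
    x - logistic_gain(u)
  }
  xs <- seq(-1, 1, length.out = n)
  gx <- g(xs)
  roots <- c()
  for (i in seq_len(n - 1)) {
    if (gx[i] == 0) roots <- c(roots, xs[i])
    else if (sign(gx[i]) * sign(gx[i + 1]) < 0) {
      lo <- xs[i]; hi <- xs[i + 1]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  sort(unique(round(roots, 10)))
}
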