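# Shared in-code fixtures.

# hand-countable 3-point pattern in a 2 x 2 window
toy_pattern <- function() {
  point_pattern(c(0.5, 1.5, 1.5), c(0.5, 0.5, 1.5), landscape(2, 2))
}

# an exactly-n uniform pattern (not Poisson), for deterministic counts
uniform_pattern <- function(n, ls, seed = 1L) {
  set.seed(seed)
  point_pattern(runif(n, 0, ls$width), runif(n, 0, ls$height), ls)
}

# numerical 1-D power-law variance oracle: the within-interval pair excess
# 2 * int_0^A (A - t) (Omega(t) - 1) dt; the self-pair atom cancels the
# Poisson term for b > 1, while b = 1 is the exact CSR branch (sigma^2 = A)
powerlaw_var_1d_numeric <- function(model, A) {
  if (model$b == 1 && model$a == 1) return(A)
  vapply(A, function(a)
    2 * integrate(function(t) (a - t) * (powerlaw_omega_1d(model, t) - 1),
                  0, a, rel.tol = 1e-10)$value, numeric(1))
}

# numerical 1-D two-interval covariance oracle: triangular-weighted
# cross-pair excess over separations [D, D + 2A]
powerlaw_cov_1d_numeric <- function(model, A, D) {
  vapply(D, function(d)
    integrate(function(u)
      (A - abs(u - (d + A))) * (powerlaw_omega_1d(model, u) - 1),
      d, d + 2 * A, rel.tol = 1e-10)$value, numeric(1))
}
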