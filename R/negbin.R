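#' Negative binomial marginal from moments
#'
#' Moment-matches a negative binomial quadrat-count distribution:
#' `k = mu^2 / (var - mu)`, `p = mu / var` (so mean `k (1-p)/p` and
#' variance `k (1-p)/p^2`).  When `var` is within tolerance of `mu` the
#' Poisson limit is returned, flagged by `poisson = TRUE` (the zero class
#' is then `exp(-mu)`).  Underdispersion beyond tolerance is an error: no
#' negative binomial has variance below its mean.
#'
#' @param mu Mean (`> 0`).
#' @param var Variance.
#' @param tol Relative tolerance for the Poisson branch,
#'   `|var - mu| <= tol * mu`.
#' @return An object of class `nb_marginal`: list with `k`, `p`, `mu`,
#'   `var`, `poisson`.
#' @export
nb_from_moments <- function(mu, var, tol = 1e-9) {
  stopifnot(is.finite(mu), is.finite(var))
  if (mu <= 0) stop("mu must be positive")
  if (abs(var - mu) <= tol * mu)
    return(structure(list(k = Inf, p = 1, mu = mu, var = mu,
                          poisson = TRUE), class = "nb_marginal"))
  if (var < mu)
    stop("underdispersed moments (var < mu): no negative binomial exists")
  structure(list(k = mu^2 / (var - mu), p = mu / var, mu = mu, var = var,
                 poisson = FALSE), class = "nb_marginal")
}

#' Occupancy probability under a negative binomial quadrat count
#'
#' `Psi = 1 - P(n = 0) = 1 - p^k = 1 - (mu/var)^(mu^2/(var - mu))`, the
#' closed-form occupancy-area relation for moment-matched negative
#' binomial counts, with the Poisson limit `1 - exp(-mu)` at `var = mu`.
#'
#' @inheritParams nb_from_moments
#' @return Occupancy probability in `(0, 1)`.
#' @examples
#' occupancy_nb(1, 2)  # k = 1, p = 0.5: Psi = 0.5
#' @export
occupancy_nb <- function(mu, var, tol = 1e-9) {
  nb <- nb_from_moments(mu, var, tol)
  if (nb$poisson) 1 - exp(-mu) else 1 - nb$p^nb$k
}

#' Three-component bivariate negative binomial from moments
#'
#' Constructs the joint quadrat-count distribution for two plots as
#' `(U + S, V + S)` where `U`, `V`, `S` are independent negative binomials
#' sharing a common success probability `p`: `S` is the population common
#' to both plots (it carries all the covariance), `U` and `V` the
#' populations private to each plot.  With
#' `k = mu^2/(var - mu)`, `p = mu/var`, the decomposition is
#' `k_s = k * cov / var` and `k_u = k_v = k - k_s`, which (by convolution
#' closure at shared `p`) keeps both marginals exactly `NB(k, p)` and gives
#' `Cov = k_s (1-p)/p^2 = cov`.  This shared-`p` choice is the unique one
#' that reproduces the closed-form turnover expression (see
#' [turnover_nb()]); the construction cannot represent negative or
#' super-marginal covariance.
#'
#' @inheritParams nb_from_moments
#' @param cov Covariance between the two plot counts, in `[0, var]`.
#' @return An object of class `bivariate_nb`: list with `k_u`, `k_v`,
#'   `k_s`, `p`, plus the generating moments.
#' @export
bivariate_from_moments <- function(mu, var, cov, tol = 1e-9) {
  nb <- nb_from_moments(mu, var, tol)
  if (nb$poisson)
    stop("bivariate construction requires strict overdispersion (var > mu)")
  if (!is.finite(cov) || cov < 0 || cov > var)
    stop("cov must lie in [0, var]: the three-component construction ",
         "cannot represent negative or super-marginal covariance")
  k_s <- nb$k * cov / var
  structure(list(k_u = nb$k - k_s, k_v = nb$k - k_s, k_s = k_s, p = nb$p,
                 k = nb$k, mu = mu, var = var, cov = cov),
            class = "bivariate_nb")
}

#' Joint probability that both plots are empty
#'
#' For the three-component construction, `n = U + S` and `n' = V + S` are
#' simultaneously zero iff all three components are zero, so
#' `P(0, 0) = p^(k_u + k_v + k_s) = p^(2k - k_s)`.
#'
#' @param params A [bivariate_from_moments()] object.
#' @return Probability.
#' @export
joint_zero_prob <- function(params) {
  stopifnot(inherits(params, "bivariate_nb"))
  params$p^(params$k_u + params$k_v + params$k_s)
}

#' Two-plot turnover under the bivariate negative binomial
#'
#' The probability that both plots are occupied divided by single-plot
#' occupancy, `T = 2 + (P(0,0) - 1) / Psi`.  Written out with
#' `P(0,0) = p^(2k - k_s)` this is the closed form
#' \deqn{T = 2 + \frac{1}{\Psi}\left[\left(\frac{\mu}{\sigma^2}\right)
#'   ^{\mu^2 (2\sigma^2 - C) / (\sigma^2(\sigma^2 - \mu))} - 1\right]}
#' the two expressions are the same object (an identity the test suite
#' checks to 1e-12).  Independence (`cov = 0`) gives `T = Psi`; identical
#' plots (`cov = var`) give `T = 1`.
#'
#' @inheritParams bivariate_from_moments
#' @return Turnover in `[Psi, 1]`.
#' @examples
#' turnover_nb(1, 2, 1)  # 2 + (0.5^1.5 - 1) / 0.5
#' @export
turnover_nb <- function(mu, var, cov, tol = 1e-9) {
  psi <- occupancy_nb(mu, var, tol)
  if (abs(var - mu) <= tol * mu)   # Poisson limit, independence forced
    return(2 + (exp(-(2 * mu - cov)) - 1) / psi)
  params <- bivariate_from_moments(mu, var, cov, tol)
  2 + (joint_zero_prob(params) - 1) / psi
}

#' Sample joint quadrat counts from the bivariate construction
#'
#' Draws `(U + S, V + S)` with `U, V, S` independent negative binomials at
#' the shared success probability.  Used as a Monte Carlo oracle for the
#' analytic zero-class and turnover formulas.
#'
#' @param params A [bivariate_from_moments()] object.
#' @param n_draws Number of joint draws.
#' @param seed Optional seed.
#' @return `n_draws x 2` integer matrix of `(n, n')`.
#' @export
sample_bivariate <- function(params, n_draws, seed = NULL) {
  stopifnot(inherits(params, "bivariate_nb"))
  rnb <- function(k) if (k == 0) integer(n_draws) else
    stats::rnbinom(n_draws, size = k, prob = params$p)
  with_seed(seed, {
    s <- rnb(params$k_s)
    cbind(rnb(params$k_u) + s, rnb(params$k_v) + s)
  })
}
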