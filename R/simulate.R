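#' Thomas cluster process parameters
#'
#' The Thomas process places cluster centres by a Poisson process with
#' intensity `rho`, draws the number of individuals per cluster from a
#' Poisson distribution with mean `mu_cluster`, and displaces each
#' individual from its centre by independent bivariate normal scatter with
#' standard deviation `sigma_cluster` on each axis.
#'
#' @param rho Cluster-centre intensity (centres per unit area).
#' @param mu_cluster Mean number of individuals per cluster.
#' @param sigma_cluster Within-cluster displacement standard deviation
#'   (length units).
#' @return An object of class `thomas_params`.
#' @seealso [simulate_thomas()], [thomas_from_alpha_beta()]
#' @export
thomas_params <- function(rho, mu_cluster, sigma_cluster) {
  vals <- c(rho = rho, mu_cluster = mu_cluster, sigma_cluster = sigma_cluster)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("thomas_params: rho, mu_cluster and sigma_cluster must be positive")
  structure(as.list(vals), class = "thomas_params")
}

#' @export
print.thomas_params <- function(x, ...) {
  cat(sprintf("Thomas process: rho = %.4g, mu = %.4g, sigma = %.4g\n",
              x$rho, x$mu_cluster, x$sigma_cluster))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Simulate complete spatial randomness
#'
#' Homogeneous Poisson process: the point count is Poisson(`expected_n`) and
#' locations are i.i.d. uniform on the window.
#'
#' @param expected_n Expected number of points (> 0).
#' @param landscape A [landscape()].
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return A `spat_pattern`.
#' @export
simulate_csr <- function(expected_n, landscape, seed = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  if (!is.finite(expected_n) || expected_n <= 0)
    stop("expected_n must be positive")
  with_seed(seed, {
    n <- stats::rpois(1L, expected_n)
    point_pattern(stats::runif(n, 0, landscape$width),
                  stats::runif(n, 0, landscape$height), landscape)
  })
}

#' Simulate a Thomas cluster process
#'
#' Parent centres are generated on a window buffered by `buffer_sd` cluster
#' standard deviations on every side, so that clusters centred just outside
#' the window still contribute offspring inside it; only offspring falling
#' inside the unbuffered window are retained.  With the default 5-sigma
#' buffer the neglected normal tail mass is below 1e-6.
#'
#' Total abundance is Poisson-random, not conditioned on a target count.
#' Pass `fixed_n` to thin (or augment with additional clusters) to an exact
#' count; this departs from the plain process and is reported via a message.
#'
#' @param params A [thomas_params()].
#' @param landscape A [landscape()].
#' @param seed Optional integer seed.
#' @param fixed_n Optional exact point count to return.
#' @param buffer_sd Parent buffer width in units of `sigma_cluster`.
#' @return A `spat_pattern`.
#' @export
simulate_thomas <- function(params, landscape, seed = NULL, fixed_n = NULL,
                            buffer_sd = 5) {
  stopifnot(inherits(params, "thomas_params"), inherits(landscape, "landscape"))
  with_seed(seed, {
    xy <- thomas_points(params, landscape, buffer_sd)
    if (!is.null(fixed_n)) {
      fixed_n <- as.integer(fixed_n)
      if (nrow(xy) > fixed_n) {
        xy <- xy[sample.int(nrow(xy), fixed_n), , drop = FALSE]
      } else while (nrow(xy) < fixed_n) {
        xy <- rbind(xy, thomas_points(params, landscape, buffer_sd))
        if (nrow(xy) > fixed_n)
          xy <- xy[sample.int(nrow(xy), fixed_n), , drop = FALSE]
      }
      message("thinned/augmented to exactly n = ", fixed_n,
              " (non-default; plain Thomas abundance is Poisson)")
    }
    point_pattern(xy[, 1L], xy[, 2L], landscape)
  })
}

# one unconditioned draw of retained offspring coordinates
thomas_points <- function(params, landscape, buffer_sd) {
  buf <- buffer_sd * params$sigma_cluster
  bw <- landscape$width + 2 * buf
  bh <- landscape$height + 2 * buf
  n_par <- stats::rpois(1L, params$rho * bw * bh)
  px <- stats::runif(n_par, -buf, landscape$width + buf)
  py <- stats::runif(n_par, -buf, landscape$height + buf)
  n_off <- stats::rpois(n_par, params$mu_cluster)
  x <- rep.int(px, n_off) + stats::rnorm(sum(n_off), 0, params$sigma_cluster)
  y <- rep.int(py, n_off) + stats::rnorm(sum(n_off), 0, params$sigma_cluster)
  keep <- x >= 0 & x <= landscape$width & y >= 0 & y <= landscape$height
  cbind(x[keep], y[keep])
}

#' Thomas parameters from Gaussian second-order-intensity parameters
#'
#' The Thomas process has pair correlation
#' `g(r) = exp(-r^2 / (4 sigma^2)) / (4 pi rho sigma^2) + 1`, i.e. a
#' Gaussian second-order intensity with `alpha = 1/(4 pi rho sigma^2)` and
#' `beta = 1/(4 sigma^2)` in units scaled so that `lambda = 1`.  Given
#' `(alpha, beta)` in scaled units and an expected landscape-wide abundance,
#' this inverts those relations and converts to landscape units via the
#' scale factor `s = sqrt(area / expected_n)`.
#'
#' @param alpha Dimensionless amplitude (> 0); invariant under rescaling.
#' @param beta Inverse squared length in scaled units (> 0).
#' @param expected_n Expected number of individuals in the window.
#' @param landscape A [landscape()] in original units.
#' @param rho_max Ceiling on the scaled cluster-centre intensity; as
#'   `alpha -> 0` the process degenerates towards CSR through an unbounded
#'   number of ever-sparser clusters, so values above the ceiling error.
#' @return A [thomas_params()] in landscape units.  The cluster mean
#'   `mu_cluster = pi * alpha / beta` is scale-free.
#' @examples
#' thomas_from_alpha_beta(4.5, 3.8, 108, landscape(500, 1000))
#' @export
thomas_from_alpha_beta <- function(alpha, beta, expected_n, landscape,
                                   rho_max = 1e6) {
  stopifnot(inherits(landscape, "landscape"))
  if (any(!is.finite(c(alpha, beta, expected_n))) ||
      alpha <= 0 || beta <= 0 || expected_n <= 0)
    stop("alpha, beta and expected_n must be positive")
  sigma2_sc <- 1 / (4 * beta)
  rho_sc <- beta / (pi * alpha)          # from alpha = 1/(4 pi rho sigma^2)
  if (rho_sc > rho_max)
    stop("scaled cluster intensity ", signif(rho_sc, 4), " exceeds rho_max; ",
         "the process is degenerating to CSR (alpha too small)")
  s <- sqrt(landscape$area / expected_n)
  thomas_params(rho = rho_sc / s^2,
                mu_cluster = 1 / rho_sc,  # = pi * alpha / beta
                sigma_cluster = sqrt(sigma2_sc) * s)
}

#' Gaussian second-order-intensity parameters of a Thomas process
#'
#' Inverse of [thomas_from_alpha_beta()]: converts landscape-unit Thomas
#' parameters to the scaled-unit `(alpha, beta)` pair, using the scale
#' factor implied by the process's expected abundance
#' `rho * mu_cluster * area`.
#'
#' @param params A [thomas_params()] in landscape units.
#' @param landscape The [landscape()] the parameters refer to.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
alpha_beta_from_thomas <- function(params, landscape) {
  stopifnot(inherits(params, "thomas_params"), inherits(landscape, "landscape"))
  n <- params$rho * params$mu_cluster * landscape$area
  s <- sqrt(landscape$area / n)
  rho_sc <- params$rho * s^2
  sigma2_sc <- params$sigma_cluster^2 / s^2
  c(alpha = 1 / (4 * pi * rho_sc * sigma2_sc), beta = 1 / (4 * sigma2_sc))
}
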