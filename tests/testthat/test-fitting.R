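test_that("noiseless curves from the Gaussian family are recovered", {
  truth <- gaussian_lambda2(2.30, 0.71)
  A <- exp(seq(log(0.2), log(8), length.out = 12))
  r <- seq(0.1, 3, length.out = 15)
  D <- seq(0, 3, length.out = 10)
  curves <- list(
    theory_curve(truth, "taylor", A),
    theory_curve(truth, "oring", r),
    theory_curve(truth, "occupancy", A),
    theory_curve(truth, "twoplot_cov", D, plot_side = 0.5),
    theory_curve(truth, "turnover", D, plot_side = 0.5))
  for (cv in curves) {
    f <- fit_gaussian_to_metric(cv)
    expect_true(f$converged)
    expect_equal(f$alpha, 2.30, tolerance = 1e-3)
    expect_equal(f$beta, 0.71, tolerance = 1e-3)
  }
})

test_that("parameter bias shrinks with the noise level", {
  truth <- gaussian_lambda2(2.0, 1.0)
  r <- seq(0.1, 3, length.out = 20)
  clean <- theory_curve(truth, "oring", r)
  set.seed(10)
  for (noise in c(0.05, 0.005)) {
    est <- replicate(10, {
      y <- clean$ordinate + rnorm(length(r), 0, noise)
      f <- fit_gaussian_to_metric(metric_curve("oring", r, y, 1L))
      c(f$alpha, f$beta)
    })
    bias <- abs(rowMeans(est) - c(2, 1))
    expect_lt(max(bias), 40 * noise)
  }
})

test_that("degenerate curves are flagged, not fitted", {
  flat <- metric_curve("oring", 1:5, rep(1, 5), 1L)
  f <- fit_gaussian_to_metric(flat)
  expect_false(f$converged)
  expect_error(fit_gaussian_to_metric(metric_curve("oring", 1:2, 1:2, 1L)),
               "at least 3")
})

test_that("minimum contrast recovers Thomas parameters and is invariant
           to coordinate units", {
  ls <- landscape(500, 1000)
  tp <- thomas_from_alpha_beta(2.7, 0.8, 800, ls)
  pat <- simulate_thomas(tp, ls, seed = 42L)
  f <- fit_thomas_mincontrast(pat)
  expect_true(f$converged)
  expect_equal(f$alpha, 2.7, tolerance = 0.5)
  expect_equal(f$beta, 0.8, tolerance = 0.5)
  # consistency of the derived Thomas fields
  expect_equal(f$rho, f$beta / (pi * f$alpha))
  # rescaled input gives the same scaled-unit estimates
  f2 <- fit_thomas_mincontrast(scale_pattern(pat, 3))
  expect_equal(f2$alpha, f$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, f$beta, tolerance = 1e-6)
})

test_that("CSR patterns are flagged as degenerate, not clustered", {
  p <- simulate_csr(2000, landscape(500, 1000), seed = 17L)
  f <- fit_thomas_mincontrast(p)
  # no clustering signal: either a vanishing amplitude or an unresolvable
  # spike below the kernel bandwidth, both reported as non-converged
  expect_false(f$converged)
  expect_error(fit_thomas_mincontrast(
    simulate_csr(3, landscape(10, 10), seed = 1L)), "at least 10")
})

test_that("cross-metric Spearman handles identity, reversal and nulls", {
  species <- sprintf("s%02d", 1:20)
  set.seed(2)
  v <- sort(runif(20))
  tab <- rbind(
    data.frame(species = species, metric = "taylor", alpha = v, beta = v),
    data.frame(species = species, metric = "oring", alpha = v, beta = rev(v)),
    data.frame(species = species, metric = "occupancy",
               alpha = sample(v), beta = sample(v)))
  out <- cross_metric_spearman(tab)
  pick <- function(m1, m2, par)
    out[out$metric1 == m1 & out$metric2 == m2 & out$parameter == par, ]
  expect_equal(pick("taylor", "oring", "alpha")$rho, 1)
  expect_equal(pick("taylor", "oring", "beta")$rho, -1)
  expect_lt(abs(pick("taylor", "occupancy", "alpha")$rho), 0.5)
  # fewer than 4 complete pairs -> undefined cell
  tab$alpha[tab$metric == "occupancy"][1:18] <- NA
  out2 <- cross_metric_spearman(tab)
  expect_true(is.na(
    out2[out2$metric1 == "taylor" & out2$metric2 == "occupancy" &
           out2$parameter == "alpha", "rho"]))
})
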