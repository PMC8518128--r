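test_that("CSR branches collapse to the analytic row at machine precision", {
  csr_g <- gaussian_lambda2(0, 1)
  csr_p <- powerlaw_tl(1, 1)
  A <- c(0.1, 1, 7); r <- c(0.2, 1, 5); D <- c(0, 1, 10)
  expect_identical(gaussian_var(csr_g, A), A)
  expect_identical(gaussian_cov(csr_g, 1, D), rep(0, 3))
  expect_equal(omega_from_lambda2(csr_g, r), rep(1, 3))
  expect_equal(powerlaw_var(csr_p, A), A)
  expect_equal(powerlaw_omega_2d(csr_p, r), rep(1, 3))
  expect_equal(powerlaw_cov_2d(csr_p, 1, D), rep(0, 3))
  expect_equal(powerlaw_cov_1d(csr_p, 1, D), rep(0, 3))
})

test_that("Gaussian closed forms agree with the numerical moment
           integrals over a parameter grid", {
  m <- gaussian_lambda2(2.30, 0.71)
  expect_equal(omega_from_lambda2(m, 0), 3.30)
  expect_equal(gaussian_var(m, 1), 2.84876, tolerance = 1e-5)
  for (A in c(0.25, 1, 4)) {
    expect_equal(gaussian_var(m, A), variance_from_lambda2(m, A),
                 tolerance = 1e-8)
    D <- c(0, 0.5, 1, 2)
    expect_equal(gaussian_cov(m, A, D),
                 covariance_from_lambda2(m, A, D), tolerance = 1e-5)
  }
  # Monte Carlo route agrees loosely with quadrature
  expect_equal(covariance_from_lambda2(m, 1, 0.5, method = "montecarlo",
                                       seed = 4L),
               covariance_from_lambda2(m, 1, 0.5), tolerance = 0.01)
})

test_that("Gaussian monotonicity properties hold", {
  m <- gaussian_lambda2(2.30, 0.71)
  D <- seq(0, 4, by = 0.25)
  expect_true(all(diff(gaussian_cov(m, 1, D)) <= 0))
  vars <- vapply(c(0.5, 1, 2, 4), function(al)
    gaussian_var(gaussian_lambda2(al, 0.71), 1) - 1, numeric(1))
  expect_true(all(diff(vars) > 0))
  expect_equal(gaussian_cov(m, 1, 60), 0, tolerance = 1e-12)
  expect_equal(omega_from_lambda2(m, 50), 1, tolerance = 1e-12)
})

test_that("1-D power-law closed forms match direct integration", {
  expect_equal(powerlaw_omega_1d(powerlaw_tl(1, 1.5), 1), 1.375)
  expect_equal(powerlaw_omega_1d(powerlaw_tl(1, 1), 3), 1)  # CSR
  # omega pushed through the 1-D moment identity returns a A^b: exact for
  # b = 2, quadrature-exact otherwise
  m2 <- powerlaw_tl(1, 2)
  expect_equal(powerlaw_var_1d_numeric(m2, c(0.5, 1, 3)),
               powerlaw_var(m2, c(0.5, 1, 3)), tolerance = 1e-12)
  for (b in c(1.2, 1.51, 1.8)) {
    m <- powerlaw_tl(0.88, b)
    A <- c(0.5, 1, 2, 5)
    expect_equal(powerlaw_var_1d_numeric(m, A), powerlaw_var(m, A),
                 tolerance = 1e-8)
    D <- c(0, 0.7, 2)
    expect_equal(powerlaw_cov_1d(m, 1, D),
                 powerlaw_cov_1d_numeric(m, 1, D), tolerance = 1e-8)
  }
  # hand values: a=1, b=2, A=1, D=0 gives (0 - 2 + 4)/2 = 1
  expect_equal(powerlaw_cov_1d(m2, 1, 0), 1)
  expect_equal(powerlaw_cov_1d(powerlaw_tl(2, 1), 1, c(0, 3)), c(0, 0))
})

test_that("2-D power-law amplitude makes the variance power law
           self-consistent and vanishes towards CSR", {
  m <- powerlaw_tl(0.88, 1.51)
  A <- c(0.5, 1, 2, 5, 20)
  expect_equal(variance_from_lambda2(m, A), powerlaw_var(m, A),
               tolerance = 1e-8)
  expect_lt(powerlaw_c2d(powerlaw_tl(1, 1.01)), 0.05)
  expect_error(powerlaw_c2d(powerlaw_tl(1, 2.5)), "strictly in")
  # Omega finite and decreasing for r > 0
  om <- powerlaw_omega_2d(m, c(0.1, 0.5, 1, 3))
  expect_true(all(is.finite(om)) && all(diff(om) < 0))
})

test_that("2-D power-law covariance approximation converges to the
           numerical integral in the far field", {
  m <- powerlaw_tl(0.88, 1.51)
  Dnear <- c(1, 2); Dfar <- c(8, 16)
  rel <- function(D) {
    cl <- powerlaw_cov_2d(m, 1, D)
    nm <- powerlaw_cov_2d(m, 1, D, method = "numeric")
    abs(cl - nm) / abs(nm)
  }
  expect_lt(max(rel(Dnear)), 0.10)
  expect_lt(max(rel(Dfar)), 0.01)
})

test_that("theory curves compose occupancy and turnover correctly", {
  m <- gaussian_lambda2(2.30, 0.71)
  A <- c(0.5, 1, 2)
  occ <- theory_curve(m, "occupancy", A)
  expect_equal(occ$ordinate,
               vapply(A, function(a) occupancy_nb(a, gaussian_var(m, a)),
                      numeric(1)))
  D <- c(0.5, 1, 2)
  tv <- theory_curve(m, "turnover", D, plot_side = 1)
  s2 <- gaussian_var(m, 1)
  expect_equal(tv$ordinate,
               vapply(D, function(d)
                 turnover_nb(1, s2, gaussian_cov(m, 1, d)), numeric(1)))
  expect_true(all(tv$ordinate <= 1 & tv$ordinate >= 0))
  # oring curve for the power-law family uses the 2-D approximation
  oc <- theory_curve(powerlaw_tl(0.88, 1.51), "oring", c(0.5, 1))
  expect_equal(oc$ordinate, powerlaw_omega_2d(powerlaw_tl(0.88, 1.51),
                                              c(0.5, 1)))
})
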