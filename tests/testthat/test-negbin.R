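test_that("moment inversion recovers negative binomial parameters", {
  nb <- nb_from_moments(1, 2)
  expect_equal(nb$k, 1)
  expect_equal(nb$p, 0.5)
  expect_false(nb$poisson)
  expect_true(nb_from_moments(1, 1)$poisson)
  expect_error(nb_from_moments(1, 0.5), "underdispersed")
  expect_error(nb_from_moments(0, 1), "positive")
})

test_that("occupancy closed form equals the NB zero class", {
  expect_equal(occupancy_nb(1, 2), 0.5)
  # Poisson limit by continuity
  expect_equal(occupancy_nb(2, 2), 1 - exp(-2))
  expect_equal(occupancy_nb(2, 2 + 1e-12), 1 - exp(-2))
  # pmf-at-zero oracle across a moment sweep
  for (mu in c(0.3, 1, 4)) for (vr in mu * c(1.5, 3, 10)) {
    nb <- nb_from_moments(mu, vr)
    expect_equal(occupancy_nb(mu, vr),
                 1 - dnbinom(0, size = nb$k, prob = nb$p),
                 tolerance = 1e-12)
  }
  # limits: Psi -> 0 as A -> 0; -> 1 as A grows with b < 2 scaling
  expect_lt(occupancy_nb(1e-8, 2e-8), 1e-7)
  expect_gt(occupancy_nb(500, 0.9 * 500^1.5), 0.999)
})

test_that("three-component decomposition reproduces the moments", {
  bv <- bivariate_from_moments(1, 2, 1)
  expect_equal(bv$k_s, 0.5)
  expect_equal(bv$k_u, 0.5)
  expect_equal(bv$k_s * (1 - bv$p) / bv$p^2, 1)   # covariance check
  expect_equal(bivariate_from_moments(1, 2, 0)$k_s, 0)
  ident <- bivariate_from_moments(1, 2, 2)
  expect_equal(ident$k_u, 0)
  expect_error(bivariate_from_moments(1, 2, -0.1), "cannot represent")
  expect_error(bivariate_from_moments(1, 2, 2.5), "cannot represent")
})

test_that("joint zero probability follows the shared-p product", {
  expect_equal(joint_zero_prob(bivariate_from_moments(1, 2, 1)), 0.5^1.5)
  # independence: P(0,0) = P(0)^2
  bv0 <- bivariate_from_moments(1, 2, 0)
  expect_equal(joint_zero_prob(bv0), (1 - occupancy_nb(1, 2))^2)
  # identical plots: P(0,0) = P(0)
  bv1 <- bivariate_from_moments(1, 2, 2)
  expect_equal(joint_zero_prob(bv1), 1 - occupancy_nb(1, 2))
})

test_that("turnover closed form and product construction are the same
           object over a randomized sweep", {
  expect_equal(turnover_nb(1, 2, 1), 2 + (0.5^1.5 - 1) / 0.5)
  set.seed(71)
  for (i in 1:300) {
    A <- runif(1, 0.05, 20)
    s2 <- A * (1 + runif(1, 1e-4, 20))
    C <- runif(1, 0, s2)
    # printed closed form, written out directly from the moments
    psi <- 1 - (A / s2)^(A^2 / (s2 - A))
    closed <- 2 + ((A / s2)^(A^2 * (2 * s2 - C) / (s2 * (s2 - A))) - 1) / psi
    expect_equal(turnover_nb(A, s2, C), closed, tolerance = 1e-12)
  }
})

test_that("turnover limits and bounds hold", {
  expect_equal(turnover_nb(1, 2, 0), occupancy_nb(1, 2))
  expect_equal(turnover_nb(1, 2, 2), 1)
  set.seed(8)
  for (i in 1:100) {
    A <- runif(1, 0.1, 10); s2 <- A * runif(1, 1.01, 8)
    C <- runif(1, 0, s2)
    tv <- turnover_nb(A, s2, C)
    psi <- occupancy_nb(A, s2)
    expect_true(tv >= psi - 1e-12 && tv <= 1 + 1e-12)
  }
  # T decreasing as covariance decays
  Cs <- seq(1.8, 0, by = -0.2)
  expect_true(all(diff(vapply(Cs, function(C) turnover_nb(1, 2, C),
                              numeric(1))) <= 0))
})

test_that("marginals of the construction stay negative binomial
           (convolution closure at shared p)", {
  bv <- bivariate_from_moments(2, 5, 2)
  n <- 0:200
  pmf_sum <- vapply(n, function(nn)
    sum(dnbinom(0:nn, size = bv$k_u, prob = bv$p) *
          dnbinom(nn - (0:nn), size = bv$k_s, prob = bv$p)), numeric(1))
  expect_equal(pmf_sum, dnbinom(n, size = bv$k, prob = bv$p),
               tolerance = 1e-12)
  expect_equal(sum(pmf_sum), 1, tolerance = 1e-8)
})

test_that("the bivariate sampler matches its analytic moments", {
  bv <- bivariate_from_moments(1, 2, 1)
  s1 <- sample_bivariate(bv, 1000L, seed = 5L)
  expect_identical(s1, sample_bivariate(bv, 1000L, seed = 5L))
  big <- sample_bivariate(bv, 1e5L, seed = 6L)
  se_mean <- sqrt(2 / 1e5)
  expect_lt(abs(mean(big[, 1]) - 1), 3 * se_mean)
  cv <- cov(big[, 1], big[, 2])
  expect_lt(abs(cv - 1), 3 * 0.02)   # bootstrap-scale SE for the covariance
  bv0 <- bivariate_from_moments(1, 2, 0)
  ind <- sample_bivariate(bv0, 1e5L, seed = 7L)
  expect_lt(abs(cor(ind[, 1], ind[, 2])), 0.02)
})
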