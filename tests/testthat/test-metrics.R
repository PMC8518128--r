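test_that("grid quadrat counts match hand counts on the toy pattern", {
  toy <- toy_pattern()
  expect_equal(sort(quadrat_counts(toy, 1)), c(0L, 1L, 1L, 1L))
  expect_equal(quadrat_counts(toy, 2), 3L)            # one tile = everything
  empty <- point_pattern(numeric(0), numeric(0), landscape(2, 2))
  expect_equal(quadrat_counts(empty, 1), rep(0L, 4))
  expect_error(quadrat_counts(toy, 3), "exceeds")
})

test_that("Taylor and occupancy curves reproduce toy hand computations", {
  toy <- toy_pattern()
  tc <- taylor_curve(toy, 1)
  expect_equal(tc$mu, 0.75)
  expect_equal(tc$ordinate, 0.25)      # unbiased variance, divisor 3
  oc <- occupancy_curve(toy, 1)
  expect_equal(oc$ordinate, 0.75)
  # full-window plot is always occupied for n >= 1
  expect_equal(occupancy_curve(toy, 2)$ordinate, 1)
  # sides with fewer than 2 quadrats are dropped with a warning
  expect_warning(tc2 <- taylor_curve(toy, c(1, 1.9)), "dropping")
  expect_equal(nrow(tc2), 1L)
})

test_that("empty pattern gives zero occupancy everywhere", {
  empty <- point_pattern(numeric(0), numeric(0), landscape(4, 4))
  expect_equal(occupancy_curve(empty, c(1, 2))$ordinate, c(0, 0))
})

test_that("buffer-corrected O-ring matches the two-point hand count", {
  # two interior points at distance 1 in a large window
  ls <- landscape(20, 20)
  p <- point_pattern(c(10, 11), c(10, 10), ls)
  edges <- seq(0, 2, by = 0.5)
  om <- oring_estimate(p, edges, correction = "buffer")
  ann <- pi * diff(edges^2)
  lam <- 2 / 400
  # both points are focal; each sees one neighbor in the bin holding d = 1
  expect_equal(om$ordinate[3], 1 / (ann[3] * lam))
  expect_equal(om$ordinate[-3], rep(0, 3))
})

test_that("O-ring of CSR is flat at 1 in scaled units", {
  g <- rowMeans(vapply(1:10, function(i) {
    p <- simulate_csr(1000, landscape(500, 1000), seed = 40L + i)
    sc <- rescale_unit_intensity(p)$pattern
    oring_estimate(sc, seq(0, 5, length.out = 11))$ordinate
  }, numeric(10)))
  expect_lt(max(abs(g - 1)), 0.08)
})

test_that("buffer O-ring integrates back to the mean neighbor count", {
  p <- simulate_thomas(thomas_params(0.002, 8, 5), landscape(200, 200),
                       seed = 9L)
  edges <- seq(0, 20, by = 2)
  om <- oring_estimate(p, edges, correction = "buffer")
  ann <- pi * diff(edges^2)
  rmax <- max(edges)
  focal <- p$x >= rmax & p$x <= 200 - rmax & p$y >= rmax & p$y <= 200 - rmax
  d <- as.matrix(dist(cbind(p$x, p$y)))[focal, , drop = FALSE]
  nb <- (rowSums(d <= rmax) - 1)           # exclude self
  expect_equal(sum(om$ordinate * ann) * p$intensity, mean(nb),
               tolerance = 1e-10)
})

test_that("two-plot pair enumeration and covariance match hand counts", {
  toy <- toy_pattern()
  prs <- two_plot_pairs(toy, 1, 0)[["0"]]
  # horizontal rows give (1,1) and (0,1); vertical columns (1,0) and (1,1)
  expect_equal(nrow(prs), 4L)
  expect_equal(sort(rowSums(prs)), c(1, 1, 2, 2))
  cv <- two_plot_cov(toy, 1, 0)
  # symmetrized about the pooled mean 0.75
  expect_equal(cv$ordinate, -0.25 / 3)
  tv <- two_plot_turnover(toy, 1, 0)
  expect_equal(tv$ordinate, (2 / 4) / (6 / 8))
})

test_that("infeasible gaps are dropped with a warning", {
  toy <- toy_pattern()
  expect_warning(out <- two_plot_pairs(toy, 1, c(0, 5)), "dropped")
  expect_named(out, "0")
})

test_that("an exact translated copy produces strong positive covariance", {
  ls <- landscape(60, 20)
  set.seed(3)
  x <- runif(40, 0, 10); y <- runif(40, 0, 20)
  gap <- 5; side <- 10
  p <- point_pattern(c(x, x + side + gap), c(y, y), ls)
  cv <- two_plot_cov(p, side, c(gap))
  expect_gt(cv$ordinate, 10)
})

test_that("turnover approaches occupancy at large gaps under CSR", {
  ls <- landscape(400, 400)
  tt <- replicate(8, {
    p <- simulate_csr(600, ls, seed = sample.int(1e6, 1))
    side <- 20
    tv <- two_plot_turnover(p, side, c(160))
    oc <- mean(quadrat_counts(p, side) > 0)
    tv$ordinate - oc
  })
  expect_lt(abs(mean(tt)), 0.05)
})

test_that("dense patterns give turnover exactly 1", {
  p <- simulate_csr(4000, landscape(40, 40), seed = 5L)
  tv <- two_plot_turnover(p, 10, c(0, 10))
  expect_equal(tv$ordinate, c(1, 1))
})

test_that("measure_all_metrics returns the five curves in scaled units", {
  p <- simulate_thomas(thomas_params(0.003, 6, 4), landscape(200, 400),
                       seed = 21L)
  sc <- rescale_unit_intensity(p)$pattern
  out <- suppressWarnings(measure_all_metrics(sc))
  expect_named(out, c("taylor", "occupancy", "oring", "twoplot_cov",
                      "turnover"))
  expect_true(all(vapply(out, inherits, TRUE, "metric_curve")))
  # mu(A) tracks A under the lambda = 1 convention
  expect_equal(out$taylor$mu / out$taylor$abscissa,
               rep(1, nrow(out$taylor)), tolerance = 0.25)
  expect_true(all(diff(out$occupancy$ordinate) >= 0))
})
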