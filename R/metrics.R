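#' Metric curve container
#'
#' One of the five focal spatial metrics evaluated on a grid.  The abscissa
#' is a plot area `A` (Taylor's Law, occupancy), a point-pair distance `r`
#' (O-ring) or a nearest-edge gap `D` (two-plot covariance and turnover),
#' in whatever length units the producing pattern used.
#'
#' @param kind One of `"taylor"`, `"occupancy"`, `"oring"`,
#'   `"twoplot_cov"`, `"turnover"`.
#' @param abscissa Strictly increasing numeric grid.
#' @param ordinate Metric values.
#' @param support Number of quadrats, point pairs or plot pairs behind each
#'   value.
#' @param plot_side Fixed plot side length for the two-plot metrics
#'   (`NA` otherwise).
#' @param scale Length-ratio between original and working units (`s` from
#'   [rescale_unit_intensity()]; 1 if unscaled).
#' @param mu Optional mean quadrat counts (stored for Taylor's Law).
#' @return A data frame of class `metric_curve` with attributes `kind`,
#'   `plot_side` and `scale`.
#' @export
metric_curve <- function(kind, abscissa, ordinate, support,
                         plot_side = NA_real_, scale = 1, mu = NULL) {
  kind <- match.arg(kind, c("taylor", "occupancy", "oring",
                            "twoplot_cov", "turnover"))
  stopifnot(length(abscissa) == length(ordinate),
            length(support) %in% c(1L, length(abscissa)))
  if (is.unsorted(abscissa, strictly = TRUE))
    stop("abscissa must be strictly increasing")
  if (kind %in% c("twoplot_cov", "turnover") && !is.finite(plot_side))
    stop("two-plot metrics require a fixed plot_side")
  df <- data.frame(abscissa = abscissa, ordinate = ordinate,
                   support = rep_len(support, length(abscissa)))
  if (!is.null(mu)) df$mu <- mu
  structure(df, kind = kind, plot_side = plot_side, scale = scale,
            class = c("metric_curve", "data.frame"))
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("metric curve '%s' (%d points%s)\n", attr(x, "kind"), nrow(x),
              if (is.finite(attr(x, "plot_side")))
                sprintf(", plot side %g", attr(x, "plot_side")) else ""))
  print.data.frame(x, ...)
  invisible(x)
}

curve_kind <- function(curve) attr(curve, "kind")

#' Quadrat counts for a point pattern
#'
#' @param pattern A `spat_pattern`.
#' @param side Quadrat side length (same units as the pattern).
#' @param scheme `"grid"` tiles the window with non-overlapping squares
#'   anchored at the origin, discarding partial tiles (deterministic);
#'   `"random"` places `n_random` uniformly located, non-clipped squares.
#' @param n_random Number of random quadrats for `scheme = "random"`.
#' @param seed Optional seed for random placement.
#' @return Integer vector of per-quadrat counts (column-major tile order
#'   for the grid scheme).
#' @export
quadrat_counts <- function(pattern, side, scheme = c("grid", "random"),
                           n_random = 200L, seed = NULL) {
  stopifnot(inherits(pattern, "spat_pattern"), side > 0)
  scheme <- match.arg(scheme)
  W <- pattern$landscape$width; H <- pattern$landscape$height
  if (side > min(W, H)) stop("quadrat side exceeds the window")
  if (scheme == "grid") {
    nx <- floor(W / side + 1e-9); ny <- floor(H / side + 1e-9)
    ix <- floor(pattern$x / side); iy <- floor(pattern$y / side)
    keep <- ix < nx & iy < ny   # points beyond the last full tile dropped
    idx <- ix[keep] * ny + iy[keep] + 1L
    counts <- integer(nx * ny)
    if (length(idx)) {
      tab <- tabulate(idx, nbins = nx * ny)
      counts <- tab
    }
    counts
  } else {
    with_seed(seed, {
      x0 <- stats::runif(n_random, 0, W - side)
      y0 <- stats::runif(n_random, 0, H - side)
      vapply(seq_len(n_random), function(i)
        sum(pattern$x >= x0[i] & pattern$x < x0[i] + side &
            pattern$y >= y0[i] & pattern$y < y0[i] + side), integer(1L))
    })
  }
}

check_sides <- function(pattern, sides, min_quadrats = 2L) {
  W <- pattern$landscape$width; H <- pattern$landscape$height
  nq <- floor(W / sides + 1e-9) * floor(H / sides + 1e-9)
  drop <- nq < min_quadrats
  if (any(drop))
    warning("dropping plot side(s) with fewer than ", min_quadrats,
            " quadrat(s): ", paste(signif(sides[drop], 4), collapse = ", "))
  sides[!drop]
}

#' Empirical Taylor's Law curve
#'
#' For each plot side the window is tiled with grid quadrats and the sample
#' mean and (divisor n-1) variance of the counts are recorded.  The curve
#' ordinate is the variance `sigma^2(A)` at plot area `A = side^2`; the
#' companion means are kept in the `mu` column.
#'
#' @param pattern A `spat_pattern`.
#' @param sides Vector of quadrat side lengths.
#' @return A `metric_curve` of kind `"taylor"`.
#' @export
taylor_curve <- function(pattern, sides) {
  sides <- sort(check_sides(pattern, sides))
  stats_ <- vapply(sides, function(s) {
    cts <- quadrat_counts(pattern, s)
    c(mean(cts), stats::var(cts), length(cts))
  }, numeric(3L))
  metric_curve("taylor", sides^2, stats_[2L, ], stats_[3L, ],
               scale = pattern$scale, mu = stats_[1L, ])
}

#' Empirical occupancy-area curve
#'
#' `Psi(A)` is estimated as the fraction of grid quadrats of area `A` that
#' contain at least one point.
#'
#' @inheritParams taylor_curve
#' @return A `metric_curve` of kind `"occupancy"`.
#' @export
occupancy_curve <- function(pattern, sides) {
  sides <- sort(check_sides(pattern, sides, min_quadrats = 1L))
  stats_ <- vapply(sides, function(s) {
    cts <- quadrat_counts(pattern, s)
    c(mean(cts > 0L), length(cts))
  }, numeric(2L))
  metric_curve("occupancy", sides^2, stats_[1L, ], stats_[2L, ],
               scale = pattern$scale)
}

# pairwise separation components; returns list(dx, dy, d) full matrices
pair_seps <- function(pattern) {
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  list(dx = dx, dy = dy, d = sqrt(dx^2 + dy^2))
}

#' Binned O-ring (neighborhood density) estimator
#'
#' Estimates `Omega(r)`, the density of further points in an annulus at
#' distance `r` from a typical point, divided by... nothing further: in
#' units where `lambda = 1` this equals the pair correlation function.
#' The translation correction weights each pair by the reciprocal
#' translation-overlap area; the buffer correction restricts focal points
#' to those further than `max(r_edges)` from every edge, for which the
#' annulus counts need no correction.
#'
#' @param pattern A `spat_pattern` with at least 2 points.
#' @param r_edges Increasing bin boundaries; the first evaluation point
#'   (bin midpoint) must be positive so the self-pair atom at `r = 0` is
#'   excluded.
#' @param correction `"translation"` (default, standard for rectangular
#'   windows) or `"buffer"`.
#' @return A `metric_curve` of kind `"oring"` evaluated at bin midpoints,
#'   in the pattern's units; the ordinate estimates `lambda2(r) / lambda`.
#' @export
oring_estimate <- function(pattern, r_edges,
                           correction = c("translation", "buffer")) {
  stopifnot(inherits(pattern, "spat_pattern"))
  correction <- match.arg(correction)
  if (pattern$n < 2L) stop("O-ring estimation needs at least 2 points")
  r_edges <- sort(r_edges)
  if (r_edges[1L] < 0) stop("r_edges must be non-negative")
  mids <- (r_edges[-1L] + r_edges[-length(r_edges)]) / 2
  if (mids[1L] <= 0) stop("first bin midpoint must be positive")
  W <- pattern$landscape$width; H <- pattern$landscape$height
  area <- W * H; lam <- pattern$intensity
  ann <- pi * diff(r_edges^2)
  sp <- pair_seps(pattern)
  off <- !diag(pattern$n)
  if (correction == "translation") {
    wt <- area / ((W - sp$dx) * (H - sp$dy))
    bins <- findInterval(sp$d[off], r_edges, rightmost.closed = TRUE)
    wsum <- vapply(seq_along(mids), function(b)
      sum(wt[off][bins == b]), numeric(1L))
    npairs <- vapply(seq_along(mids), function(b)
      sum(bins == b), numeric(1L))
    omega <- wsum / (pattern$n * ann * lam)
  } else {
    rmax <- max(r_edges)
    focal <- pattern$x >= rmax & pattern$x <= W - rmax &
             pattern$y >= rmax & pattern$y <= H - rmax
    if (!any(focal)) stop("no interior points for buffer correction")
    d <- sp$d[focal, , drop = FALSE]
    d[cbind(seq_len(sum(focal)), which(focal))] <- NA  # drop self pairs
    bins <- findInterval(as.vector(d), r_edges, rightmost.closed = TRUE)
    npairs <- vapply(seq_along(mids), function(b)
      sum(bins == b, na.rm = TRUE), numeric(1L))
    omega <- npairs / (sum(focal) * ann * lam)
  }
  metric_curve("oring", mids, omega, pmax(npairs, 1L),
               scale = pattern$scale)
}

#' Kernel-smoothed pair correlation estimate
#'
#' Translation-corrected estimator with an Epanechnikov kernel and the
#' traditional `1/(2 pi r)` divisor, following the usual stem-map practice.
#' The default bandwidth is Stoyan's rule `bw = 0.15 / sqrt(lambda)`, where
#' `bw` is the kernel's standard deviation (half-width `bw * sqrt(5)`).
#' With `lambda = 1` scaling this estimates `Omega(r)` directly.
#'
#' @param pattern A `spat_pattern` with at least 2 points.
#' @param r Evaluation grid (positive).
#' @param bw Kernel standard deviation; default Stoyan's rule.
#' @return Data frame with columns `r` and `g`.
#' @seealso [fit_thomas_mincontrast()] which fits this curve.
#' @export
pcf_kernel <- function(pattern, r, bw = NULL) {
  stopifnot(inherits(pattern, "spat_pattern"), all(r > 0))
  if (pattern$n < 2L) stop("pair correlation needs at least 2 points")
  W <- pattern$landscape$width; H <- pattern$landscape$height
  lam <- pattern$intensity
  if (is.null(bw)) bw <- 0.15 / sqrt(lam)
  hw <- bw * sqrt(5)                      # Epanechnikov half-width
  sp <- pair_seps(pattern)
  ut <- upper.tri(sp$d)
  dd <- sp$d[ut]
  wt <- 2 / ((W - sp$dx[ut]) * (H - sp$dy[ut]))  # both pair orders
  keep <- dd <= max(r) + hw
  dd <- dd[keep]; wt <- wt[keep]
  g <- vapply(r, function(ri) {
    u <- (ri - dd) / hw
    inb <- abs(u) < 1
    sum(0.75 * (1 - u[inb]^2) / hw * wt[inb]) / (2 * pi * ri * lam^2)
  }, numeric(1L))
  data.frame(r = r, g = g)
}

#' Enumerate two-plot count pairs
#'
#' Places pairs of axis-aligned square plots of the given side with
#' nearest-edge gap `D`, on a raster stepping by one side length, in both
#' the horizontal and vertical orientation, and returns the joint counts.
#' Isotropy makes the orientation irrelevant in expectation, so both are
#' pooled.
#'
#' @param pattern A `spat_pattern`.
#' @param side Plot side length.
#' @param gaps Nearest-edge gaps `D >= 0`.  Gaps for which no pair fits in
#'   the window are dropped with a warning.
#' @return Named list (by gap) of two-column matrices of `(n, n')` counts;
#'   dropped gaps are absent.
#' @export
two_plot_pairs <- function(pattern, side, gaps) {
  stopifnot(inherits(pattern, "spat_pattern"), side > 0, all(gaps >= 0))
  W <- pattern$landscape$width; H <- pattern$landscape$height
  count_in <- function(x0, y0)
    vapply(seq_along(x0), function(i)
      sum(pattern$x >= x0[i] & pattern$x < x0[i] + side &
          pattern$y >= y0[i] & pattern$y < y0[i] + side), numeric(1L))
  out <- list()
  for (D in gaps) {
    pairs <- NULL
    # horizontal separation: first plot at (x0, y0), second at (x0+side+D, y0)
    if (2 * side + D <= W && side <= H) {
      x0 <- seq(0, W - (2 * side + D), by = side)
      y0 <- seq(0, H - side, by = side)
      grid <- expand.grid(x = x0, y = y0)
      pairs <- rbind(pairs, cbind(count_in(grid$x, grid$y),
                                  count_in(grid$x + side + D, grid$y)))
    }
    if (2 * side + D <= H && side <= W) {
      x0 <- seq(0, W - side, by = side)
      y0 <- seq(0, H - (2 * side + D), by = side)
      grid <- expand.grid(x = x0, y = y0)
      pairs <- rbind(pairs, cbind(count_in(grid$x, grid$y),
                                  count_in(grid$x, grid$y + side + D)))
    }
    if (is.null(pairs)) {
      warning("no feasible plot pair for gap D = ", signif(D, 4),
              "; dropped")
    } else {
      out[[as.character(D)]] <- pairs
    }
  }
  out
}

#' Empirical two-plot Taylor's Law (covariance versus gap)
#'
#' Sample covariance of the joint counts from [two_plot_pairs()] at each
#' gap.  Each unordered placement contributes once; the covariance is
#' symmetrized by centring both members on the pooled mean, so swapping
#' the two plots leaves the estimate unchanged.
#'
#' @inheritParams two_plot_pairs
#' @return A `metric_curve` of kind `"twoplot_cov"` with `plot_side` fixed.
#' @export
two_plot_cov <- function(pattern, side, gaps) {
  prs <- two_plot_pairs(pattern, side, gaps)
  if (!length(prs)) stop("no feasible gaps")
  D <- as.numeric(names(prs))
  cv <- vapply(prs, function(m) {
    mbar <- mean(m)
    sum((m[, 1L] - mbar) * (m[, 2L] - mbar)) / (nrow(m) - 1L)
  }, numeric(1L))
  sup <- vapply(prs, nrow, numeric(1L))
  o <- order(D)
  metric_curve("twoplot_cov", D[o], cv[o], sup[o], plot_side = side,
               scale = pattern$scale)
}

#' Empirical two-plot turnover
#'
#' `T(A, D)` is the fraction of plot pairs at gap `D` in which both plots
#' are occupied, divided by the single-plot occupancy fraction pooled over
#' the same placements; equivalently the conditional probability that one
#' plot is occupied given the other is.  Values nudged outside `[0, 1]` by
#' sampling noise are clipped with a warning.
#'
#' @inheritParams two_plot_pairs
#' @return A `metric_curve` of kind `"turnover"`.
#' @export
two_plot_turnover <- function(pattern, side, gaps) {
  prs <- two_plot_pairs(pattern, side, gaps)
  if (!length(prs)) stop("no feasible gaps")
  D <- as.numeric(names(prs))
  tv <- vapply(prs, function(m) {
    occ <- m > 0L
    psi <- mean(occ)
    if (psi == 0) stop("turnover undefined: no occupied plot at some gap")
    mean(occ[, 1L] & occ[, 2L]) / psi
  }, numeric(1L))
  if (any(tv > 1 + 1e-12)) {
    warning("turnover clipped to [0, 1]")
    tv <- pmin(tv, 1)
  }
  sup <- vapply(prs, nrow, numeric(1L))
  o <- order(D)
  metric_curve("turnover", D[o], tv[o], sup[o], plot_side = side,
               scale = pattern$scale)
}

#' Measure all five spatial metrics of a pattern
#'
#' Convenience wrapper producing the five focal metric curves on default or
#' supplied grids.  Patterns are typically rescaled to unit intensity first
#' so the curves are comparable across species (see
#' [rescale_unit_intensity()]).
#'
#' @param pattern A `spat_pattern`.
#' @param sides Quadrat sides for Taylor's Law and occupancy; default five
#'   dyadic fractions `shortside / 2^(6:2)`, capped at a quarter of the
#'   short window side so the variance at the largest plot still rests on
#'   at least 8 quadrats.
#' @param r_edges O-ring bin boundaries; default 24 equal bins up to a
#'   quarter of the short window side.
#' @param plot_side Fixed plot side for the two-plot metrics; defaults to
#'   `min(window) / 20`, matching a 25 m plot in a 500 m window.
#' @param gaps Nearest-edge gaps; default multiples of `plot_side` spanning
#'   half the short side.
#' @return Named list of five `metric_curve`s.
#' @export
measure_all_metrics <- function(pattern, sides = NULL, r_edges = NULL,
                                plot_side = NULL, gaps = NULL) {
  short <- min(pattern$landscape$width, pattern$landscape$height)
  if (is.null(sides)) sides <- short / 2^(6:2)
  if (is.null(r_edges)) r_edges <- seq(0, short / 4, length.out = 25L)
  if (is.null(plot_side)) plot_side <- short / 20
  if (is.null(gaps)) gaps <- seq(0, short / 2, by = plot_side)
  list(taylor = taylor_curve(pattern, sides),
       occupancy = occupancy_curve(pattern, sides),
       oring = oring_estimate(pattern, r_edges),
       twoplot_cov = two_plot_cov(pattern, plot_side, gaps),
       turnover = two_plot_turnover(pattern, plot_side, gaps))
}
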