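#' Idealized species specification
#'
#' A species is specified by its landscape-wide expected abundance and the
#' Gaussian second-order-intensity parameters (scaled units) of the Thomas
#' process that generates it.
#'
#' @param name Species label.
#' @param n Expected abundance in the landscape.
#' @param alpha,beta Gaussian second-order-intensity parameters.
#' @param overlay `"recovered"` to draw theoretical overlays at the median
#'   parameters recovered by minimum contrast from the simulations,
#'   `"target"` to use `alpha`/`beta` themselves.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(name, n, alpha, beta,
                         overlay = c("recovered", "target")) {
  stopifnot(n > 0, alpha > 0, beta > 0)
  structure(list(name = name, n = n, alpha = alpha, beta = beta,
                 overlay = match.arg(overlay)), class = "species_spec")
}

#' Simulation study configuration
#'
#' @param species List of [species_spec()]s.
#' @param landscape Simulation window, original units (default 500 x 1000).
#' @param reps Replicate point patterns per species.
#' @param seed Master seed; replicate `r` of species `i` uses
#'   `seed + (i - 1) * 10000 + r`, so any replicate is reproducible in
#'   isolation.
#' @param plot_side Plot side for the two-plot metrics, original units.
#' @param sides Quadrat sides (original units) for Taylor's Law and
#'   occupancy; default dyadic fractions of the short window side, capped
#'   at a quarter of it (at least 8 quadrats per side).
#' @param n_rbins Number of O-ring bins up to a quarter short side.
#' @param gaps Nearest-edge gaps (original units); default multiples of
#'   `plot_side` up to half the short side.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(species, landscape = NULL,
                              reps = 200L, seed = 1L, plot_side = 25,
                              sides = NULL, n_rbins = 24L, gaps = NULL) {
  if (is.null(landscape)) landscape <- spatlink::landscape(500, 1000)
  stopifnot(length(species) >= 1L, reps >= 1L,
            inherits(landscape, "landscape"), plot_side > 0)
  short <- min(landscape$width, landscape$height)
  if (is.null(sides)) sides <- short / 2^(6:2)
  if (is.null(gaps)) gaps <- seq(0, short / 2, by = plot_side)
  structure(list(species = species, landscape = landscape,
                 reps = as.integer(reps), seed = as.integer(seed),
                 plot_side = plot_side, sides = sides,
                 n_rbins = as.integer(n_rbins), gaps = gaps),
            class = "experiment_config")
}

#' Default configuration: three idealized species
#'
#' Low-, medium- and high-abundance idealized species (abundance-tertile
#' medians of Thomas fits to a large tropical forest census), simulated in
#' a 500 x 1000 landscape with 200 replicates and a 25-unit plot side for
#' the two-plot metrics.  Overlays use recovered parameters for the low
#' and medium species and target parameters for the high species.
#'
#' @param reps Replicates per species.
#' @param seed Master seed.
#' @return An [experiment_config()].
#' @export
default_config <- function(reps = 200L, seed = 1L) {
  experiment_config(
    species = list(
      species_spec("low", 108, 4.5, 3.8),
      species_spec("medium", 432, 2.7, 0.8),
      species_spec("high", 1856, 1.0, 0.1, overlay = "target")),
    reps = reps, seed = seed)
}

# metric grids in scaled units for a species of expected abundance n
scaled_grids <- function(config, n) {
  s0 <- sqrt(config$landscape$area / n)
  short_sc <- min(config$landscape$width, config$landscape$height) / s0
  list(sides = config$sides / s0,
       r_edges = seq(0, short_sc / 4, length.out = config$n_rbins + 1L),
       plot_side = config$plot_side / s0,
       gaps = config$gaps / s0,
       scale = s0)
}

#' Run the simulation study
#'
#' For each idealized species: simulate `reps` Thomas point patterns, fit
#' each by minimum contrast on the pair correlation function, rescale each
#' pattern to unit intensity and measure all five metrics on common
#' scaled-unit grids, then take the per-abscissa median curve across
#' replicates.  Theoretical overlay curves are computed from the Gaussian
#' second-order-intensity equations at either the median recovered or the
#' target parameters (per species spec).
#'
#' Because the negative binomial quadrat-count distribution is only an
#' approximation for the Thomas process, the occupancy and turnover
#' overlays are expected to sit above the simulation medians; the other
#' three metrics should track closely.
#'
#' @param config An [experiment_config()].
#' @param progress Emit per-species progress messages.
#' @return List with elements `species` (per-species list: `median_curves`,
#'   `theory_curves`, `fits`, `alpha_hat`, `beta_hat`, `grids`) and
#'   `recovered` (data frame of median recovered parameters).
#' @export
run_simulation_study <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  kinds <- c("taylor", "occupancy", "oring", "twoplot_cov", "turnover")
  res <- list()
  for (i in seq_along(config$species)) {
    sp <- config$species[[i]]
    g <- scaled_grids(config, sp$n)
    if (progress)
      message("simulating species '", sp$name, "' (", config$reps,
              " replicates)")
    params <- thomas_from_alpha_beta(sp$alpha, sp$beta, sp$n,
                                     config$landscape)
    curves <- vector("list", config$reps)
    ab <- matrix(NA_real_, config$reps, 2L)
    for (r in seq_len(config$reps)) {
      seed_r <- config$seed + (i - 1L) * 10000L + r
      pat <- simulate_thomas(params, config$landscape, seed = seed_r)
      if (pat$n < 10L) next
      fit <- fit_thomas_mincontrast(pat)
      ab[r, ] <- c(fit$alpha, fit$beta)
      sc <- rescale_unit_intensity(pat)$pattern
      curves[[r]] <- suppressWarnings(measure_all_metrics(
        sc, sides = g$sides, r_edges = g$r_edges,
        plot_side = g$plot_side, gaps = g$gaps))
    }
    curves <- curves[!vapply(curves, is.null, logical(1L))]
    med <- lapply(kinds, function(k) median_curve(lapply(curves, `[[`, k)))
    names(med) <- kinds
    a_hat <- stats::median(ab[, 1L], na.rm = TRUE)
    b_hat <- stats::median(ab[, 2L], na.rm = TRUE)
    ov <- if (sp$overlay == "recovered") c(a_hat, b_hat)
          else c(sp$alpha, sp$beta)
    model <- gaussian_lambda2(ov[1L], ov[2L])
    theo <- lapply(kinds, function(k)
      theory_curve(model, k, med[[k]]$abscissa, plot_side = g$plot_side))
    names(theo) <- kinds
    res[[sp$name]] <- list(median_curves = med, theory_curves = theo,
                           fits = ab, alpha_hat = a_hat, beta_hat = b_hat,
                           overlay_params = ov, grids = g)
  }
  recovered <- data.frame(
    species = vapply(config$species, `[[`, "", "name"),
    alpha_target = vapply(config$species, `[[`, 0, "alpha"),
    beta_target = vapply(config$species, `[[`, 0, "beta"),
    alpha_hat = vapply(res, `[[`, 0, "alpha_hat"),
    beta_hat = vapply(res, `[[`, 0, "beta_hat"), row.names = NULL)
  list(species = res, recovered = recovered)
}

# per-abscissa median across a list of metric_curves sharing a grid;
# curves may have dropped abscissa values, so align on value
median_curve <- function(curves) {
  if (!length(curves)) return(NULL)
  kind <- curve_kind(curves[[1L]])
  absc <- sort(unique(unlist(lapply(curves, `[[`, "abscissa"))))
  ords <- vapply(curves, function(cv)
    cv$ordinate[match(absc, cv$abscissa)], numeric(length(absc)))
  ords <- matrix(ords, nrow = length(absc))
  metric_curve(kind, absc,
               apply(ords, 1L, stats::median, na.rm = TRUE),
               rowSums(!is.na(ords)),
               plot_side = attr(curves[[1L]], "plot_side"),
               scale = attr(curves[[1L]], "scale"))
}

#' Generate a synthetic multi-species community
#'
#' Draws `n_species` independent Thomas-process species with heterogeneous
#' `(alpha, beta)` (log-uniform over ranges bracketing the low/medium/high
#' idealized species) and log-uniform abundances, and simulates one stem
#' map for each.  Used to exercise the multi-species pipeline without any
#' external census data.
#'
#' @param n_species Number of species.
#' @param landscape Window, original units (default 500 x 1000).
#' @param seed Master seed.
#' @param n_range Abundance range (log-uniform).
#' @param alpha_range,beta_range Parameter ranges (log-uniform).
#' @return Data frame with columns `x`, `y`, `species`, plus an attribute
#'   `truth`: the per-species true parameters.
#' @export
synthetic_community <- function(n_species = 50L, landscape = NULL,
                                seed = 1L, n_range = c(150, 2000),
                                alpha_range = c(0.5, 8),
                                beta_range = c(0.1, 5)) {
  if (is.null(landscape)) landscape <- spatlink::landscape(500, 1000)
  runif_log <- function(n, rng) exp(stats::runif(n, log(rng[1L]), log(rng[2L])))
  with_seed(seed, {
    truth <- data.frame(
      species = sprintf("sp%02d", seq_len(n_species)),
      n = round(runif_log(n_species, n_range)),
      alpha = runif_log(n_species, alpha_range),
      beta = runif_log(n_species, beta_range))
    maps <- lapply(seq_len(n_species), function(i) {
      params <- thomas_from_alpha_beta(truth$alpha[i], truth$beta[i],
                                       truth$n[i], landscape)
      pat <- simulate_thomas(params, landscape,
                             seed = sample.int(2^30, 1L))
      if (pat$n == 0L) return(NULL)
      data.frame(x = pat$x, y = pat$y, species = truth$species[i])
    })
    out <- do.call(rbind, maps)
    attr(out, "truth") <- truth
    out
  })
}

#' Run the multi-species (empirical-style) study
#'
#' Applies the full per-species pipeline to a stem map: abundance filter,
#' rescaling to unit intensity, measurement of all five metrics, Gaussian
#' second-order-intensity fits to each metric, and the cross-metric
#' Spearman correlation analysis of the fitted parameters.
#'
#' @param stem_map Data frame with columns `x`, `y`, `species` (or a CSV
#'   path readable by [read_stem_map()]).
#' @param landscape Window the coordinates live in.
#' @param min_abundance Minimum living individuals for a species to be
#'   analysed.
#' @param plot_side Plot side for the two-plot metrics, original units.
#' @param progress Emit per-species messages.
#' @return List with `fits` (long data frame: species, metric, alpha, beta,
#'   converged, n) and `spearman` (from [cross_metric_spearman()]; `NULL`
#'   if fewer than 2 species pass the filter).
#' @export
run_empirical_study <- function(stem_map, landscape, min_abundance = 70L,
                                plot_side = 25, progress = interactive()) {
  if (is.character(stem_map))
    stem_map <- utils::read.csv(stem_map)
  stopifnot(all(c("x", "y", "species") %in% names(stem_map)))
  tab <- table(stem_map$species)
  keep <- names(tab)[tab >= min_abundance]
  if (!length(keep))
    stop("no species passes the abundance filter (min_abundance = ",
         min_abundance, ")")
  fits <- NULL
  for (spname in keep) {
    rows <- stem_map$species == spname
    pat <- point_pattern(stem_map$x[rows], stem_map$y[rows], landscape)
    sc <- rescale_unit_intensity(pat)
    p <- sc$pattern
    if (progress) message("fitting species '", spname, "' (n = ", pat$n, ")")
    curves <- suppressWarnings(
      measure_all_metrics(p, plot_side = plot_side / sc$scale))
    for (k in names(curves)) {
      f <- fit_gaussian_to_metric(curves[[k]])
      fits <- rbind(fits, data.frame(
        species = spname, metric = k, alpha = f$alpha, beta = f$beta,
        converged = f$converged, n = pat$n))
    }
  }
  sp <- if (length(keep) >= 2L) cross_metric_spearman(fits) else NULL
  list(fits = fits, spearman = sp)
}
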