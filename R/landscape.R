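#' Rectangular study landscape
#'
#' A landscape is an axis-aligned rectangular observation window with its
#' origin at the lower-left corner.  All point patterns live inside a
#' landscape, and all plot-based metrics tile or sample it.
#'
#' @param width,height Positive side lengths, in the data's own length units
#'   (e.g. metres for a forest census plot).
#'
#' @return An object of class `landscape` with fields `width`, `height` and
#'   `area`.
#' @examples
#' landscape(500, 1000)  # a 50-ha census plot
#' @export
landscape <- function(width, height) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("landscape dimensions must be positive and finite")
  structure(list(width = width, height = height, area = width * height),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %g x %g window (area %g)\n", x$width, x$height,
              x$area))
  invisible(x)
}

#' Planar point pattern in a rectangular window
#'
#' Represents the mapped locations of individuals of a single species.  The
#' pattern is assumed orderly (no two points at exactly the same location),
#' homogeneous and isotropic; duplicate coordinates are therefore rejected
#' unless `jitter_dup = TRUE`, in which case they are displaced by a tiny
#' uniform amount and a message is emitted.
#'
#' @param x,y Numeric coordinate vectors of equal length, inside
#'   `[0, width] x [0, height]`.
#' @param landscape A [landscape()].
#' @param jitter_dup Logical; jitter duplicated coordinates instead of
#'   failing.  The jitter amplitude is `1e-8 * min(width, height)`.
#' @param scale Optional length-ratio recording how coordinates relate to
#'   their original units (see [rescale_unit_intensity()]); `1` means
#'   original units.
#'
#' @return An object of class `spat_pattern` with fields `x`, `y`,
#'   `landscape`, `n`, `intensity` (points per unit area) and `scale`.
#' @seealso [rescale_unit_intensity()], [simulate_csr()], [simulate_thomas()]
#' @export
point_pattern <- function(x, y, landscape, jitter_dup = FALSE, scale = 1) {
  stopifnot(inherits(landscape, "landscape"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("coordinates must not contain NA")
  if (length(x) && (any(x < 0 | x > landscape$width) ||
                    any(y < 0 | y > landscape$height)))
    stop("points outside the landscape window: rows ",
         paste(utils::head(which(x < 0 | x > landscape$width |
                                 y < 0 | y > landscape$height), 10L),
               collapse = ", "))
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    if (!jitter_dup)
      stop("duplicate coordinates violate the orderliness assumption ",
           "(rows ", paste(utils::head(which(dup), 10L), collapse = ", "),
           "); set jitter_dup = TRUE to displace them")
    eps <- 1e-8 * min(landscape$width, landscape$height)
    message(sum(dup), " duplicated point(s) jittered by up to ", eps)
    x[dup] <- pmin(pmax(x[dup] + stats::runif(sum(dup), -eps, eps), 0),
                   landscape$width)
    y[dup] <- pmin(pmax(y[dup] + stats::runif(sum(dup), -eps, eps), 0),
                   landscape$height)
  }
  structure(list(x = x, y = y, landscape = landscape, n = length(x),
                 intensity = length(x) / landscape$area, scale = scale),
            class = "spat_pattern")
}

#' @export
print.spat_pattern <- function(x, ...) {
  cat(sprintf(
    "point pattern: %d points in %g x %g window (intensity %.4g%s)\n",
    x$n, x$landscape$width, x$landscape$height, x$intensity,
    if (!is.null(x$scale) && x$scale != 1)
      sprintf("; coordinates scaled by 1/%.4g", x$scale) else ""))
  invisible(x)
}

#' Rescale a pattern to unit intensity
#'
#' Divides all coordinates (and the window) by `s = sqrt(area / n)` so that
#' the rescaled window has area `n` and the first-order intensity is exactly
#' `lambda = 1`.  In these units a plot of area `A` has expected abundance
#' `mu(A) = A`, which is the convention assumed by every theoretical
#' expression in this package: variation in plot area is then equivalent to
#' variation in expected abundance.
#'
#' @param pattern A [point_pattern()] with at least one point.
#' @return A list with elements `pattern` (the rescaled pattern, whose
#'   `scale` field records `s`) and `scale` (`s` itself, original length
#'   units per scaled unit).
#' @examples
#' ls <- landscape(500, 1000)
#' p <- simulate_csr(108, ls, seed = 1)
#' sp <- rescale_unit_intensity(p)
#' sp$pattern$intensity  # exactly 1
#' @export
rescale_unit_intensity <- function(pattern) {
  stopifnot(inherits(pattern, "spat_pattern"))
  if (pattern$n < 1L)
    stop("intensity undefined: pattern has no points")
  s <- sqrt(pattern$landscape$area / pattern$n)
  ls2 <- landscape(pattern$landscape$width / s, pattern$landscape$height / s)
  out <- point_pattern(pattern$x / s, pattern$y / s, ls2,
                       scale = pattern$scale * s)
  list(pattern = out, scale = s)
}

#' Undo (or apply) a coordinate rescaling
#'
#' Multiplies coordinates and window by `s`, the inverse of the division
#' performed by [rescale_unit_intensity()].
#'
#' @param pattern A `spat_pattern`.
#' @param s Length-ratio to multiply by.
#' @return The rescaled `spat_pattern`.
#' @export
scale_pattern <- function(pattern, s) {
  stopifnot(inherits(pattern, "spat_pattern"), s > 0)
  ls2 <- landscape(pattern$landscape$width * s, pattern$landscape$height * s)
  point_pattern(pattern$x * s, pattern$y * s, ls2,
                scale = pattern$scale / s)
}
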