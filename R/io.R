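#' Read a stem map from CSV
#'
#' Expects a header with columns `x`, `y` and optionally `species`.  All
#' coordinates are validated against the window; offending row numbers are
#' reported.  Duplicate coordinates within a species violate the
#' orderliness assumption and are rejected (or jittered on request).
#'
#' @param path CSV file path.
#' @param landscape The window the coordinates must lie in.
#' @param jitter_dup Passed to [point_pattern()].
#' @return Named list of `spat_pattern`s, one per species (a single
#'   element named `"all"` if there is no species column).
#' @export
read_stem_map <- function(path, landscape, jitter_dup = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("stem map must have columns 'x' and 'y'")
  if (!nrow(df)) stop("empty stem map")
  bad <- which(!is.finite(df$x) | !is.finite(df$y) |
                 df$x < 0 | df$x > landscape$width |
                 df$y < 0 | df$y > landscape$height)
  if (length(bad))
    stop("out-of-bounds or non-numeric coordinates at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  groups <- if ("species" %in% names(df)) split(df, df$species)
            else list(all = df)
  lapply(groups, function(g)
    point_pattern(g$x, g$y, landscape, jitter_dup = jitter_dup))
}

#' Write / read a metric curve as TSV
#'
#' Plain-text round trip: metadata (`kind`, `plot_side`, `scale`) in `#`
#' header lines, then a tab-separated table.  Values are written with full
#' precision (`format(..., digits = 17)`) so decimal-representable values
#' survive bit-exactly.
#'
#' @param curve A `metric_curve`.
#' @param path Output file.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns
#'   the `metric_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "metric_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", curve_kind(curve)),
               paste0("# plot_side: ",
                      format(attr(curve, "plot_side"), digits = 17)),
               paste0("# scale: ", format(attr(curve, "scale"), digits = 17))),
             con)
  utils::write.table(format(as.data.frame(curve), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param expect_kind Optional kind the caller requires; a mismatch errors.
#' @rdname write_curve
#' @export
read_curve <- function(path, expect_kind = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("missing '", key, "' metadata in ", path)
    sub(paste0("^# ", key, ": *"), "", ln[1L])
  }
  kind <- meta("kind")
  if (!is.null(expect_kind) && kind != expect_kind)
    stop("curve kind mismatch: file has '", kind, "', expected '",
         expect_kind, "'")
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  as_num <- function(s) if (s == "NA") NA_real_ else as.numeric(s)
  metric_curve(kind, df$abscissa, df$ordinate, df$support,
               plot_side = as_num(meta("plot_side")),
               scale = as_num(meta("scale")),
               mu = if ("mu" %in% names(df)) df$mu)
}

#' Write a run manifest
#'
#' Records the command, parameters, master seed and package version needed
#' to re-run a producing command exactly.
#'
#' @param path Output JSON file.
#' @param command Command or function name.
#' @param parameters Named list of parameters (must be serializable).
#' @param seed Master seed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, parameters, seed) {
  jsonlite::write_json(
    list(command = command, parameters = parameters, seed = seed,
         package_version = as.character(utils::packageVersion("spatlink")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate the bundled toy fixtures
#'
#' Writes small deterministic datasets used by the unit tests and examples
#' to a directory: the 3-point hand-countable pattern in a 2 x 2 window, a
#' small CSR pattern, a small Thomas pattern, and a 2-species stem map.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the random fixtures.
#' @return Named character vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(toy = file.path(dir, "toy3.csv"),
             csr = file.path(dir, "csr_small.csv"),
             thomas = file.path(dir, "thomas_small.csv"),
             community = file.path(dir, "two_species.csv"))
  utils::write.csv(data.frame(x = c(0.5, 1.5, 1.5), y = c(0.5, 0.5, 1.5)),
                   paths["toy"], row.names = FALSE)
  ls <- landscape(100, 100)
  p1 <- simulate_csr(80, ls, seed = seed)
  utils::write.csv(data.frame(x = p1$x, y = p1$y), paths["csr"],
                   row.names = FALSE)
  p2 <- simulate_thomas(thomas_params(0.003, 4, 3), ls, seed = seed + 1L)
  utils::write.csv(data.frame(x = p2$x, y = p2$y), paths["thomas"],
                   row.names = FALSE)
  p3 <- simulate_csr(60, ls, seed = seed + 2L)
  p4 <- simulate_thomas(thomas_params(0.004, 5, 2.5), ls, seed = seed + 3L)
  utils::write.csv(data.frame(
    x = c(p3$x, p4$x), y = c(p3$y, p4$y),
    species = rep(c("spA", "spB"), c(p3$n, p4$n))),
    paths["community"], row.names = FALSE)
  paths
}
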