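#' Configuration for a synthetic bounty landscape
#'
#' The generator lays hunting units on a regular planar grid and gives the
#' top predator a circular range ("disc" geometry, default): abundance is
#' ~0 outside the range edge, rises linearly to a plateau over `top_rise` km
#' inside it, and stays at the plateau toward the core. The mesopredator's
#' expected bounty rate declines linearly with distance into the range —
#' passing through `meso_outside_level` at the edge, so rates are higher
#' further outside — until it reaches `meso_floor` at `true_breakpoint_b` km
#' inside, and stays at that floor deeper in: a continuous piecewise-linear
#' suppression profile with a single knee, which is the breakpoint the
#' pipeline should recover. Counts are Poisson draws of rate x years. The
#' generator emits rates/counts only; z-scores arise downstream through the
#' pipeline's own standardization, mirroring the real data flow.
#'
#' The disc geometry makes the true signed distance to the range edge well
#' defined for every unit in two dimensions (`d* = R - distance to range
#' center`), which is what the closed isopleth stage estimates. A
#' `"halfplane"` geometry (straight north-south edge at `edge_x`, range to
#' the east) is available for one-dimensional checks; note that with a
#' bounded unit grid the fitted isopleth still closes around the data, so
#' deep-core distances are then capped by the grid's own extent.
#'
#' @param n_units_x,n_units_y grid dimensions; default 15 x 10 = 150 units.
#' @param unit_spacing grid spacing, km; default 100 (bounty tallies over
#'   100 km x 100 km squares).
#' @param edge_x westernmost x-position of the true range edge, km.
#' @param range_radius disc geometry: true range radius, km.
#' @param top_rise distance over which the top predator rises from 0 to its
#'   plateau, km (small relative to the range: the edge is sharp).
#' @param true_breakpoint_b distance inside the edge at which the
#'   mesopredator reaches its floor, km.
#' @param meso_outside_level expected mesopredator bounty rate outside the
#'   range, bounties/year.
#' @param meso_floor expected mesopredator bounty rate at and beyond the
#'   breakpoint, bounties/year.
#' @param rate_scale top predator plateau bounty rate, bounties/year.
#' @param noise_model `"poisson"` (counts ~ Poisson(rate x years)) or
#'   `"none"` (counts = round(rate x years)).
#' @param years collection years.
#' @param seed optional RNG seed; a fixed seed makes the dataset bit-identical.
#' @param geometry `"disc"` (default) or `"halfplane"`.
#' @param top_ramp `"linear"` (clamped ramp, default) or `"logistic"`.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_units_x = 15, n_units_y = 10,
                             unit_spacing = 100, edge_x = 250,
                             range_radius = 450, top_rise = 50,
                             true_breakpoint_b = 300,
                             meso_outside_level = 6, meso_floor = 0.3,
                             rate_scale = 5,
                             noise_model = c("poisson", "none"),
                             years = 10, seed = NULL,
                             geometry = c("disc", "halfplane"),
                             top_ramp = c("linear", "logistic")) {
  noise_model <- match.arg(noise_model)
  geometry <- match.arg(geometry)
  top_ramp <- match.arg(top_ramp)
  stopifnot(n_units_x >= 2, n_units_y >= 2, unit_spacing > 0, top_rise > 0,
            true_breakpoint_b > 0, rate_scale > 0, years >= 1,
            meso_outside_level > meso_floor, meso_floor >= 0)
  if (geometry == "disc" && range_radius <= true_breakpoint_b) {
    stop("range_radius must exceed true_breakpoint_b, or the mesopredator ",
         "floor is never reached inside the range", call. = FALSE)
  }
  structure(
    list(n_units_x = n_units_x, n_units_y = n_units_y,
         unit_spacing = unit_spacing, edge_x = edge_x,
         range_radius = range_radius, top_rise = top_rise,
         true_breakpoint_b = true_breakpoint_b,
         meso_outside_level = meso_outside_level, meso_floor = meso_floor,
         rate_scale = rate_scale, noise_model = noise_model, years = years,
         seed = seed, geometry = geometry, top_ramp = top_ramp),
    class = "synthetic_config"
  )
}

#' Expected abundance rates as functions of true distance to the edge
#'
#' The conceptual suppression profile: the top predator's rate is
#' `rate_scale * clamp(d*/top_rise, 0, 1)` (or a logistic ramp of the same
#' midpoint and width), zero at and outside the edge; the mesopredator's
#' rate is linear in `d*` with a single knee: it declines through
#' `meso_outside_level` at `d* = 0` down to `meso_floor` at
#' `d* = true_breakpoint_b` and is constant beyond. Both functions are
#' continuous.
#'
#' @param d_star true signed distance to the range edge, km (negative
#'   outside).
#' @param config a `synthetic_config`.
#' @return List with numeric vectors `mu_top` and `mu_meso` (bounties/year).
#' @export
ech_mean_functions <- function(d_star, config) {
  stopifnot(inherits(config, "synthetic_config"))
  mu_top <- if (config$top_ramp == "linear") {
    config$rate_scale * pmin(pmax(d_star / config$top_rise, 0), 1)
  } else {
    config$rate_scale *
      stats::plogis(d_star, location = config$top_rise / 2,
                    scale = config$top_rise / 8)
  }
  b <- config$true_breakpoint_b
  lvl <- config$meso_outside_level
  flr <- config$meso_floor
  # single knee at b: the decline runs linearly through the edge (rates are
  # higher further outside) and flattens at the floor from b inward
  mu_meso <- lvl + (flr - lvl) * pmin(d_star / b, 1)
  list(mu_top = mu_top, mu_meso = mu_meso)
}

#' Generate a synthetic bounty landscape with known ground truth
#'
#' Draws one bounty dataset under the configured suppression profile and
#' returns it together with the per-unit truth (true signed distance and
#' expected rates), so recovery of the range edge and the mesopredator
#' breakpoint can be measured exactly.
#'
#' @param config a `synthetic_config`.
#' @return List of class `synthetic_landscape` with elements `dataset`
#'   (a `bounty_dataset`, species `"toppred"`/`"mesopred"`) and `truth`
#'   (tibble: `unit_id`, `x`, `y`, `d_star`, `mu_top`, `mu_meso`), plus the
#'   config as an attribute.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  xs <- (seq_len(config$n_units_x) - 1) * config$unit_spacing
  ys <- (seq_len(config$n_units_y) - 1) * config$unit_spacing
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  if (config$geometry == "disc") {
    cx <- config$edge_x + config$range_radius
    cy <- (max(ys) + min(ys)) / 2
    d_star <- config$range_radius - sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
  } else {
    d_star <- grid$x - config$edge_x
  }
  mu <- ech_mean_functions(d_star, config)
  lam_top <- mu$mu_top * config$years
  lam_meso <- mu$mu_meso * config$years
  if (config$noise_model == "poisson") {
    counts_top <- stats::rpois(length(lam_top), lam_top)
    counts_meso <- stats::rpois(length(lam_meso), lam_meso)
  } else {
    counts_top <- round(lam_top)
    counts_meso <- round(lam_meso)
  }
  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(nrow(grid))),
    x = grid$x, y = grid$y,
    toppred = as.integer(counts_top),
    mesopred = as.integer(counts_meso),
    years = config$years
  )
  dataset <- bounty_dataset(units,
                            species_roles = c(toppred = "top",
                                              mesopred = "meso"),
                            region_label = "synthetic")
  truth <- tibble::tibble(
    unit_id = units$unit_id, x = units$x, y = units$y,
    d_star = d_star, mu_top = mu$mu_top, mu_meso = mu$mu_meso
  )
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("<synthetic_landscape> ", nrow(x$truth), " units (",
      x$config$geometry, " geometry, ", x$config$noise_model, " noise)\n",
      sep = "")
  cat("  true breakpoint: ", x$config$true_breakpoint_b, " km\n", sep = "")
  invisible(x)
}

#' Write the generator's ground truth as JSON
#'
#' @param landscape a `synthetic_landscape`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(landscape, path) {
  jsonlite::write_json(
    list(config = unclass(landscape$config),
         truth = landscape$truth),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
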