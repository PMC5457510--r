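#' Density threshold enclosing a probability volume
#'
#' Finds the density value `t` such that the cells with density >= `t` hold
#' the smallest cumulative mass at least `level_p` of the surface total —
#' the volume-contour rule used to delineate a range from a utilization
#' surface. All cells tied at the threshold are included (mass overshoot is
#' allowed and reported by [extract_isopleth()]).
#'
#' @param surface a `density_surface`.
#' @param level_p probability level in (0, 1); default 0.85, the level used
#'   to define a top predator's range edge.
#' @return The density threshold (per km^2).
#' @export
volume_threshold <- function(surface, level_p = 0.85) {
  if (!is.numeric(level_p) || level_p <= 0 || level_p >= 1) {
    stop("level_p must lie strictly between 0 and 1", call. = FALSE)
  }
  v <- as.vector(surface$values)
  cell_mass <- v * surface$cell_size^2
  total <- sum(cell_mass)
  if (total < 0.98) stop("surface mass below 0.98; rebuild with more padding",
                         call. = FALSE)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(cell_mass[ord])
  k <- which(cum >= level_p * total)[1]
  thr <- v[ord][k]
  pos <- unique(v[v > 0])
  if (length(pos) == 1) {
    warning("uniform surface: all cells tie at the threshold; ",
            "contained mass will be 1")
  }
  thr
}

#' Extract the probability isopleth (range edge) from a density surface
#'
#' Runs marching squares (with linear interpolation along cell edges) at the
#' volume threshold and returns all closed contour rings. The realized
#' contained mass is reported two ways, bracketing the isopleth accounting:
#' by cells (mass of cells at or above the threshold) and by interpolated
#' ring area (km^2).
#'
#' @param surface a `density_surface`.
#' @param level_p probability level; used when `threshold` is `NULL`.
#' @param threshold optional density threshold overriding `level_p`.
#' @param min_ring_mass prune rings holding less than this fraction of the
#'   contained mass; default 0 (keep every ring).
#' @return An object of class `range_edge`: `level_p`, `threshold`, `rings`
#'   (list of closed two-column matrices, km), `ring_mass`, `contained_mass`
#'   (fraction of total surface mass), `area_km2`, `hole` (logical, rings
#'   nested inside another ring).
#' @export
extract_isopleth <- function(surface, level_p = 0.85, threshold = NULL,
                             min_ring_mass = 0) {
  if (is.null(threshold)) threshold <- volume_threshold(surface, level_p)
  v <- surface$values
  if (!any(v >= threshold)) {
    stop("no cell reaches the threshold; empty range edge", call. = FALSE)
  }
  cl <- grDevices::contourLines(surface$x, surface$y, v, levels = threshold)
  cell_mass <- v * surface$cell_size^2
  total <- sum(cell_mass)
  contained <- sum(cell_mass[v >= threshold]) / total

  if (length(cl) == 0) {
    # every cell at or above threshold (degenerate, e.g. uniform surface):
    # the grid boundary is the only sensible edge
    warning("threshold below every interior gradient; using grid boundary ",
            "as the range edge")
    hx <- surface$cell_size / 2
    ring <- rbind(
      c(min(surface$x) - hx, min(surface$y) - hx),
      c(max(surface$x) + hx, min(surface$y) - hx),
      c(max(surface$x) + hx, max(surface$y) + hx),
      c(min(surface$x) - hx, max(surface$y) + hx),
      c(min(surface$x) - hx, min(surface$y) - hx)
    )
    rings <- list(ring)
  } else {
    rings <- lapply(cl, function(l) {
      ring <- cbind(l$x, l$y)
      if (any(ring[1, ] != ring[nrow(ring), ])) {
        if (sqrt(sum((ring[1, ] - ring[nrow(ring), ])^2)) >
            2 * surface$cell_size) {
          warning("open contour polyline closed across the grid boundary; ",
                  "consider more padding")
        }
        ring <- rbind(ring, ring[1, ])
      }
      ring
    })
  }

  # per-ring mass: assign each super-threshold cell to its innermost
  # enclosing ring
  idx <- which(v >= threshold, arr.ind = TRUE)
  cx <- surface$x[idx[, 1]]
  cy <- surface$y[idx[, 2]]
  cm <- cell_mass[v >= threshold]
  areas <- vapply(rings, ring_area, 0)
  inside_mat <- vapply(rings, function(r) point_in_ring(cx, cy, r),
                       logical(length(cx)))
  inside_mat <- matrix(inside_mat, nrow = length(cx))
  ring_mass <- numeric(length(rings))
  if (length(cx) > 0) {
    owner <- apply(inside_mat, 1, function(row) {
      hit <- which(row)
      if (length(hit) == 0) return(NA_integer_)
      hit[which.min(areas[hit])]
    })
    tab <- tapply(cm, factor(owner, levels = seq_along(rings)), sum)
    ring_mass <- ifelse(is.na(tab), 0, tab) / total
  }

  # nesting parity: a ring whose vertex lies inside an odd number of other
  # rings bounds a hole
  hole <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1, , drop = FALSE]
    depth <- sum(vapply(seq_along(rings)[-i], function(j) {
      point_in_ring(p[1], p[2], rings[[j]])
    }, logical(1)))
    depth %% 2 == 1
  }, logical(1))

  if (min_ring_mass > 0) {
    keep <- ring_mass >= min_ring_mass * sum(ring_mass) | hole
    rings <- rings[keep]
    ring_mass <- ring_mass[keep]
    hole <- hole[keep]
    areas <- areas[keep]
  }

  structure(
    list(level_p = level_p, threshold = threshold, rings = rings,
         ring_mass = as.numeric(ring_mass), contained_mass = contained,
         area_km2 = sum(areas[!hole]) - sum(areas[hole]), hole = hole,
         cell_size = surface$cell_size),
    class = "range_edge"
  )
}

#' @export
print.range_edge <- function(x, ...) {
  cat("<range_edge> level ", x$level_p, " (threshold ",
      format(x$threshold, digits = 4), " per km^2)\n", sep = "")
  cat("  rings: ", length(x$rings), " (", sum(x$hole), " hole(s))",
      "   contained mass: ", format(round(x$contained_mass, 4)),
      "   area: ", format(round(x$area_km2)), " km^2\n", sep = "")
  invisible(x)
}

# signed area of a closed ring (positive = counter-clockwise); returns |area|
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  i <- seq_len(n - 1)
  abs(sum(x[i] * y[i + 1] - x[i + 1] * y[i]) / 2)
}

# even-odd (ray casting) point-in-ring test, vectorized over points
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n - 1 # ring is closed: vertex n duplicates vertex 1
  for (i in seq_len(n - 1)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from points to the segments of one ring
point_ring_distance <- function(px, py, ring) {
  best <- rep(Inf, length(px))
  n <- nrow(ring)
  for (i in seq_len(n - 1)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx^2 + dy^2
    if (l2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Signed distance from points to a range edge
#'
#' Distance (km) from each point to the closest location on any edge ring,
#' multiplied by -1 for points lying outside the range: negative values are
#' outside the probability contour, positive values inside. Interior
#' membership uses the even-odd rule across all rings, so holes count as
#' outside.
#'
#' @param px,py point coordinates, km.
#' @param edge a `range_edge`.
#' @return Numeric vector of signed distances, km.
#' @export
signed_distance <- function(px, py, edge) {
  if (!inherits(edge, "range_edge")) stop("edge must be a range_edge",
                                          call. = FALSE)
  if (length(edge$rings) == 0) stop("edge has no rings", call. = FALSE)
  if (any(!is.finite(px)) || any(!is.finite(py))) {
    stop("non-finite point coordinates at index ",
         paste(which(!is.finite(px) | !is.finite(py)), collapse = ", "),
         call. = FALSE)
  }
  d <- rep(Inf, length(px))
  inside <- rep(FALSE, length(px))
  for (ring in edge$rings) {
    d <- pmin(d, point_ring_distance(px, py, ring))
    inside <- xor(inside, point_in_ring(px, py, ring))
  }
  ifelse(inside, d, -d)
}

#' Per-unit signed distance-to-edge profile with z-scored indices
#'
#' Pairs every hunting unit's signed distance to the top predator's range
#' edge with its z-scored abundance indices for both species. Distances for
#' both species are measured to the top predator's edge.
#'
#' @param dataset a `bounty_dataset` (after any exclusion filtering).
#' @param edge a `range_edge` for the top predator.
#' @param ddof passed to [zscore()].
#' @return A tibble with columns `unit_id`, `d_km`, `z_top`, `z_meso`,
#'   `inside` (0/1), `x`, `y`.
#' @export
distance_profile <- function(dataset, edge, ddof = 1) {
  stopifnot(inherits(dataset, "bounty_dataset"))
  bad <- !is.finite(dataset$units$x) | !is.finite(dataset$units$y)
  if (any(bad)) {
    stop("non-finite centroid for unit(s): ",
         paste(dataset$units$unit_id[bad], collapse = ", "), call. = FALSE)
  }
  d <- signed_distance(dataset$units$x, dataset$units$y, edge)
  idx <- abundance_indices(dataset, ddof = ddof)
  top <- species_for_role(dataset, "top")
  meso <- species_for_role(dataset, "meso")
  z_top <- idx$z[idx$species == top]
  z_meso <- idx$z[idx$species == meso]
  tibble::tibble(
    unit_id = dataset$units$unit_id,
    d_km = d,
    z_top = z_top,
    z_meso = z_meso,
    inside = as.integer(d > 0),
    x = dataset$units$x,
    y = dataset$units$y
  )
}

#' Export a range edge as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection with one MultiPolygon feature; each
#' ring becomes a polygon ring (holes follow the even-odd semantics of
#' [signed_distance()]). Coordinates are in the working projected CRS (km).
#'
#' @param edge a `range_edge`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_geojson <- function(edge, path) {
  polys <- lapply(edge$rings, function(r) {
    list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = polys),
      properties = list(
        level_p = edge$level_p,
        threshold = edge$threshold,
        contained_mass = edge$contained_mass,
        area_km2 = edge$area_km2
      )
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
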