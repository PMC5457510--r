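#' Assemble a bounty dataset from per-hunting-unit records
#'
#' A bounty dataset holds one row per hunting unit: an identifier, the unit
#' centroid in a projected metric coordinate system (km), one bounty-count
#' column per species, and the number of collection years. Species are mapped
#' to ecological roles: exactly one `"top"` (apex) predator and one `"meso"`
#' (suppressed) predator per analysis run.
#'
#' Coordinates must already be projected; no reprojection is performed. Counts
#' are validated as non-negative integers and unit identifiers must be unique.
#'
#' @param units data frame with columns `unit_id`, `x`, `y`, one integer count
#'   column per species named in `species_roles`, and optionally `years`
#'   (per-unit collection years applying to all species).
#' @param species_roles named character vector mapping species (column) name to
#'   role, e.g. `c(wolf = "top", coyote = "meso")`.
#' @param years dataset-wide collection years: a single number, or a named
#'   vector with one entry per species (used when national datasets with
#'   different spans are pooled). Ignored for units that carry their own
#'   `years` column value.
#' @param region_label free-text label for the analysis region.
#' @param polygons optional named list (by `unit_id`) of closed coordinate
#'   rings (two-column matrices, km) describing unit boundaries.
#' @return An object of class `bounty_dataset`.
#' @export
bounty_dataset <- function(units, species_roles, years = NULL,
                           region_label = "", polygons = NULL) {
  units <- tibble::as_tibble(units)
  required <- c("unit_id", "x", "y")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  species <- names(species_roles)
  if (length(species) == 0 || is.null(species)) {
    stop("species_roles must be a named vector of roles", call. = FALSE)
  }
  if (!all(species_roles %in% c("top", "meso"))) {
    stop("species roles must be 'top' or 'meso'", call. = FALSE)
  }
  if (sum(species_roles == "top") != 1 || sum(species_roles == "meso") != 1) {
    stop("exactly one 'top' and one 'meso' species are required", call. = FALSE)
  }
  missing_sp <- setdiff(species, names(units))
  if (length(missing_sp) > 0) {
    stop("missing count column(s): ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(units$unit_id)) {
    dups <- unique(units$unit_id[duplicated(units$unit_id)])
    stop("duplicate unit_id: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(units$x)) || !all(is.finite(units$y))) {
    bad <- units$unit_id[!is.finite(units$x) | !is.finite(units$y)]
    stop("non-finite centroid coordinates for unit(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (sp in species) {
    cnt <- units[[sp]]
    if (any(is.na(cnt))) {
      stop("missing count for species '", sp, "'", call. = FALSE)
    }
    if (any(cnt < 0)) {
      bad <- units$unit_id[cnt < 0]
      stop("negative count for species '", sp, "' in unit(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(abs(cnt - round(cnt)) > 1e-8)) {
      bad <- units$unit_id[abs(cnt - round(cnt)) > 1e-8]
      stop("non-integer count for species '", sp, "' in unit(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    units[[sp]] <- as.integer(round(cnt))
  }
  if (!"years" %in% names(units)) {
    if (is.null(years)) {
      stop("collection years must be given (column 'years' or argument)",
           call. = FALSE)
    }
    units$years <- if (length(years) == 1 && is.null(names(years))) {
      as.numeric(years)
    } else {
      NA_real_ # per-species years held separately
    }
  }
  species_years <- NULL
  if (!is.null(years) && !is.null(names(years))) {
    missing_sp <- setdiff(species, names(years))
    if (length(missing_sp) > 0) {
      stop("years missing for species: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
    species_years <- as.numeric(years[species])
    names(species_years) <- species
  }
  yr_all <- c(units$years[!is.na(units$years)], species_years)
  if (length(yr_all) == 0 || any(yr_all < 1)) {
    stop("collection years must be >= 1", call. = FALSE)
  }
  structure(
    list(
      units = units,
      species_roles = species_roles,
      species_years = species_years,
      region_label = region_label,
      polygons = polygons
    ),
    class = "bounty_dataset"
  )
}

#' @export
print.bounty_dataset <- function(x, ...) {
  roles <- x$species_roles
  cat("<bounty_dataset>", if (nzchar(x$region_label)) x$region_label else NULL, "\n")
  cat("  units:  ", nrow(x$units), "\n", sep = "")
  cat("  top:    ", names(roles)[roles == "top"], "\n", sep = "")
  cat("  meso:   ", names(roles)[roles == "meso"], "\n", sep = "")
  invisible(x)
}

#' Species name holding a given role
#' @param dataset a `bounty_dataset`.
#' @param role `"top"` or `"meso"`.
#' @return Species (column) name.
#' @export
species_for_role <- function(dataset, role = c("top", "meso")) {
  role <- match.arg(role)
  names(dataset$species_roles)[dataset$species_roles == role]
}

years_for_species <- function(dataset, sp) {
  yr <- dataset$units$years
  if (!is.null(dataset$species_years) && sp %in% names(dataset$species_years)) {
    yr_sp <- dataset$species_years[[sp]]
    yr <- ifelse(is.na(yr), yr_sp, yr)
    # explicit per-species years override the shared column when both exist
    if (all(is.na(dataset$units$years))) yr <- rep(yr_sp, nrow(dataset$units))
  }
  if (any(is.na(yr))) stop("collection years undefined for species '", sp, "'",
                           call. = FALSE)
  yr
}

#' Read a bounty table from CSV or GeoJSON
#'
#' The CSV dialect has columns `unit_id`, `x`, `y`, one count column per
#' species and `years` (header row required, UTF-8, `.` decimal separator).
#' The GeoJSON dialect (RFC 7946) is a FeatureCollection of Polygon features
#' whose `properties` carry the same fields; centroids are taken from the
#' `x`/`y` properties when present, otherwise computed as the area-weighted
#' polygon centroid.
#'
#' @param path file path.
#' @param species_roles named character vector mapping species name to role
#'   (`"top"`/`"meso"`), see [bounty_dataset()].
#' @param format `"csv"` or `"geojson"`; guessed from the file extension by
#'   default.
#' @param years optional dataset-wide or per-species collection years, used
#'   when the table has no `years` column.
#' @param coord_units `"km"` (default) or `"m"`; metre coordinates are divided
#'   by 1000 on ingest. Distances throughout the package are in km.
#' @param region_label free-text label attached to the dataset.
#' @return A `bounty_dataset`.
#' @export
read_bounty_table <- function(path, species_roles,
                              format = c("auto", "csv", "geojson"),
                              years = NULL, coord_units = c("km", "m"),
                              region_label = "") {
  format <- match.arg(format)
  coord_units <- match.arg(coord_units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "csv"
    }
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    required <- c("unit_id", "x", "y", names(species_roles))
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0) {
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    polygons <- NULL
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$type) || gj$type != "FeatureCollection") {
      stop("GeoJSON input must be a FeatureCollection", call. = FALSE)
    }
    rows <- list()
    polygons <- list()
    for (ft in gj$features) {
      props <- ft$properties
      ring <- NULL
      if (!is.null(ft$geometry) && identical(ft$geometry$type, "Polygon")) {
        ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]],
                                      function(p) c(p[[1]], p[[2]])))
      }
      cxy <- c(props$x, props$y)
      if (length(cxy) < 2 || is.null(props$x) || is.null(props$y)) {
        if (is.null(ring)) {
          stop("feature without centroid properties or polygon geometry",
               call. = FALSE)
        }
        cxy <- polygon_centroid(ring)
      }
      row <- c(list(unit_id = props$unit_id, x = cxy[1], y = cxy[2]),
               props[setdiff(names(props), c("unit_id", "x", "y"))])
      rows[[length(rows) + 1]] <- row
      if (!is.null(ring)) polygons[[as.character(props$unit_id)]] <- ring
    }
    tab <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    if (length(polygons) == 0) polygons <- NULL
  }
  if (coord_units == "m") {
    tab$x <- tab$x / 1000
    tab$y <- tab$y / 1000
  }
  if (max(abs(c(tab$x, tab$y))) > 1e5) {
    warning("coordinate magnitudes look larger than plausible km values; ",
            "did you mean coord_units = 'm'?")
  }
  bounty_dataset(tab, species_roles = species_roles, years = years,
                 region_label = region_label, polygons = polygons)
}

#' Write a bounty dataset as CSV
#'
#' Columns are written in the stable order `unit_id`, `x`, `y`, top-predator
#' counts, mesopredator counts, `years`.
#'
#' @param dataset a `bounty_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bounty_csv <- function(dataset, path) {
  top <- species_for_role(dataset, "top")
  meso <- species_for_role(dataset, "meso")
  cols <- c("unit_id", "x", "y", top, meso, "years")
  utils::write.csv(dataset$units[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# area-weighted centroid of a closed ring (shoelace formula)
polygon_centroid <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  i <- seq_len(n - 1); j <- i + 1
  cross <- x[i] * y[j] - x[j] * y[i]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x[i]), mean(y[i])))
  c(sum((x[i] + x[j]) * cross) / (6 * a),
    sum((y[i] + y[j]) * cross) / (6 * a))
}

#' Convert bounty counts to per-year abundance rates
#'
#' The abundance index of each species in each hunting unit is its total
#' bounty count divided by the number of collection years, which standardizes
#' datasets with different collection spans.
#'
#' @param dataset a `bounty_dataset`.
#' @return A tibble with columns `unit_id`, `species`, `role`, `rate`
#'   (bounties per year) and `z` (`NA` until [zscore()] is applied).
#' @export
standardize_rate <- function(dataset) {
  stopifnot(inherits(dataset, "bounty_dataset"))
  out <- lapply(names(dataset$species_roles), function(sp) {
    yr <- years_for_species(dataset, sp)
    if (any(yr < 1)) stop("years must be >= 1", call. = FALSE)
    tibble::tibble(
      unit_id = dataset$units$unit_id,
      species = sp,
      role = unname(dataset$species_roles[[sp]]),
      rate = dataset$units[[sp]] / yr,
      z = NA_real_
    )
  })
  do.call(rbind, out)
}

#' z-score a numeric vector
#'
#' Standardizes by subtracting the mean and dividing by the standard
#' deviation, so that indices from different regions are directly comparable.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @param ddof delta degrees of freedom for the standard deviation: `1`
#'   (default, sample s.d.) or `0` (population s.d.).
#' @return Numeric vector with mean 0 and s.d. 1 (per `ddof`), same order.
#' @export
zscore <- function(values, ddof = 1) {
  if (!ddof %in% c(0, 1)) stop("ddof must be 0 or 1", call. = FALSE)
  n <- length(values)
  if (n < 2) stop("need at least 2 values to z-score", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / (n - ddof))
  if (s <= 0) stop("cannot z-score a constant vector (zero s.d.)", call. = FALSE)
  (values - m) / s
}

#' Drop hunting units with neither predator recorded
#'
#' Units where both the top predator and the mesopredator counts are zero are
#' removed before model fitting; units where exactly one species is absent are
#' retained (a zero for one species is information about suppression, a double
#' zero is indistinguishable from no sampling effort).
#'
#' @param dataset a `bounty_dataset`.
#' @return A `bounty_dataset` with the double-zero units removed. The removed
#'   identifiers are attached as attribute `"removed_units"`.
#' @export
exclude_double_zero <- function(dataset) {
  stopifnot(inherits(dataset, "bounty_dataset"))
  top <- species_for_role(dataset, "top")
  meso <- species_for_role(dataset, "meso")
  keep <- dataset$units[[top]] > 0 | dataset$units[[meso]] > 0
  removed <- dataset$units$unit_id[!keep]
  if (length(removed) > 0) {
    message("excluding ", length(removed),
            " unit(s) with zero counts for both species: ",
            paste(utils::head(removed, 10), collapse = ", "),
            if (length(removed) > 10) ", ..." else "")
  }
  out <- dataset
  out$units <- dataset$units[keep, , drop = FALSE]
  if (nrow(out$units) == 0) warning("all units removed: every unit had zero ",
                                    "counts for both species")
  attr(out, "removed_units") <- removed
  out
}

#' Per-unit z-scored abundance indices
#'
#' Convenience wrapper: [standardize_rate()] followed by [zscore()] within
#' each species across the dataset.
#'
#' @inheritParams standardize_rate
#' @param ddof passed to [zscore()].
#' @return The tibble of [standardize_rate()] with `z` filled in.
#' @export
abundance_indices <- function(dataset, ddof = 1) {
  idx <- standardize_rate(dataset)
  for (sp in unique(idx$species)) {
    sel <- idx$species == sp
    idx$z[sel] <- zscore(idx$rate[sel], ddof = ddof)
  }
  idx
}
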