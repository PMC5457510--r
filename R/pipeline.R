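#' Run the full range-edge breakpoint analysis
#'
#' Executes the whole pipeline on one regional bounty dataset:
#' double-zero exclusion, per-year rate standardization, weighted Gaussian
#' kernel density surface of the top predator, probability isopleth (range
#' edge), signed distances from every unit centroid to that edge, z-scoring,
#' continuous one-breakpoint piecewise regressions of both species' indices
#' on distance, bootstrap confidence intervals and slope-change tests,
#' no-clear-breakpoint detection, and spatial residual diagnostics
#' (standardized-residual maps plus permutation Moran's I). Both species'
#' regressions use distances to the top predator's edge.
#'
#' All tabular and JSON outputs are deterministic given the dataset, the
#' parameters and `seed`; plots are written alongside but carry no additional
#' data. When a stage fails, the error is re-raised with the stage name and a
#' `MANIFEST.txt` in `out_dir` records the failure point next to any outputs
#' already written.
#'
#' @param dataset a `bounty_dataset`, or a path to a CSV/GeoJSON bounty table
#'   (then `species_roles` must be given).
#' @param out_dir output directory; created if missing. `NULL` (default)
#'   computes everything in memory and writes nothing.
#' @param species_roles passed to [read_bounty_table()] when `dataset` is a
#'   path.
#' @param cell_size KDE grid cell edge, km; default 2.5.
#' @param level_p isopleth probability level; default 0.85.
#' @param bandwidth_method `"silverman"`, `"plugin"`, `"scv"` or `"fixed"`.
#' @param fixed_h kernel s.d. (km) when `bandwidth_method = "fixed"`.
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed RNG seed governing the bootstrap and permutation stages.
#' @param ddof degrees-of-freedom convention for z-scoring (default 1).
#' @param k_neighbors,n_perm Moran's I settings.
#' @param write_plots,write_surface control optional artifacts.
#' @return An object of class `ech_report` (list): `params`, `region`,
#'   `n_units`, `excluded_units`, `bandwidth`, `edge`, `profile`, and per-role
#'   results under `fits$top` / `fits$meso` (`fit`, `boot`, `no_breakpoint`,
#'   `moran`, `diagnostics`).
#' @export
run_ech_analysis <- function(dataset, out_dir = NULL, species_roles = NULL,
                             cell_size = 2.5, level_p = 0.85,
                             bandwidth_method = "silverman", fixed_h = NULL,
                             n_boot = 1000, seed = NULL, ddof = 1,
                             k_neighbors = 8, n_perm = 999,
                             write_plots = TRUE, write_surface = FALSE) {
  if (is.character(dataset)) {
    if (is.null(species_roles)) {
      stop("species_roles is required when dataset is a file path",
           call. = FALSE)
    }
    dataset <- read_bounty_table(dataset, species_roles = species_roles)
  }
  stopifnot(inherits(dataset, "bounty_dataset"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)
  finish_manifest <- function(status) {
    if (!is.null(out_dir)) {
      writeLines(c(paste0("status: ", status), manifest),
                 file.path(out_dir, "MANIFEST.txt"))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      finish_manifest(paste0("failed at stage: ", name))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  params <- list(
    cell_size = cell_size, level_p = level_p,
    bandwidth_method = bandwidth_method, fixed_h = fixed_h,
    n_boot = n_boot, seed = seed, ddof = ddof,
    k_neighbors = k_neighbors, n_perm = n_perm,
    version = as.character(utils::packageVersion("mesobreak"))
  )

  n_before <- nrow(dataset$units)
  dataset <- stage("exclude_double_zero", exclude_double_zero(dataset))
  excluded <- attr(dataset, "removed_units")
  top_sp <- species_for_role(dataset, "top")

  rates <- stage("standardize_rate", standardize_rate(dataset))
  top_rate <- rates$rate[rates$species == top_sp]

  bw <- stage("select_bandwidth", select_bandwidth(
    cbind(dataset$units$x, dataset$units$y), weights = top_rate,
    method = bandwidth_method, fixed_h = fixed_h
  ))
  surface <- stage("estimate_density", estimate_density(
    cbind(dataset$units$x, dataset$units$y), weights = top_rate,
    bandwidth = bw, cell_size = cell_size
  ))
  edge <- stage("extract_isopleth", extract_isopleth(surface, level_p))
  profile <- stage("signed_distance", distance_profile(dataset, edge,
                                                       ddof = ddof))

  seed_for <- function(offset) if (is.null(seed)) NULL else seed + offset
  roles <- list(top = profile$z_top, meso = profile$z_meso)
  fits <- list()
  for (j in seq_along(roles)) {
    role <- names(roles)[j]
    z <- roles[[j]]
    fit <- stage(paste0("fit_piecewise_", role),
                 fit_piecewise(profile$d_km, z))
    boot <- stage(paste0("bootstrap_", role),
                  bootstrap_breakpoint(profile$d_km, z, n_boot = n_boot,
                                       seed = seed_for(j)))
    nb <- detect_no_breakpoint(fit, boot)
    diag <- stage(paste0("residuals_", role),
                  standardized_residuals(fit, profile$x, profile$y,
                                         unit_id = profile$unit_id))
    moran <- stage(paste0("morans_i_", role), tryCatch(
      morans_i(diag$residual_std, diag$x, diag$y, k_neighbors = k_neighbors,
               n_perm = n_perm, seed = seed_for(10 + j)),
      error = function(e) NULL # < 10 units or constant residuals: report NA
    ))
    fits[[role]] <- list(fit = fit, boot = boot, no_breakpoint = nb,
                         diagnostics = diag, moran = moran)
  }

  report <- structure(
    list(params = params, region = dataset$region_label,
         n_units = c(before = n_before, after = nrow(dataset$units)),
         excluded_units = excluded, bandwidth = bw, surface = surface,
         edge = edge, profile = profile, fits = fits),
    class = "ech_report"
  )

  if (!is.null(out_dir)) {
    stage("write_outputs", {
      utils::write.csv(
        profile[, c("unit_id", "d_km", "z_top", "z_meso", "inside")],
        file.path(out_dir, "distance_profile.csv"), row.names = FALSE,
        quote = FALSE
      )
      note("distance_profile.csv")
      write_edge_geojson(edge, file.path(out_dir, "edge.geojson"))
      note("edge.geojson")
      for (role in names(fits)) {
        utils::write.csv(
          fits[[role]]$diagnostics[, c("unit_id", "x", "y", "residual_std")],
          file.path(out_dir, paste0("diagnostics_", role, ".csv")),
          row.names = FALSE, quote = FALSE
        )
        note(paste0("diagnostics_", role, ".csv"))
      }
      if (write_surface) {
        write_surface_csv(surface, file.path(out_dir, "surface.csv"))
        note("surface.csv")
      }
      jsonlite::write_json(report_json(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note("report.json")
      if (write_plots) {
        for (role in names(fits)) {
          plot_breakpoint_fit(profile, fits[[role]]$fit, fits[[role]]$boot,
                              role = role,
                              out_path = file.path(out_dir,
                                                   paste0("fit_", role,
                                                          ".png")))
          note(paste0("fit_", role, ".png"))
          residual_map(fits[[role]]$diagnostics,
                       out_path = file.path(out_dir,
                                            paste0("residuals_", role,
                                                   ".png")))
          note(paste0("residuals_", role, ".png"))
        }
      }
    })
    finish_manifest("ok")
  }
  report
}

# serializable summary of an ech_report (stable field order, no volatile
# content, so identical runs produce identical bytes)
report_json <- function(report) {
  fit_block <- function(role) {
    fr <- report$fits[[role]]
    list(
      region = report$region,
      species_role = role,
      b_km = fr$fit$breakpoint,
      ci_km = c(fr$boot$ci_low, fr$boot$ci_high),
      beta = unname(fr$fit$coefficients),
      r2 = fr$fit$r2,
      p_slope_change = fr$boot$p_slope_change,
      n = fr$fit$n,
      n_boot = fr$boot$n_boot,
      seed = fr$boot$seed,
      no_clear_breakpoint = fr$no_breakpoint$no_clear_breakpoint,
      reason = fr$no_breakpoint$reason,
      morans_i = if (is.null(fr$moran)) NA else fr$moran$i,
      morans_p = if (is.null(fr$moran)) NA else fr$moran$p
    )
  }
  list(
    params = report$params,
    region = report$region,
    n_units = as.list(report$n_units),
    excluded_units = report$excluded_units,
    bandwidth = list(matrix = report$bandwidth$matrix,
                     method_tag = report$bandwidth$method_tag),
    edge = list(level_p = report$edge$level_p,
                threshold = report$edge$threshold,
                contained_mass = report$edge$contained_mass,
                area_km2 = report$edge$area_km2,
                n_rings = length(report$edge$rings)),
    fits = list(top = fit_block("top"), meso = fit_block("meso"))
  )
}

#' @export
print.ech_report <- function(x, ...) {
  cat("<ech_report> region: ",
      if (nzchar(x$region)) x$region else "(unlabelled)", "\n", sep = "")
  cat("  units: ", x$n_units[["after"]], " analysed (",
      x$n_units[["before"]] - x$n_units[["after"]], " double-zero excluded)\n",
      sep = "")
  cat("  edge: ", length(x$edge$rings), " ring(s), contained mass ",
      format(round(x$edge$contained_mass, 3)), "\n", sep = "")
  for (role in names(x$fits)) {
    fr <- x$fits[[role]]
    cat(sprintf(
      "  %-4s breakpoint %8.1f km  CI [%.1f, %.1f]  R²=%.2f  p=%s%s\n",
      role, fr$fit$breakpoint, fr$boot$ci_low, fr$boot$ci_high, fr$fit$r2,
      format.pval(fr$boot$p_slope_change),
      if (fr$no_breakpoint$no_clear_breakpoint) {
        paste0("  [no clear breakpoint: ", fr$no_breakpoint$reason, "]")
      } else ""
    ))
  }
  invisible(x)
}
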