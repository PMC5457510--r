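#' Standardized residuals of a piecewise fit, georeferenced
#'
#' Residuals `z - fitted` divided by their sample standard deviation,
#' attached to unit centroid coordinates so spatial structure can be
#' inspected (clumps of same-sign residuals indicate spatial dependence the
#' regression does not capture).
#'
#' @param fit a `piecewise_fit`.
#' @param x,y unit centroid coordinates, km, in the order of the fitted data.
#' @param unit_id optional unit identifiers.
#' @param d,z data the fit was computed on; default the data stored in `fit`.
#' @return A tibble of class `residual_diagnostics` with columns `unit_id`,
#'   `x`, `y`, `residual`, `residual_std`.
#' @export
standardized_residuals <- function(fit, x, y, unit_id = NULL,
                                   d = fit$d, z = fit$z) {
  if (length(x) != length(d) || length(y) != length(d)) {
    stop("coordinate lengths must match the fitted data", call. = FALSE)
  }
  res <- z - predict(fit, d)
  s <- stats::sd(res)
  if (!is.finite(s) || s < 1e-12) {
    warning("zero residual variance (perfect fit); standardized residuals ",
            "set to 0")
    rs <- rep(0, length(res))
  } else {
    rs <- res / s
  }
  out <- tibble::tibble(
    unit_id = if (is.null(unit_id)) seq_along(res) else unit_id,
    x = x, y = y, residual = res, residual_std = rs
  )
  class(out) <- c("residual_diagnostics", class(out))
  out
}

#' Moran's I of residuals with k-nearest-neighbour weights
#'
#' Quantitative complement to the visual residual map: Moran's I under a
#' row-standardized k-nearest-neighbour spatial weight matrix, with a
#' permutation p-value. Under spatial independence the expectation of I is
#' `-1/(n-1)`.
#'
#' @param values numeric vector (typically standardized residuals).
#' @param x,y coordinates, km.
#' @param k_neighbors neighbours per unit (default 8).
#' @param n_perm permutation count for the p-value (default 999).
#' @param seed optional RNG seed.
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two.sided"`.
#' @return List of class `morans_i_result`: `i`, `expectation`, `p`,
#'   `k_neighbors`, `n_perm`, `seed`, `alternative`.
#' @export
morans_i <- function(values, x, y, k_neighbors = 8, n_perm = 999,
                     seed = NULL, alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than n", call. = FALSE)
  if (stats::sd(values) < 1e-14) stop("constant values: Moran's I undefined",
                                      call. = FALSE)
  W <- knn_weights(x, y, k_neighbors)
  vc <- values - mean(values)
  denom <- sum(vc^2)
  quad <- function(v) sum(v * (W %*% v))
  i_obs <- quad(vc) / denom # S0 = n for row-standardized W, so n/S0 = 1
  if (!is.null(seed)) set.seed(seed)
  i_perm <- vapply(seq_len(n_perm), function(r) {
    quad(vc[sample.int(n)]) / denom
  }, 0)
  p <- switch(alternative,
    greater = (1 + sum(i_perm >= i_obs)) / (n_perm + 1),
    less = (1 + sum(i_perm <= i_obs)) / (n_perm + 1),
    two.sided = {
      e <- -1 / (n - 1)
      (1 + sum(abs(i_perm - e) >= abs(i_obs - e))) / (n_perm + 1)
    }
  )
  structure(
    list(i = i_obs, expectation = -1 / (n - 1), p = p,
         k_neighbors = k_neighbors, n_perm = n_perm, seed = seed,
         alternative = alternative),
    class = "morans_i_result"
  )
}

#' @export
print.morans_i_result <- function(x, ...) {
  cat("<morans_i_result> I = ", format(x$i, digits = 4),
      " (E[I] = ", format(x$expectation, digits = 3), ")\n", sep = "")
  cat("  permutation p = ", format.pval(x$p), " (", x$alternative, ", k = ",
      x$k_neighbors, ", ", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

# row-standardized k-nearest-neighbour weight matrix (ties broken by index)
knn_weights <- function(x, y, k) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    W[i, nb] <- 1 / k
  }
  W
}

#' Map of standardized residuals over the study area
#'
#' Scatter of hunting units at their centroids, with symbol colour giving the
#' residual sign and symbol size its magnitude — the visual check that
#' positive and negative residuals are not spatially clumped.
#'
#' @param diag a `residual_diagnostics` tibble.
#' @param out_path optional file path (png/svg/pdf); when given the plot is
#'   written there.
#' @return The ggplot object, invisibly.
#' @export
residual_map <- function(diag, out_path = NULL) {
  if (nrow(diag) == 0) stop("empty diagnostics", call. = FALSE)
  dd <- diag
  dd$sign <- factor(ifelse(dd$residual_std >= 0, "positive", "negative"),
                    levels = c("negative", "positive"))
  dd$sign <- droplevels(dd$sign)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y,
                                        size = abs(.data$residual_std),
                                        colour = .data$sign)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(negative = "#2166AC",
                                            positive = "#B2182B"),
                                 drop = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  size = "|std. residual|", colour = "sign",
                  title = "Standardized residuals at unit centroids") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 5.5, dpi = 150)
  }
  invisible(p)
}

#' Abundance index against distance to the range edge, with fitted segments
#'
#' The standard presentation of a range-edge breakpoint analysis: z-scored
#' abundance against signed distance to the top predator's 85% contour edge
#' (zero line), the fitted two-segment mean, a dashed line at the estimated
#' breakpoint and dashed lines at its bootstrap confidence bounds.
#'
#' @param profile a [distance_profile()] tibble.
#' @param fit a `piecewise_fit`.
#' @param boot optional `bootstrap_result` (adds CI lines).
#' @param role `"meso"` or `"top"` — which z column to plot.
#' @param out_path optional output file path.
#' @return The ggplot object, invisibly.
#' @export
plot_breakpoint_fit <- function(profile, fit, boot = NULL,
                                role = c("meso", "top"), out_path = NULL) {
  role <- match.arg(role)
  zcol <- if (role == "meso") "z_meso" else "z_top"
  dd <- tibble::tibble(d = profile$d_km, z = profile[[zcol]])
  grid <- tibble::tibble(d = seq(min(dd$d), max(dd$d), length.out = 400))
  grid$z <- predict(fit, grid$d)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$d, y = .data$z)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey55") +
    ggplot2::geom_point(alpha = 0.6, size = 1.6) +
    ggplot2::geom_line(data = grid, colour = "black", linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = fit$breakpoint, linetype = "dashed") +
    ggplot2::labs(
      x = "distance to range edge (km)",
      y = paste0("abundance index (z), ", role, "predator"),
      subtitle = sprintf("breakpoint %.0f km, R² = %.2f",
                         fit$breakpoint, fit$r2)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(boot)) {
    p <- p + ggplot2::geom_vline(xintercept = c(boot$ci_low, boot$ci_high),
                                 linetype = "dashed", colour = "red")
  }
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}
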