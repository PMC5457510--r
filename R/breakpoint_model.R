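#' Continuous one-breakpoint piecewise linear regression
#'
#' Fits the broken-stick model
#' `E[z | d] = beta0 + beta1 * d + beta2 * max(0, d - b)`,
#' a linear spline with a single knot at the breakpoint `b`: the mean is
#' continuous at `b`, the slope is `beta1` to the left and `beta1 + beta2` to
#' the right. For a fixed `b` the coefficients are exact least squares on the
#' design `(1, d, (d - b)+)`; `b` itself is found by exhaustive search over
#' every distinct sorted `d` value and every midpoint of consecutive distinct
#' values that leaves at least `min_distinct_side` distinct `d` values on
#' each side (so the search RSS is never above that of a midpoint-only grid),
#' then refined by golden-section search within the bracketing intervals
#' around the best candidate (`refine = TRUE`, the default), which lets the
#' knot land between grid points — e.g. exactly on a kink that falls inside
#' a gap in the data. Ties in RSS are broken toward the smallest candidate
#' breakpoint.
#'
#' Candidate-wise coefficients are solved from suffix-sum sufficient
#' statistics (a 3x3 normal-equation solve per candidate), so the search is
#' O(n log n + k n) for k candidates.
#'
#' @param d signed distances to the range edge, km.
#' @param z z-scored abundance indices, same length.
#' @param min_distinct_side minimum distinct `d` values required on each side
#'   of a candidate breakpoint (default 2, the identifiability minimum).
#' @param refine logical: refine the breakpoint continuously within the
#'   intervals adjacent to the best grid candidate (default `TRUE`).
#' @return An object of class `piecewise_fit`: `breakpoint`, `coefficients`
#'   (`intercept`, `slope_left`, `slope_change`), `slope_right`, `rss`, `r2`,
#'   `n`, `d_range`, `n_candidates`, and the data (`d`, `z`).
#' @export
fit_piecewise <- function(d, z, min_distinct_side = 2, refine = TRUE) {
  if (length(d) != length(z)) stop("d and z lengths differ", call. = FALSE)
  ok <- is.finite(d) & is.finite(z)
  if (!all(ok)) stop("d and z must be finite", call. = FALSE)
  n <- length(d)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  u <- sort(unique(d))
  m <- length(u)
  if (m == 1) stop("all distance values are identical", call. = FALSE)
  if (m < 2 * min_distinct_side) {
    stop("need at least ", 2 * min_distinct_side,
         " distinct distance values", call. = FALSE)
  }
  ord <- order(d)
  ds <- d[ord]; zs <- z[ord]

  # candidates: every distinct value u[i] and every midpoint between u[i]
  # and u[i+1] that leave min_distinct_side distinct values on each side
  # (points at d == b sit on the left segment, their hinge term is zero)
  lo <- min_distinct_side
  hi <- m - min_distinct_side
  if (hi < lo) stop("no admissible breakpoint candidates", call. = FALSE)
  ii <- lo:hi
  cand <- as.vector(rbind(u[ii], (u[ii] + u[ii + 1]) / 2)) # increasing order

  # suffix sums over sorted points: the right-hand set of every candidate in
  # [u[i], u[i+1]) is every point with d >= u[i+1]
  rev_cum <- function(v) rev(cumsum(rev(v)))
  S1 <- rev_cum(rep(1, n)); Sd <- rev_cum(ds); Sdd <- rev_cum(ds^2)
  Sz <- rev_cum(zs); Sdz <- rev_cum(ds * zs)
  # index of first point with d >= u[i+1] (exact, via the multiplicity of
  # each distinct value)
  cnt <- cumsum(tabulate(match(ds, u), nbins = m))
  starts <- rep(cnt[ii] + 1L, each = 2)

  n_all <- n
  Sd_all <- Sd[1]; Sdd_all <- Sdd[1]
  Sz_all <- Sz[1]; Sdz_all <- Sdz[1]
  Szz_all <- sum(zs^2)
  zbar <- Sz_all / n
  tss <- sum((zs - zbar)^2)

  # closed-form least squares at breakpoint b via a symmetric 3x3 Cramer
  # solve on the normal equations (no per-candidate LAPACK call), given the
  # index s of the first sorted point strictly right of b; RSS through the
  # algebraic identity rss = z'z - beta' X'y (clamped at 0)
  solve_at <- function(b, s) {
    if (s > n) return(NULL)
    r1 <- S1[s]; rd <- Sd[s]; rdd <- Sdd[s]; rz <- Sz[s]; rdz <- Sdz[s]
    a11 <- n_all; a12 <- Sd_all; a22 <- Sdd_all
    a13 <- rd - b * r1
    a23 <- rdd - b * rd
    a33 <- rdd - 2 * b * rd + b^2 * r1
    y1 <- Sz_all; y2 <- Sdz_all; y3 <- rdz - b * rz
    m11 <- a22 * a33 - a23 * a23
    m12 <- a12 * a33 - a13 * a23
    m13 <- a12 * a23 - a13 * a22
    det <- a11 * m11 - a12 * m12 + a13 * m13
    mag <- abs(a11 * m11) + abs(a12 * m12) + abs(a13 * m13)
    if (!is.finite(det) || abs(det) <= 1e-12 * mag) return(NULL)
    beta1 <- (y1 * m11 - a12 * (y2 * a33 - y3 * a23) +
                a13 * (y2 * a23 - y3 * a22)) / det
    beta2 <- (a11 * (y2 * a33 - y3 * a23) - y1 * m12 +
                a13 * (a12 * y3 - a13 * y2)) / det
    beta3 <- (a11 * (a22 * y3 - a23 * y2) - a12 * (a12 * y3 - a13 * y2) +
                y1 * m13) / det
    rss <- max(0, Szz_all - (beta1 * y1 + beta2 * y2 + beta3 * y3))
    list(rss = rss, b = b, beta = c(beta1, beta2, beta3))
  }

  best <- list(rss = Inf)
  best_i <- NA_integer_
  for (j in seq_along(cand)) {
    fit <- solve_at(cand[j], starts[j])
    if (is.null(fit)) next
    if (fit$rss < best$rss - 1e-12 ||
        (abs(fit$rss - best$rss) <= 1e-12 && is.finite(best$rss) &&
           fit$b < best$b)) {
      best <- fit
      best_i <- ii[ceiling(j / 2)]
    }
  }
  if (!is.finite(best$rss)) stop("piecewise fit failed: singular design for ",
                                 "every candidate breakpoint", call. = FALSE)

  if (refine) {
    # continuous golden-section refinement within the distinct-value
    # intervals adjacent to the best grid candidate; the right-hand point
    # set is constant within each interval, so rss(b) is smooth there
    tol <- 1e-10 * (u[m] - u[1])
    for (i in intersect(best_i + (-1:1), lo:hi)) {
      opt <- golden_min(function(b) {
        fit <- solve_at(b, cnt[i] + 1L)
        if (is.null(fit)) Inf else fit$rss
      }, u[i], u[i + 1], tol)
      if (opt$objective < best$rss - 1e-12) {
        fit <- solve_at(opt$minimum, cnt[i] + 1L)
        if (!is.null(fit)) best <- fit
      }
    }
  }

  beta <- best$beta
  structure(
    list(
      breakpoint = best$b,
      coefficients = c(intercept = beta[1], slope_left = beta[2],
                       slope_change = beta[3]),
      slope_right = beta[2] + beta[3],
      rss = best$rss,
      r2 = if (tss > 0) 1 - best$rss / tss else NA_real_,
      n = n,
      d_range = range(d),
      n_candidates = length(cand),
      d = d,
      z = z
    ),
    class = "piecewise_fit"
  )
}

# golden-section minimization; translation- and scale-covariant (unlike
# Brent's method, whose convergence test mixes in absolute |x| terms)
golden_min <- function(f, a, b, tol) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  xm <- (a + b) / 2
  list(minimum = xm, objective = f(xm))
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("<piecewise_fit> n = ", x$n, "\n", sep = "")
  cat("  breakpoint:  ", format(x$breakpoint, digits = 5), " km\n", sep = "")
  cat("  slope left:  ", format(x$coefficients[["slope_left"]], digits = 4),
      " z/km   slope right: ", format(x$slope_right, digits = 4),
      " z/km\n", sep = "")
  cat("  R^2: ", format(round(x$r2, 4)), "   RSS: ",
      format(x$rss, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict from a piecewise fit
#'
#' @param object a `piecewise_fit`.
#' @param newdata numeric vector of distances, km; defaults to the fitted
#'   distances.
#' @param ... unused.
#' @return Fitted mean values.
#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$d else newdata
  co <- object$coefficients
  co[["intercept"]] + co[["slope_left"]] * d +
    co[["slope_change"]] * pmax(d - object$breakpoint, 0)
}

#' Bootstrap confidence interval and slope-change test for the breakpoint
#'
#' Case-resampling bootstrap: `(d, z)` pairs are resampled with replacement
#' and the piecewise model refit; the 2.5% and 97.5% percentiles of the
#' bootstrap breakpoints give the confidence interval, and the slope-change
#' p-value is the two-sided bootstrap sign probability
#' `2 * min(frac(beta2* <= 0), frac(beta2* >= 0))`. Replicates in which the
#' resample cannot support a breakpoint (fewer than the required distinct
#' distances on one side) are redrawn and counted; more than 20% redraws
#' triggers a warning.
#'
#' @param d,z as in [fit_piecewise()].
#' @param n_boot number of bootstrap replicates; default 1000.
#' @param seed optional RNG seed for reproducibility.
#' @param conf percentile pair; default `c(0.025, 0.975)`.
#' @param min_distinct_side passed to [fit_piecewise()].
#' @return An object of class `bootstrap_result`: `ci_low`, `ci_high`,
#'   `p_slope_change`, `n_boot`, `seed`, `n_redraws`, and the bootstrap
#'   draws `b_star`, `slope_change_star`.
#' @export
bootstrap_breakpoint <- function(d, z, n_boot = 1000, seed = NULL,
                                 conf = c(0.025, 0.975),
                                 min_distinct_side = 2) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  fit_piecewise(d, z, min_distinct_side) # contract: base fit must succeed
  if (!is.null(seed)) set.seed(seed)
  n <- length(d)
  b_star <- numeric(n_boot)
  b2_star <- numeric(n_boot)
  redraws <- 0L
  max_redraws <- 50L * n_boot
  for (r in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(fit_piecewise(d[idx], z[idx], min_distinct_side),
                    error = function(e) NULL)
      if (!is.null(f)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap cannot find valid resamples; data too degenerate",
             call. = FALSE)
      }
    }
    b_star[r] <- f$breakpoint
    b2_star[r] <- f$coefficients[["slope_change"]]
  }
  if (redraws > 0.2 * n_boot) {
    warning(redraws, " bootstrap resamples redrawn (over 20% of n_boot); ",
            "breakpoint support is fragile")
  }
  ci <- stats::quantile(b_star, conf, names = FALSE, type = 7)
  p <- 2 * min(mean(b2_star <= 0), mean(b2_star >= 0))
  structure(
    list(ci_low = ci[1], ci_high = ci[2],
         p_slope_change = min(1, p),
         n_boot = n_boot, seed = seed, n_redraws = redraws,
         b_star = b_star, slope_change_star = b2_star),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> n_boot = ", x$n_boot, "\n", sep = "")
  cat("  breakpoint 95% CI: [", format(x$ci_low, digits = 5), ", ",
      format(x$ci_high, digits = 5), "] km\n", sep = "")
  cat("  p (slope change):  ", format.pval(x$p_slope_change), "\n", sep = "")
  invisible(x)
}

#' Decide whether the data show a clear breakpoint
#'
#' A breakpoint is flagged as unclear when the bootstrap confidence interval
#' spans more than half the observed distance range, or when the slope-change
#' p-value exceeds 0.05 — either way the kink location is not identified by
#' the data.
#'
#' @param fit a `piecewise_fit`.
#' @param boot a `bootstrap_result` for the same data.
#' @param d_range observed distance range; defaults to the fit's.
#' @return List with `no_clear_breakpoint` (logical) and `reason`
#'   (`"ci_span"`, `"p_slope_change"`, or `""`).
#' @export
detect_no_breakpoint <- function(fit, boot, d_range = fit$d_range) {
  span <- boot$ci_high - boot$ci_low
  if (span > 0.5 * diff(d_range)) {
    list(no_clear_breakpoint = TRUE, reason = "ci_span")
  } else if (boot$p_slope_change > 0.05) {
    list(no_clear_breakpoint = TRUE, reason = "p_slope_change")
  } else {
    list(no_clear_breakpoint = FALSE, reason = "")
  }
}

#' Asymptotic t-test on the slope change at the fitted breakpoint
#'
#' Fallback to the bootstrap sign test: refits the linear model at the fixed
#' estimated breakpoint and returns the usual t-test on the hinge
#' coefficient. The test conditions on the estimated knot, so it is
#' anti-conservative when the breakpoint is weakly identified.
#'
#' @param fit a `piecewise_fit`.
#' @return List with `t`, `df`, `p`.
#' @export
slope_change_ttest <- function(fit) {
  h <- pmax(fit$d - fit$breakpoint, 0)
  sm <- summary(stats::lm(fit$z ~ fit$d + h))
  co <- sm$coefficients["h", ]
  list(t = unname(co["t value"]), df = sm$df[2],
       p = unname(co["Pr(>|t|)"]))
}
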