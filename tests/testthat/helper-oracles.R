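# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops, lm() fits, closed forms.

# two-pass mean/sd standardization
oracle_zscore <- function(x, ddof = 1) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - ddof))
  (x - m) / s
}

# naive weighted Gaussian-mixture density at a single location
oracle_mixture_density <- function(cx, cy, pts, w, H) {
  Hi <- solve(H)
  total <- 0
  for (k in seq_len(nrow(pts))) {
    u <- c(cx - pts[k, 1], cy - pts[k, 2])
    q <- drop(t(u) %*% Hi %*% u)
    total <- total + w[k] * exp(-0.5 * q) / (2 * pi * sqrt(det(H)))
  }
  total / sum(w)
}

# sort-and-accumulate volume threshold
oracle_volume_threshold <- function(values, cell_size, level_p) {
  mass <- as.vector(values) * cell_size^2
  v <- as.vector(values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  v[ord][which(cum >= level_p * sum(mass))[1]]
}

# brute-force distance from one point to every segment of a closed ring
oracle_segment_distance <- function(px, py, ring) {
  best <- Inf
  for (i in seq_len(nrow(ring) - 1)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    ab <- b - a
    t <- sum((c(px, py) - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    p <- a + t * ab
    best <- min(best, sqrt(sum((c(px, py) - p)^2)))
  }
  best
}

# scalar ray-casting point-in-polygon (even-odd), independent loop form
oracle_ray_cast <- function(px, py, ring) {
  inside <- FALSE
  n <- nrow(ring)
  j <- n - 1
  for (i in seq_len(n - 1)) {
    if ((ring[i, 2] > py) != (ring[j, 2] > py)) {
      xint <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) /
        (ring[j, 2] - ring[i, 2]) + ring[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# exhaustive piecewise search over midpoints of consecutive distinct d,
# each candidate fitted with lm() — the reference the fast path must beat
oracle_piecewise_midpoints <- function(d, z) {
  u <- sort(unique(d))
  m <- length(u)
  cand <- (u[2:(m - 2)] + u[3:(m - 1)]) / 2
  best <- list(rss = Inf, b = NA)
  for (b in cand) {
    h <- pmax(d - b, 0)
    fit <- stats::lm(z ~ d + h)
    rss <- sum(stats::resid(fit)^2)
    if (rss < best$rss) best <- list(rss = rss, b = b, beta = stats::coef(fit))
  }
  best
}

# dense-matrix textbook Moran's I for a given weight matrix
oracle_morans_i <- function(values, W) {
  n <- length(values)
  vc <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * vc[i] * vc[j]
  }
  (n / sum(W)) * num / sum(vc^2)
}

# regular n-gon approximation of a circle, closed ring
circle_ring <- function(cx, cy, r, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# small three-unit bounty table fixture
make_bounty_csv <- function(path, counts = cbind(wolf = c(10, 0, 3),
                                                 coyote = c(2, 5, 0))) {
  df <- data.frame(unit_id = c("a", "b", "c"),
                   x = c(0, 10, 20), y = c(0, 5, 10),
                   wolf = counts[, 1], coyote = counts[, 2], years = 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

default_roles <- c(wolf = "top", coyote = "meso")
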