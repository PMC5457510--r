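# a small surface built from explicit cell values, for threshold tests
surface_from_values <- function(values, cell_size = 1) {
  structure(
    list(x = (seq_len(nrow(values)) - 1) * cell_size,
         y = (seq_len(ncol(values)) - 1) * cell_size,
         values = values, cell_size = cell_size,
         bandwidth = structure(list(matrix = diag(2), method_tag = "fixed"),
                               class = "bandwidth"),
         total_weight = 1, n_points = 1),
    class = "density_surface"
  )
}

gaussian_surface <- function(h = 5, cell_size = 0.5) {
  bw <- structure(list(matrix = diag(h^2, 2), method_tag = "fixed"),
                  class = "bandwidth")
  estimate_density(matrix(c(0, 0), ncol = 2), weights = 1, bandwidth = bw,
                   cell_size = cell_size)
}

test_that("volume threshold matches the sort-and-accumulate oracle", {
  # cell masses 0.5, 0.3, 0.2: cumulative 0.8 < 0.85, so the third cell is
  # needed and the threshold equals its density
  vals <- matrix(c(0.5, 0.3, 0.2), nrow = 3)
  surf <- surface_from_values(vals, cell_size = 1)
  thr <- volume_threshold(surf, 0.85)
  expect_equal(thr, 0.2)
  expect_equal(thr, oracle_volume_threshold(vals, 1, 0.85))

  set.seed(9)
  g <- gaussian_surface()
  for (p in c(0.5, 0.85, 0.95)) {
    expect_equal(volume_threshold(g, p),
                 oracle_volume_threshold(g$values, g$cell_size, p))
  }
  # level -> 1 limit: every positive cell included (bounded-range surface)
  thr1 <- volume_threshold(surf, 1 - 1e-9)
  expect_lte(thr1, min(vals[vals > 0]) + 1e-12)
  expect_error(volume_threshold(g, 1.2), "level_p")
})

test_that("a uniform surface ties every cell and warns", {
  vals <- matrix(0.25, 2, 2)
  surf <- surface_from_values(vals, cell_size = 1)
  expect_warning(thr <- volume_threshold(surf, 0.85), "uniform")
  edge <- suppressWarnings(extract_isopleth(surf, threshold = thr))
  expect_equal(edge$contained_mass, 1.0)
})

test_that("isopleth of an isotropic Gaussian is the analytic circle", {
  h <- 5; cs <- 0.5
  g <- gaussian_surface(h, cs)
  edge <- extract_isopleth(g, level_p = 0.85)
  expect_length(edge$rings, 1)
  r_expected <- h * sqrt(-2 * log(1 - 0.85))
  radii <- sqrt(rowSums(edge$rings[[1]]^2))
  expect_lt(max(abs(radii - r_expected)), cs)
  # realized mass within the isopleth accounting tolerance
  expect_gte(edge$contained_mass, 0.83)
  expect_lte(edge$contained_mass, 0.87)
  # interpolated ring area brackets the analytic disc area
  expect_equal(edge$area_km2, pi * r_expected^2, tolerance = 0.05)
})

test_that("nesting: the 95% region contains the 85% region", {
  g <- gaussian_surface()
  e85 <- extract_isopleth(g, 0.85)
  e95 <- extract_isopleth(g, 0.95)
  expect_lt(e95$threshold, e85$threshold)
  for (ring in e85$rings) {
    d <- signed_distance(ring[, 1], ring[, 2], e95)
    expect_true(all(d > 0))
  }
})

test_that("two separated modes give two rings whose masses sum to the
           contained mass", {
  bw <- structure(list(matrix = diag(4, 2), method_tag = "fixed"),
                  class = "bandwidth")
  pts <- matrix(c(0, 0, 40, 0), ncol = 2, byrow = TRUE)
  surf <- estimate_density(pts, weights = c(1, 1), bandwidth = bw,
                           cell_size = 0.5)
  edge <- extract_isopleth(surf, 0.85)
  expect_length(edge$rings, 2)
  expect_false(any(edge$hole))
  expect_equal(sum(edge$ring_mass), edge$contained_mass, tolerance = 1e-9)
  # per-ring mass by direct cell summation: equal modes split evenly
  expect_equal(edge$ring_mass[1], edge$ring_mass[2], tolerance = 1e-6)
})

test_that("one super-threshold cell yields one small closed ring", {
  vals <- matrix(1e-6, 9, 9)
  vals[5, 5] <- 1
  surf <- surface_from_values(vals / sum(vals), cell_size = 1)
  edge <- extract_isopleth(surf, threshold = 0.5 / sum(1e-6 * 80 + 1))
  expect_length(edge$rings, 1)
  ring <- edge$rings[[1]]
  expect_identical(ring[1, ], ring[nrow(ring), ])
  # surrounds the hot cell at (4, 4) in grid coordinates
  expect_true(oracle_ray_cast(4, 4, ring))
  expect_lt(ring_span <- max(dist(ring)), 3)
})

test_that("signed distance: circle geometry, boundary point, and oracles", {
  ring <- circle_ring(0, 0, 10)
  edge <- structure(list(level_p = 0.85, threshold = 1, rings = list(ring),
                         ring_mass = 1, contained_mass = 0.85,
                         area_km2 = pi * 100, hole = FALSE, cell_size = 1),
                    class = "range_edge")
  d <- signed_distance(c(0, 0, ring[1, 1]), c(15, 4, ring[1, 2]), edge)
  expect_equal(d[1], -5, tolerance = 1e-3)
  expect_equal(d[2], 6, tolerance = 1e-3)
  expect_equal(d[3], 0, tolerance = 1e-12)

  # 50 random points against brute-force segment scan + ray casting
  set.seed(71)
  poly <- cbind(c(0, 8, 12, 6, -2, 0), c(0, -3, 5, 11, 7, 0))
  pedge <- structure(list(level_p = 0.85, threshold = 1, rings = list(poly),
                          ring_mass = 1, contained_mass = 0.85,
                          area_km2 = 1, hole = FALSE, cell_size = 1),
                     class = "range_edge")
  px <- runif(50, -6, 18); py <- runif(50, -8, 16)
  d <- signed_distance(px, py, pedge)
  for (i in seq_along(px)) {
    expect_equal(abs(d[i]), oracle_segment_distance(px[i], py[i], poly),
                 tolerance = 1e-9)
    expect_identical(d[i] > 0, oracle_ray_cast(px[i], py[i], poly))
  }
})

test_that("distances are translation-equivariant and sign matches
           membership", {
  set.seed(72)
  poly <- circle_ring(3, -2, 7, n = 100)
  edge <- structure(list(level_p = 0.85, threshold = 1, rings = list(poly),
                         ring_mass = 1, contained_mass = 0.85,
                         area_km2 = 1, hole = FALSE, cell_size = 1),
                    class = "range_edge")
  px <- runif(30, -10, 16); py <- runif(30, -15, 11)
  d0 <- signed_distance(px, py, edge)
  shift <- c(123.4, -56.7)
  edge2 <- edge
  edge2$rings[[1]] <- sweep(poly, 2, -shift)
  d1 <- signed_distance(px + shift[1], py + shift[2], edge2)
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_identical(d0 > 0,
                   vapply(seq_along(px), function(i) {
                     oracle_ray_cast(px[i], py[i], poly)
                   }, logical(1)))
})

test_that("interior holes count as outside", {
  outer <- circle_ring(0, 0, 10, n = 200)
  hole <- circle_ring(0, 0, 3, n = 100)
  edge <- structure(list(level_p = 0.85, threshold = 1,
                         rings = list(outer, hole), ring_mass = c(1, 0),
                         contained_mass = 0.85, area_km2 = 1,
                         hole = c(FALSE, TRUE), cell_size = 1),
                    class = "range_edge")
  d <- signed_distance(c(0, 5, 12), c(0, 0, 0), edge)
  expect_lt(d[1], 0)          # inside the hole: outside the range
  expect_equal(d[1], -3, tolerance = 1e-3)
  expect_equal(d[2], 2, tolerance = 1e-3)  # between hole and outer edge
  expect_lt(d[3], 0)
})

test_that("range edge exports valid GeoJSON", {
  g <- gaussian_surface()
  edge <- extract_isopleth(g, 0.85)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_edge_geojson(edge, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  geom <- gj$features[[1]]$geometry
  expect_identical(geom$type, "MultiPolygon")
  expect_length(geom$coordinates, length(edge$rings))
  expect_equal(gj$features[[1]]$properties$level_p, 0.85)
})
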