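test_that("silverman bandwidth is scale-equivariant and matches the
           closed-form weighted rule of thumb", {
  set.seed(21)
  pts <- matrix(rnorm(400), ncol = 2)
  w <- runif(200, 0.5, 2)
  bw <- select_bandwidth(pts, w, method = "silverman")
  bw2 <- select_bandwidth(2 * pts, w, method = "silverman")
  expect_equal(bw2$matrix, 4 * bw$matrix, tolerance = 1e-12)

  # closed-form oracle: weighted marginal sds with reliability-weight
  # correction, scaled by n_eff^(-1/6) per axis
  sw <- sum(w)
  n_eff <- sw^2 / sum(w^2)
  s2 <- vapply(1:2, function(j) {
    m <- sum(w * pts[, j]) / sw
    sum(w * (pts[, j] - m)^2) / (sw - sum(w^2) / sw)
  }, 0)
  H_oracle <- diag(s2, 2) * n_eff^(-1 / 3)
  expect_equal(bw$matrix, H_oracle, tolerance = 1e-9)
})

test_that("bandwidth selection validates input and records its method", {
  pts <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  expect_error(select_bandwidth(pts[c(1, 1, 1), ]), "distinct")
  expect_error(select_bandwidth(pts, rep(0, 4)), "weight")
  expect_identical(select_bandwidth(pts, method = "scv")$method_tag, "scv")
  expect_identical(select_bandwidth(pts, method = "fixed",
                                    fixed_h = 2)$method_tag, "fixed")
  ev <- eigen(select_bandwidth(pts, method = "scv")$matrix,
              only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("a single kernel reproduces the bivariate normal peak and mass", {
  bw <- select_bandwidth(matrix(c(0, 0, 5, 5, -5, 5), ncol = 2, byrow = TRUE),
                         method = "fixed", fixed_h = 2)
  surf <- estimate_density(matrix(c(0, 0), ncol = 2), weights = 1,
                           bandwidth = bw, cell_size = 0.25)
  h <- 2
  expect_equal(max(surf$values), 1 / (2 * pi * h^2), tolerance = 1e-3)
  m <- surface_mass(surf)
  expect_gte(m, 0.98)
  expect_lte(m, 1.0 + 1e-9)
})

test_that("mirrored point patterns give mirrored surfaces", {
  bw <- select_bandwidth(matrix(c(-3, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE),
                         method = "fixed", fixed_h = 1.5)
  pts <- matrix(c(-3, 0, 3, 0), ncol = 2, byrow = TRUE)
  surf <- estimate_density(pts, weights = c(1, 1), bandwidth = bw,
                           cell_size = 0.5)
  v <- surf$values
  expect_equal(v, v[nrow(v):1, ], tolerance = 1e-12)
})

test_that("the grid equals a naive Gaussian-mixture oracle cell by cell", {
  set.seed(33)
  pts <- matrix(runif(20, 0, 10), ncol = 2)
  w <- runif(10, 0.2, 3)
  H <- matrix(c(2.5, 0.6, 0.6, 1.8), 2)
  bw <- structure(list(matrix = H, method_tag = "fixed"), class = "bandwidth")
  surf <- estimate_density(pts, w, bw, cell_size = 1.2)
  # spot-check a 20x20 block of cells against the naive double loop
  ix <- round(seq(1, length(surf$x), length.out = 20))
  iy <- round(seq(1, length(surf$y), length.out = 20))
  for (i in ix) {
    for (j in iy) {
      expect_equal(surf$values[i, j],
                   oracle_mixture_density(surf$x[i], surf$y[j], pts, w, H),
                   tolerance = 1e-10)
    }
  }
})

test_that("surface invariants: mass, monotone smoothing, weight scaling,
           permutation order", {
  set.seed(44)
  pts <- matrix(rnorm(30, sd = 5), ncol = 2)
  w <- rpois(15, 4) + 1
  bw <- select_bandwidth(pts, w, method = "silverman")
  surf <- estimate_density(pts, w, bw, cell_size = 1)
  expect_gte(surface_mass(surf), 0.98)
  expect_lte(surface_mass(surf), 1 + 1e-9)

  bw4 <- structure(list(matrix = 4 * bw$matrix, method_tag = "fixed"),
                   class = "bandwidth")
  surf4 <- estimate_density(pts, w, bw4, cell_size = 1)
  expect_lte(max(surf4$values), max(surf$values))

  surf_2w <- estimate_density(pts, 2 * w, bw, cell_size = 1)
  expect_equal(surf_2w$values, surf$values, tolerance = 1e-12)

  perm <- sample(nrow(pts))
  surf_p <- estimate_density(pts[perm, ], w[perm], bw, cell_size = 1)
  expect_identical(dim(surf_p$values), dim(surf$values))
  expect_equal(surf_p$values, surf$values, tolerance = 1e-14)
})

test_that("insufficient padding is rejected with advice", {
  pts <- matrix(c(0, 0, 4, 0, 0, 4), ncol = 2, byrow = TRUE)
  bw <- select_bandwidth(pts, method = "fixed", fixed_h = 5)
  expect_error(estimate_density(pts, bandwidth = bw, cell_size = 1,
                                padding = 2), "padding")
})

test_that("surface CSV serialization round-trips values and registration", {
  set.seed(5)
  pts <- matrix(runif(12, 0, 8), ncol = 2)
  bw <- select_bandwidth(pts, method = "fixed", fixed_h = 2)
  surf <- estimate_density(pts, bandwidth = bw, cell_size = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(surf, path)
  hdr <- readLines(path, n = 5)
  expect_match(hdr[1], "^ncols,")
  expect_match(hdr[3], "^xll_center,")
  back <- read_surface_csv(path)
  expect_equal(back$values, surf$values, tolerance = 1e-15)
  expect_equal(back$x, surf$x, tolerance = 1e-9)
  expect_equal(back$cell_size, surf$cell_size)
})
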