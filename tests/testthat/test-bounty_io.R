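test_that("CSV bounty tables parse, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_bounty_csv(path)
  ds <- read_bounty_table(path, species_roles = default_roles)
  expect_s3_class(ds, "bounty_dataset")
  expect_equal(nrow(ds$units), 3)
  expect_identical(ds$units$unit_id, c("a", "b", "c"))
  expect_type(ds$units$wolf, "integer")
  expect_equal(species_for_role(ds, "top"), "wolf")

  out <- withr::local_tempfile(fileext = ".csv")
  write_bounty_csv(ds, out)
  ds2 <- read_bounty_table(out, species_roles = default_roles)
  expect_identical(ds2$units$wolf, ds$units$wolf)
  expect_identical(ds2$units$coyote, ds$units$coyote)
  expect_equal(ds2$units$x, ds$units$x, tolerance = 1e-9)
  expect_equal(ds2$units$y, ds$units$y, tolerance = 1e-9)
})

test_that("schema and validation errors name the offending column or unit", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_bounty_csv(path)

  df_neg <- df; df_neg$wolf[2] <- -1
  utils::write.csv(df_neg, path, row.names = FALSE)
  expect_error(read_bounty_table(path, species_roles = default_roles), "b")

  df_dup <- df; df_dup$unit_id[2] <- "a"
  utils::write.csv(df_dup, path, row.names = FALSE)
  expect_error(read_bounty_table(path, species_roles = default_roles),
               "duplicate")

  utils::write.csv(df[, setdiff(names(df), "x")], path, row.names = FALSE)
  expect_error(read_bounty_table(path, species_roles = default_roles), "x")

  expect_error(
    bounty_dataset(df[, names(df) != "years"], default_roles, years = 0),
    "years"
  )
})

test_that("GeoJSON polygons are read and centroids computed when absent", {
  square <- list(list(list(0, 0), list(1, 0), list(1, 1), list(0, 1),
                      list(0, 0)))
  gj <- list(
    type = "FeatureCollection",
    features = lapply(1:3, function(i) {
      list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(square[[1]], function(p) {
                          list(p[[1]] + 2 * (i - 1), p[[2]])
                        }))),
        properties = list(unit_id = paste0("u", i), wolf = i, coyote = 5 - i,
                          years = 10)
      )
    })
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  ds <- read_bounty_table(path, species_roles = default_roles)
  # area-weighted centroid of the unit square is its middle
  expect_equal(ds$units$x, c(0.5, 2.5, 4.5), tolerance = 1e-9)
  expect_equal(ds$units$y, rep(0.5, 3), tolerance = 1e-9)
  expect_length(ds$polygons, 3)
})

test_that("rates are counts per collection year", {
  units <- tibble::tibble(unit_id = c("a", "b", "c"), x = 0:2, y = 0:2,
                          wolf = c(30L, 0L, 10L), coyote = c(10L, 20L, 40L),
                          years = c(30, 30, 30))
  ds <- bounty_dataset(units, default_roles)
  r <- standardize_rate(ds)
  expect_equal(r$rate[r$species == "wolf"], c(1, 0, 10 / 30))
  # elementwise-division oracle on a 10-year table
  units$years <- 10
  r10 <- standardize_rate(bounty_dataset(units, default_roles))
  expect_equal(r10$rate[r10$species == "coyote"], c(10, 20, 40) / 10)
  expect_true(all(is.na(r10$z)))
})

test_that("per-species years are honoured when datasets are pooled", {
  units <- tibble::tibble(unit_id = c("a", "b", "c"), x = 0:2, y = 0:2,
                          wolf = c(9L, 18L, 27L), coyote = c(6L, 12L, 18L))
  ds <- bounty_dataset(units, default_roles, years = c(wolf = 9, coyote = 6))
  r <- standardize_rate(ds)
  expect_equal(r$rate[r$species == "wolf"], c(1, 2, 3))
  expect_equal(r$rate[r$species == "coyote"], c(1, 2, 3))
})

test_that("zscore matches its contract and an independent oracle", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  # affine invariance
  x <- c(4.2, -1, 7, 0.5, 3)
  expect_equal(zscore(5 * x + 7), zscore(x), tolerance = 1e-12)
  # seeded draws against the two-pass oracle
  set.seed(11)
  u <- runif(100)
  expect_equal(zscore(u, ddof = 1), oracle_zscore(u, 1), tolerance = 1e-12)
  expect_equal(zscore(u, ddof = 0), oracle_zscore(u, 0), tolerance = 1e-12)
  # post-conditions
  for (ddof in c(0, 1)) {
    z <- zscore(u, ddof)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sqrt(sum((z - mean(z))^2) / (length(z) - ddof)) - 1), 1e-10)
  }
  # idempotence
  expect_equal(zscore(zscore(u)), zscore(u), tolerance = 1e-10)
  # contract violations
  expect_error(zscore(rep(2, 5)), "constant")
  expect_error(zscore(1), "at least 2")
})

test_that("double-zero exclusion removes exactly the jointly empty units", {
  units <- tibble::tibble(unit_id = paste0("u", 1:4), x = 1:4, y = 1:4,
                          wolf = c(0L, 0L, 3L, 2L),
                          coyote = c(0L, 5L, 0L, 2L), years = 1)
  ds <- bounty_dataset(units, default_roles)
  kept <- suppressMessages(exclude_double_zero(ds))
  expect_identical(kept$units$unit_id, c("u2", "u3", "u4"))
  expect_identical(attr(kept, "removed_units"), "u1")
  # partition: |kept| + |removed| = |input|, survivors unaltered
  expect_equal(nrow(kept$units) + length(attr(kept, "removed_units")),
               nrow(ds$units))
  expect_identical(kept$units, ds$units[2:4, ])

  # identity when nothing to remove
  ds_ok <- bounty_dataset(units[2:4, ], default_roles)
  expect_identical(exclude_double_zero(ds_ok)$units, ds_ok$units)

  # boundary: everything removed
  units0 <- units; units0$wolf <- 0L; units0$coyote <- 0L
  expect_warning(
    suppressMessages(exclude_double_zero(bounty_dataset(units0,
                                                        default_roles))),
    "all units removed"
  )
})
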