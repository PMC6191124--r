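# Landscape / nest / literature IO, availability and patch assignment.

test_that("GeoJSON round trip preserves the landscape", {
  land <- two_patch_landscape()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(land, path)
  back <- load_landscape(path)
  expect_s3_class(back, "landscape")
  expect_equal(nrow(back$patches), 2)
  expect_equal(back$patches$patch_id, land$patches$patch_id)
  expect_equal(back$patches$forest_type, land$patches$forest_type)
  expect_equal(back$patches$area_ha, land$patches$area_ha)
  expect_equal(back$patches$elevation_m, land$patches$elevation_m)
  expect_equal(back$study_area_km2, land$study_area_km2)
})

test_that("area is computed from geometry in hectares", {
  # 100 m x 100 m square = 1 ha
  land <- make_rect_landscape(data.frame(xmin = 0, ymin = 0, xmax = 100,
                                         ymax = 100, forest_type = 1,
                                         elevation_m = 50))
  expect_equal(land$patches$area_ha, 1.0)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_landscape(land, path)
  expect_equal(load_landscape(path)$patches$area_ha, 1.0)
})

test_that("missing attributes and bad geometry are format errors", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(patch_id = "A", elevation_m = 10),  # no forest_type
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(1000, 0),
                                            list(1000, 1000), list(0, 0))))
  )))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  expect_error(load_landscape(path), "forest_type")

  gj$features[[1]]$properties$forest_type <- 1
  gj$features[[1]]$geometry$coordinates <-
    list(list(list(0, 0), list(1000, 1000), list(0, 0)))  # degenerate
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  expect_error(load_landscape(path), "polygon|area")
  expect_error(load_landscape(withr::local_tempfile()), "not found")
})

test_that("declared areas inconsistent with geometry are rejected", {
  land <- two_patch_landscape()
  path <- withr::local_tempfile(fileext = ".geojson")
  land$patches$area_ha[1] <- land$patches$area_ha[1] * 1.05
  write_landscape(land, path)
  expect_error(load_landscape(path), "disagrees")
})

test_that("availability proportions are forest-area percentages", {
  same <- two_patch_landscape(types = c(3L, 3L))
  expect_equal(availability_proportions(same), c(`3` = 100))

  ab <- make_rect_landscape(data.frame(
    xmin = c(0, 0), ymin = c(0, 1000), xmax = c(2100, 7900), ymax = c(100, 1100),
    forest_type = c(1L, 2L), elevation_m = 100))
  # 21.0 ha and 79.0 ha
  expect_equal(unname(availability_proportions(ab)), c(21, 79))
  expect_error(availability_proportions(landscape(
    two_patch_landscape()$patches[0, ], 1)), "no patches")
})

test_that("availability is permutation-invariant and split-invariant", {
  spec <- data.frame(xmin = c(0, 1000, 3000), ymin = 0,
                     xmax = c(1000, 3000, 3500), ymax = 1000,
                     forest_type = c(1L, 2L, 1L), elevation_m = 10)
  a1 <- availability_proportions(make_rect_landscape(spec))
  a2 <- availability_proportions(make_rect_landscape(spec[c(3, 1, 2), ]))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(sum(a1), 100, tolerance = 1e-9)

  # split the first patch in two equal halves of the same type
  split_spec <- rbind(
    data.frame(xmin = c(0, 500), ymin = 0, xmax = c(500, 1000), ymax = 1000,
               forest_type = 1L, elevation_m = 10),
    spec[2:3, ])
  expect_equal(availability_proportions(make_rect_landscape(split_spec)), a1,
               tolerance = 1e-9)
})

test_that("the bundled availability column behaves like a rounded percentage table", {
  use <- case_study_forest_use()
  expect_equal(nrow(use), 12)
  # printed percentages sum to 100 up to rounding of 12 entries
  expect_lt(abs(sum(use$forest_area_pct) - 100), 0.6)
  expect_lt(abs(sum(use$sparrowhawk_pct) - 100), 0.6)
  expect_lt(abs(sum(use$buzzard_pct) - 100), 0.6)
  expect_lt(abs(sum(use$goshawk_pct) - 100), 0.6)
})

test_that("nests are assigned to their containing patches", {
  land <- two_patch_landscape()
  nests <- data.frame(species = "goshawk", territory_id = c("T1", "T2", "T3"),
                      nest_id = c("N1", "N2", "N3"),
                      x = c(500, 1500, 5000), y = c(500, 500, 5000),
                      stringsAsFactors = FALSE)
  nests$years <- I(list(2004L, 2004L, 2004L))
  out <- suppressMessages(assign_nests_to_patches(nests, land))
  expect_equal(out$patch_id[1:2], c("P001", "P002"))
  expect_equal(out$forest_type[1:2], c(1L, 2L))
  expect_true(out$unassigned[3])
  expect_true(is.na(out$patch_id[3]))
})

test_that("assignment agrees with an exhaustive point-in-polygon oracle", {
  set.seed(71)
  lc <- landscape_config(extent_m = c(4000, 4000), cell_size_m = 500, seed = 9)
  land <- generate_landscape(lc)
  nests <- data.frame(species = "sparrowhawk",
                      territory_id = sprintf("T%02d", 1:50),
                      nest_id = sprintf("N%02d", 1:50),
                      x = runif(50, -200, 4200), y = runif(50, -200, 4200),
                      stringsAsFactors = FALSE)
  nests$years <- I(as.list(rep(2006L, 50)))
  out <- suppressMessages(assign_nests_to_patches(nests, land))
  for (i in 1:50) {
    hits <- which(vapply(land$patches$geometry, function(g)
      oracle_point_in_polygon(nests$x[i], nests$y[i], g), logical(1)))
    if (length(hits) == 0) {
      expect_true(out$unassigned[i])
    } else {
      expect_true(out$patch_id[i] %in% land$patches$patch_id[hits])
    }
  }
})

test_that("nest CSV round trip preserves records and years", {
  nests <- data.frame(species = "buzzard", territory_id = c("T1", "T2"),
                      nest_id = c("T1N1", "T2N1"),
                      x = c(10.5, 20.25), y = c(30, 40),
                      stringsAsFactors = FALSE)
  nests$years <- I(list(c(2004L, 2006L), 2005L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_nests(nests, path)
  back <- load_nests(path)
  expect_equal(back$nest_id, nests$nest_id)
  expect_equal(back$x, nests$x)
  expect_equal(back$years, unclass(nests$years), ignore_attr = TRUE)
})

test_that("literature table loading validates its columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  lit <- generate_literature_nnds("goshawk", 5, c(1000, 9000), seed = 2)
  utils::write.csv(lit, path, row.names = FALSE)
  expect_equal(load_literature(path)$mean_nnd_m, lit$mean_nnd_m)
  utils::write.csv(lit[, 1:3], path, row.names = FALSE)
  expect_error(load_literature(path), "mean_nnd_m")
})
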