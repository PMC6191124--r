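# Nearest-neighbour distances, territory centroids, the habitat-constrained
# null model and the frequency histogram.

test_that("nearest-neighbour distances match hand-worked cases", {
  two <- cbind(x = c(0, 100), y = c(0, 0))
  r <- nearest_neighbour_distances(two)
  expect_equal(unname(r$per_point_nnd_m), c(100, 100))
  expect_equal(r$mean_m, 100)
  expect_equal(r$se_m, 0)

  three <- cbind(x = c(0, 3, 7), y = c(0, 0, 0))
  expect_equal(unname(nearest_neighbour_distances(three)$per_point_nnd_m),
               c(3, 3, 4))
})

test_that("NND contract errors: too few points, duplicates", {
  expect_error(nearest_neighbour_distances(cbind(1, 1)), "at least 2")
  expect_error(nearest_neighbour_distances(cbind(c(1, 1), c(2, 2))),
               "duplicate")
})

test_that("NNDs agree with the all-pairs O(n^2) oracle", {
  set.seed(40)
  pts <- cbind(x = runif(200, 0, 10000), y = runif(200, 0, 10000))
  r <- nearest_neighbour_distances(pts)
  expect_equal(unname(r$per_point_nnd_m), oracle_nnd(pts), tolerance = 1e-12)
  expect_equal(r$se_m, sd(oracle_nnd(pts)) / sqrt(200))
  expect_true(r$mean_m >= r$min_m && r$mean_m <= r$max_m)
})

test_that("the minimum NND is attained by a mutual nearest pair", {
  set.seed(41)
  for (k in 1:10) {
    pts <- cbind(runif(30, 0, 5000), runif(30, 0, 5000))
    nnd <- nearest_neighbour_distances(pts)$per_point_nnd_m
    expect_gte(sum(abs(nnd - min(nnd)) < 1e-9), 2)
  }
})

test_that("adding a far-away point leaves existing NNDs unchanged", {
  set.seed(42)
  pts <- cbind(runif(25, 0, 1000), runif(25, 0, 1000))
  base <- nearest_neighbour_distances(pts)$per_point_nnd_m
  far <- rbind(pts, c(1e6, 1e6))
  aug <- nearest_neighbour_distances(far)$per_point_nnd_m
  expect_equal(unname(aug[1:25]), unname(base), tolerance = 1e-12)
})

test_that("territory centroids are use-frequency-weighted means", {
  one <- data.frame(species = "goshawk", territory_id = "T1", nest_id = "N1",
                    x = 12.5, y = -3, stringsAsFactors = FALSE)
  one$years <- I(list(c(2004L, 2005L)))
  c1 <- territory_centroids(one)
  expect_equal(c(c1$x, c1$y), c(12.5, -3))
  expect_equal(c1$n_years_active, 2)

  two <- data.frame(species = "goshawk", territory_id = "T1",
                    nest_id = c("N1", "N2"), x = c(0, 4), y = c(0, 0),
                    stringsAsFactors = FALSE)
  two$years <- I(list(c(2004L, 2005L, 2006L), 2007L))
  c2 <- territory_centroids(two)
  # (3*0 + 1*4) / 4 = 1
  expect_equal(c(c2$x, c2$y), c(1, 0))
  expect_equal(c2$n_years_active, 4)
})

test_that("centroids agree with a direct weighted-mean oracle", {
  set.seed(43)
  rows <- lapply(1:20, function(t) {
    k <- sample(1:4, 1)
    df <- data.frame(species = "buzzard", territory_id = sprintf("T%02d", t),
                     nest_id = sprintf("T%02dN%d", t, seq_len(k)),
                     x = runif(k, 0, 1e4), y = runif(k, 0, 1e4),
                     stringsAsFactors = FALSE)
    df$years <- I(lapply(seq_len(k), function(i)
      sort(sample(2004:2011, sample(1:5, 1)))))
    df
  })
  nests <- do.call(rbind, rows)
  cents <- territory_centroids(nests)
  for (t in unique(nests$territory_id)) {
    sub <- nests[nests$territory_id == t, ]
    w <- lengths(sub$years)
    expect_equal(cents$x[cents$territory_id == t],
                 sum(sub$x * w) / sum(w), tolerance = 1e-12)
    expect_equal(cents$y[cents$territory_id == t],
                 sum(sub$y * w) / sum(w), tolerance = 1e-12)
    # centroid lies inside the bounding box (hence convex hull for our data)
    expect_true(cents$x[cents$territory_id == t] >= min(sub$x) - 1e-9 &&
                cents$x[cents$territory_id == t] <= max(sub$x) + 1e-9)
  }
})

test_that("null nests respect the patch-size and elevation filters", {
  # patches: one eligible, one too small (3 ha), one too high (400 m)
  land <- make_rect_landscape(data.frame(
    xmin = c(0, 2000, 3000), ymin = 0,
    xmax = c(1000, 2000 + sqrt(3e4), 4000), ymax = c(1000, sqrt(3e4), 1000),
    forest_type = c(1L, 1L, 1L), elevation_m = c(300, 300, 400)))
  cfg <- null_model_config(c(`1` = 100), min_patch_ha = 4.1,
                           max_elevation_m = 340, n_iterations = 1, seed = 1)
  set.seed(10)
  for (i in 1:50) {
    pt <- sample_null_nest(land, cfg)
    expect_equal(attr(pt, "patch_id"), "P001")
    expect_true(pt["x"] <= 1000 && pt["y"] <= 1000)
  }
})

test_that("a used type with no eligible patch is a configuration error", {
  land <- two_patch_landscape(types = c(1L, 2L), elev = c(100, 500))
  cfg <- null_model_config(c(`1` = 60, `2` = 40), min_patch_ha = 1,
                           max_elevation_m = 340, n_iterations = 1, seed = 1)
  expect_error(sample_null_nest(land, cfg), "forest type 2")
})

test_that("simulated NND sets have the exact n-1 / iterations x n shape", {
  land <- two_patch_landscape(side = 5000, types = c(1L, 1L))
  obs2 <- data.frame(nest_id = c("A", "B"), x = c(1000, 9000), y = c(2500, 2500))
  cfg <- null_model_config(c(`1` = 100), min_patch_ha = 1,
                           max_elevation_m = 1000, n_iterations = 1, seed = 7,
                           store_points = TRUE)
  sim <- simulate_null_nnds(obs2, land, cfg)
  expect_equal(dim(sim$values_m), c(1, 2))
  # one null nest: both simulated NNDs are the distances to that single point
  np <- sim$null_points[[1]]
  expect_equal(nrow(np), 1)
  d <- sqrt((obs2$x - np$x)^2 + (obs2$y - np$y)^2)
  expect_equal(unname(sim$values_m[1, ]), d, tolerance = 1e-12)

  # the flagship shape: 22 observed nests, 100 iterations of 21 random nests
  set.seed(11)
  obs22 <- data.frame(nest_id = sprintf("N%02d", 1:22),
                      x = runif(22, 0, 10000), y = runif(22, 0, 5000))
  cfg100 <- null_model_config(c(`1` = 100), min_patch_ha = 1,
                              max_elevation_m = 1000, n_iterations = 100,
                              seed = 3, store_points = TRUE)
  sim100 <- simulate_null_nnds(obs22, land, cfg100)
  expect_equal(dim(sim100$values_m), c(100, 22))
  expect_true(all(vapply(sim100$null_points, nrow, 1L) == 21))
  expect_true(all(sim100$values_m > 0))
  expect_error(simulate_null_nnds(obs2[1, ], land, cfg), "at least 2")
})

test_that("larger observed sets stochastically shorten simulated NNDs", {
  land <- two_patch_landscape(side = 5000, types = c(1L, 1L))
  cfg <- function(s) null_model_config(c(`1` = 100), min_patch_ha = 1,
                                       max_elevation_m = 1000,
                                       n_iterations = 10, seed = s)
  set.seed(17)
  wins <- 0
  for (s in 1:20) {
    small <- data.frame(nest_id = sprintf("a%d", 1:8),
                        x = runif(8, 0, 10000), y = runif(8, 0, 5000))
    big <- data.frame(nest_id = sprintf("b%d", 1:25),
                      x = runif(25, 0, 10000), y = runif(25, 0, 5000))
    m_small <- mean(simulate_null_nnds(small, land, cfg(s))$values_m)
    m_big <- mean(simulate_null_nnds(big, land, cfg(s + 1000))$values_m)
    wins <- wins + (m_big < m_small)
  }
  # one-sided sign test at the 5% level: >= 15/20 under-distances
  expect_gte(wins, 15)
})

test_that("histogram comparison handles degenerate and matched inputs", {
  one_bin <- histogram_comparison(list(`2004` = c(600, 700, 800)),
                                  list(`2004` = c(650, 750)), 1000)
  expect_equal(one_bin$observed_mean_pct[1], 100)
  expect_equal(one_bin$observed_se_pct[1], 0)

  set.seed(19)
  vals <- lapply(1:3, function(i) runif(30, 200, 3000))
  matched <- histogram_comparison(vals, vals, 500)
  expect_length(matched$exclusion_bins, 0)
  for (m in list(matched$observed_mean_pct, matched$simulated_mean_pct))
    expect_equal(sum(m), 100, tolerance = 1e-6)
  expect_error(histogram_comparison(list(), list(), 500), "at least one year")
})
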