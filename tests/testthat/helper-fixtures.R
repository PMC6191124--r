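# Fixtures built in code and independent oracles used across the suite.

# small landscape of axis-aligned rectangular patches
# spec: data.frame with xmin, ymin, xmax, ymax, forest_type, elevation_m
make_rect_landscape <- function(spec, study_area_km2 = NULL) {
  patches <- data.frame(
    patch_id = sprintf("P%03d", seq_len(nrow(spec))),
    forest_type = spec$forest_type,
    area_ha = (spec$xmax - spec$xmin) * (spec$ymax - spec$ymin) / 1e4,
    elevation_m = spec$elevation_m,
    stringsAsFactors = FALSE
  )
  patches$geometry <- I(lapply(seq_len(nrow(spec)), function(i)
    cbind(x = c(spec$xmin[i], spec$xmax[i], spec$xmax[i], spec$xmin[i], spec$xmin[i]),
          y = c(spec$ymin[i], spec$ymin[i], spec$ymax[i], spec$ymax[i], spec$ymin[i]))))
  if (is.null(study_area_km2)) study_area_km2 <- sum(patches$area_ha) / 100
  landscape(patches, study_area_km2)
}

# two side-by-side square patches of given side (m)
two_patch_landscape <- function(side = 1000, types = c(1L, 2L),
                                elev = c(100, 200)) {
  make_rect_landscape(data.frame(
    xmin = c(0, side), ymin = 0, xmax = c(side, 2 * side), ymax = side,
    forest_type = types, elevation_m = elev))
}

# --- independent oracles ------------------------------------------------

# winding-number point-in-polygon (different algorithm from the package's
# even-odd ray casting)
oracle_point_in_polygon <- function(x, y, ring) {
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  wn <- 0
  for (i in seq_len(nrow(ring) - 1)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    is_left <- (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1)
    if (y1 <= y && y2 > y && is_left > 0) wn <- wn + 1
    if (y1 > y && y2 <= y && is_left < 0) wn <- wn - 1
  }
  wn != 0
}

# O(n^2) all-pairs nearest neighbour distances, plain loops
oracle_nnd <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# direct two-mean evaluation of the G statistic (n-th roots taken before
# multiplying so the product cannot overflow)
oracle_g <- function(d) {
  sq <- d^2
  geometric <- prod(sq^(1 / length(sq)))
  geometric / (sum(sq) / length(sq))
}

# AICc by direct formula evaluation
oracle_aicc <- function(ll, k, n) -2 * ll + 2 * k + (2 * k^2 + 2 * k) / (n - k - 1)

# mid-rank counting percentile
oracle_percentile <- function(value, ref) {
  below <- 0; ties <- 0
  for (v in ref) {
    if (v < value) below <- below + 1
    else if (v == value) ties <- ties + 1
  }
  100 * (below + 0.5 * ties) / length(ref)
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# generator settings used by several stochastic checks: territorial raptors
# in the three mature-eucalyptus types of the default mosaic
preferred_weights <- c(`1` = 39.2, `2` = 43.1, `3` = 5.9)

eligible_area_m2 <- function(land, types = c(1, 2, 3)) {
  sum(land$patches$area_ha[land$patches$forest_type %in% types]) * 1e4
}

# a hard-core (territorial) multi-year pattern plus its habitat-matched
# null-model simulations; the shared fixture for the power/recovery checks
make_power_fixture <- function(seed, delta_factor = 1.5, n_terr = 25,
                               n_iter = 20, years = 5) {
  lc <- landscape_config(seed = seed)
  land <- generate_landscape(lc)
  delta <- delta_factor * expected_random_nnd(n_terr, eligible_area_m2(land))
  pc <- pattern_config("goshawk", n_terr, hard_core_m = delta,
                       preferred_types = preferred_weights,
                       years = seq_len(years), annual_activity_prob = 1,
                       nest_switch_prob = 0.1, switch_radius_m = 150,
                       seed = seed + 7)
  nests <- suppressMessages(
    assign_nests_to_patches(generate_nest_pattern(land, pc), land))
  sets <- annual_nest_sets(nests)
  props <- observed_type_proportions(nests)
  obs <- lapply(sets, nearest_neighbour_distances)
  sims <- lapply(seq_along(sets), function(k)
    simulate_null_nnds(sets[[k]], land,
                       null_model_config(props, min_patch_ha = 1,
                                         max_elevation_m = 1000,
                                         n_iterations = n_iter,
                                         seed = seed + 100 + k)))
  names(sims) <- names(sets)
  list(obs = obs, sims = sims, land = land,
       terr_of = setNames(nests$territory_id, nests$nest_id), delta = delta)
}

# "observed" NNDs drawn as one extra iteration of the very null model they
# are compared against: the exchangeable no-signal case
make_null_case_fixture <- function(seed, land, n_nests = 25, years = 5,
                                   n_iter = 20) {
  set.seed(seed)
  ext <- sqrt(land$study_area_km2 * 1e6)
  sets <- lapply(seq_len(years), function(y)
    data.frame(nest_id = sprintf("y%dN%d", y, seq_len(n_nests)),
               x = runif(n_nests, 0, ext), y = runif(n_nests, 0, ext)))
  names(sets) <- seq_len(years)
  sims <- lapply(seq_along(sets), function(k)
    simulate_null_nnds(sets[[k]], land,
                       null_model_config(default_type_proportions(),
                                         min_patch_ha = 1,
                                         max_elevation_m = 1000,
                                         n_iterations = n_iter + 1,
                                         seed = seed + 500 + k)))
  names(sims) <- names(sets)
  obs <- lapply(sims, function(s) setNames(s$values_m[1, ], colnames(s$values_m)))
  sims_rest <- lapply(sims, function(s) s$values_m[-1, , drop = FALSE])
  list(obs = obs, sims = sims_rest)
}
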