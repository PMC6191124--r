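# AICc, the observed-vs-null mixed model, across-year ANOVA, count trend.

test_that("AICc matches the small-sample formula", {
  expect_equal(aicc(0, 1, 10), 2.5)  # 0 + 2 + 4/8
  # correction vanishes for large n
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 3e-5)
  set.seed(60)
  for (k in 1:20) {
    ll <- runif(1, -1e5, 0); kk <- sample(1:8, 1); n <- sample(20:500, 1)
    expect_equal(aicc(ll, kk, n), oracle_aicc(ll, kk, n), tolerance = 1e-12)
  }
  expect_error(aicc(0, 5, 6), "undefined")
})

test_that("the observation table aligns simulated NNDs with their source nest", {
  obs <- list(`2004` = c(N1 = 100, N2 = 200))
  sim <- list(`2004` = matrix(c(10, 20, 30, 40), 2, 2,
                              dimnames = list(NULL, c("N1", "N2"))))
  tab <- nnd_observation_table(obs, sim, c(N1 = "T1", N2 = "T2"))
  expect_equal(nrow(tab), 2 + 4)
  expect_equal(tab$kind, c("observed", "observed", rep("simulated", 4)))
  sim_n1 <- tab[tab$kind == "simulated" & tab$nest_id == "N1", ]
  expect_equal(sim_n1$nnd_m, c(10, 20))
  expect_equal(unique(sim_n1$territory_id), "T1")
  expect_error(nnd_observation_table(obs, list(`2005` = sim[[1]])), "align")
})

test_that("the gamma GLMM detects hard-core spacing with positive beta", {
  fx <- make_power_fixture(seed = 3)
  tab <- nnd_observation_table(fx$obs, fx$sims, fx$terr_of)
  mc <- compare_observed_vs_null(tab)
  expect_s3_class(mc, "model_comparison")
  expect_equal(mc$delta_i, mc$aicc_null - mc$aicc_full)
  expect_gte(mc$delta_i, 6)
  expect_true(mc$territorial)
  expect_gt(mc$beta, 0)
  # beta sign is consistent with the raw means
  obs_mean <- mean(unlist(lapply(fx$obs, `[[`, "per_point_nnd_m")))
  sim_mean <- mean(unlist(lapply(fx$sims, function(s) s$values_m)))
  expect_gt(obs_mean, sim_mean)
})

test_that("observed rows drawn from the null distribution give delta below 6", {
  # the "observed" values are an extra iteration of the same null model
  land <- generate_landscape(landscape_config(seed = 21))
  fx <- make_null_case_fixture(22, land, n_nests = 15, years = 3, n_iter = 10)
  tab <- nnd_observation_table(fx$obs, fx$sims)
  # variance components collapse at the boundary in the no-signal case, so
  # let the comparison fall back to the log-normal backend if gamma stalls
  mc <- compare_observed_vs_null(tab, backend = "auto")
  expect_lt(mc$delta_i, 6)
  expect_false(mc$territorial)
})

test_that("permuting the observed/simulated labels destroys the signal", {
  fx <- make_power_fixture(seed = 5, n_terr = 12, n_iter = 8, years = 3)
  tab <- nnd_observation_table(fx$obs, fx$sims, fx$terr_of)
  set.seed(99)
  hits <- 0
  for (s in 1:10) {
    perm <- tab
    for (yr in unique(perm$year)) {
      idx <- which(perm$year == yr)
      perm$kind[idx] <- sample(perm$kind[idx])
    }
    mc <- compare_observed_vs_null(perm, backend = "lognormal")
    hits <- hits + mc$territorial
  }
  expect_lte(hits, 1)
})

test_that("a single NND kind is a contract error", {
  tab <- data.frame(nnd_m = runif(10, 100, 200), kind = "observed",
                    year = 1, territory_id = "T1", nest_id = "N1")
  expect_error(compare_observed_vs_null(tab), "both observed and simulated")
})

test_that("log-scale delta is invariant to rescaling all NNDs", {
  fx <- make_power_fixture(seed = 9, n_terr = 10, n_iter = 6, years = 3)
  tab <- nnd_observation_table(fx$obs, fx$sims, fx$terr_of)
  m1 <- compare_observed_vs_null(tab, backend = "lognormal")
  tab2 <- tab; tab2$nnd_m <- tab2$nnd_m * 3.7
  m2 <- compare_observed_vs_null(tab2, backend = "lognormal")
  expect_equal(m1$delta_i, m2$delta_i, tolerance = 1e-6)
  # and the verdict is reproducible run to run
  m3 <- compare_observed_vs_null(tab, backend = "lognormal")
  expect_identical(m1$territorial, m3$territorial)
  expect_equal(m1$delta_i, m3$delta_i, tolerance = 1e-10)
})

test_that("one-way ANOVA across years behaves like the textbook test", {
  same <- list(`2004` = c(1, 2, 3), `2005` = c(1, 2, 3))
  r <- annual_nnd_anova(same)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  set.seed(61)
  a <- rnorm(12, 100, 10); b <- rnorm(15, 120, 10)
  r2 <- annual_nnd_anova(list(`2004` = a, `2005` = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)

  # df bookkeeping with 8 groups sized like the buzzard census years
  sizes <- c(29, 26, 28, 39, 32, 34, 42, 30)
  grp <- lapply(sizes, function(n) rnorm(n, 1300, 300))
  names(grp) <- 2004:2011
  r3 <- annual_nnd_anova(grp)
  expect_equal(r3$df1, 7)
  expect_equal(r3$df2, sum(sizes) - 8)
  expect_error(annual_nnd_anova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("count trends reproduce the census correlation", {
  counts <- case_study_counts()
  gos <- counts[counts$species == "goshawk", ]
  r <- count_trend(gos)
  expect_equal(r$n, 8)
  expect_equal(round(r$r, 2), -0.74)
  expect_equal(round(r$p, 3), 0.036)

  inc <- data.frame(year = 2004:2011, n = 1:8)
  expect_equal(count_trend(inc)$r, 1)

  set.seed(62)
  arb <- data.frame(year = 2004:2011, n = sample(10:60, 8))
  expect_equal(count_trend(arb)$r, oracle_pearson(arb$n, arb$year),
               tolerance = 1e-10)
  expect_error(count_trend(data.frame(year = 1:2, n = c(1, 2))), "3 years")
  expect_error(count_trend(data.frame(year = 1:5, n = rep(4, 5))), "constant")
})
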