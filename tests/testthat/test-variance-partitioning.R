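test_that("a constant table yields four zero components", {
  grid <- expand.grid(host_isolate = 1:3, parasite_isolate = 1:3,
                      replicate = 1:2)
  grid$infections <- 4
  grid$trials <- 5L
  tab <- structure(grid, class = c("cross_infection_table", "data.frame"))
  vc <- anova_decompose(tab)
  expect_equal(unname(vc$sigma2), rep(0, 4))
})

test_that("EMS estimates match the brute-force oracle to 1e-10", {
  set.seed(41)
  for (i in 1:10) {
    tab <- random_small_table(a = sample(3:5, 1), b = sample(3:5, 1),
                              n = sample(2:4, 1))
    vc <- anova_decompose(tab)
    oracle <- brute_force_anova(as.data.frame(tab))
    expect_equal(vc$sigma2_raw, oracle, tolerance = 1e-10)
  }
})

test_that("mean squares agree with stats::lm on the same table", {
  set.seed(42)
  tab <- random_small_table(a = 5, b = 4, n = 3)
  vc <- anova_decompose(tab)
  df <- as.data.frame(tab)
  fit <- anova(lm(infections ~ factor(host_isolate) *
                    factor(parasite_isolate), data = df))
  expect_equal(unname(vc$mean_squares),
               unname(fit[["Mean Sq"]]), tolerance = 1e-10)
  expect_equal(unname(vc$df), unname(fit[["Df"]]))
})

test_that("degrees of freedom follow the balanced-design formulas", {
  set.seed(43)
  tab <- random_small_table(a = 6, b = 4, n = 3)
  vc <- anova_decompose(tab)
  expect_equal(unname(vc$df), c(5, 3, 15, 48))
  ## total SS identity: sum of stratum SS equals direct total SS
  df <- as.data.frame(tab)
  total_ss <- sum((df$infections - mean(df$infections))^2)
  expect_equal(sum(vc$mean_squares * vc$df), total_ss, tolerance = 1e-10)
})

test_that("known Gaussian components are recovered without bias", {
  set.seed(44)
  truth <- c(host = 1, parasite = 0.5, gxg = 2, error = 4)
  est <- t(vapply(1:20, function(i) {
    anova_decompose(gaussian_fixture(30, 30, 5, truth[1], truth[2],
                                     truth[3], truth[4]))$sigma2_raw
  }, numeric(4)))
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) < 3 * se),
              info = paste(round(colMeans(est), 3), collapse = ", "))
})

test_that("REML cross-check agrees with EMS on a well-behaved table", {
  set.seed(45)
  tab <- gaussian_fixture(12, 12, 4, 1, 1, 1.5, 2)
  ems <- anova_decompose(tab)
  reml <- anova_decompose(tab, method = "REML")
  expect_equal(unname(reml$sigma2), unname(ems$sigma2), tolerance = 0.25)
})

test_that("binary-response mode reproduces the per-trial decomposition", {
  set.seed(46)
  tab <- simulate_table(c(.5, .5), c(.5, .5), "MA", 6, 6, 4, 3, 0.1)
  vc <- anova_decompose(tab, response = "binary")
  ## error stratum df: a * b * (n*t - 1)
  expect_equal(unname(vc$df), c(5, 5, 25, 6 * 6 * (12 - 1)))
  expect_true(all(vc$sigma2 >= 0))
})

test_that("replicate and balance preconditions are enforced", {
  grid <- expand.grid(host_isolate = 1:3, parasite_isolate = 1:3,
                      replicate = 1)
  grid$infections <- 1
  grid$trials <- 5L
  tab <- structure(grid, class = c("cross_infection_table", "data.frame"))
  expect_error(anova_decompose(tab), "replicates")
  grid2 <- expand.grid(host_isolate = 1:3, parasite_isolate = 1:3,
                       replicate = 1:2)
  grid2$infections <- 1
  grid2$trials <- 5L
  tab2 <- structure(grid2[-1, ], class = c("cross_infection_table",
                                           "data.frame"))
  expect_error(anova_decompose(tab2), "balanced")
})

test_that("expected components map the decomposition onto the count scale", {
  d5 <- experiment_design(trials_per_cell = 5)
  expect_equal(unname(expected_components(infection_matrix("CONST", 3),
                                          c(.2, .3, .5), c(.3, .3, .4),
                                          d5)$sigma2[1:3]),
               c(0, 0, 0))
  ma <- expected_components(infection_matrix("MA", 2), c(.5, .5), c(.5, .5),
                            d5)
  expect_equal(ma$sigma2[["gxg"]], 25 * 0.25)
  expect_equal(ma$sigma2[["error"]], 0)  # 0/1 matrix, no assay error

  ## skewed parasite frequencies depress expected statistical GxG
  skew <- expected_components(infection_matrix("IMA", 2), c(.5, .5),
                              c(.99, .01), d5)
  even <- expected_components(infection_matrix("IMA", 2), c(.5, .5),
                              c(.5, .5), d5)
  expect_lt(skew$sigma2[["gxg"]], even$sigma2[["gxg"]])
})

test_that("component time series stacks per-generation decompositions", {
  set.seed(47)
  params <- sim_params(N = 2000, K = 3, generations = 60, seed = 8)
  tr <- run_simulation(params)
  d <- experiment_design(8, 8, 5, 3, sampling_interval = 20,
                         error_rate = 0.05)
  tabs <- longitudinal_survey(tr, d)
  ts <- component_timeseries(tabs)
  expect_equal(nrow(ts), 4)
  expect_equal(ts$generation, c(0L, 20L, 40L, 60L))
  one <- anova_decompose(tabs[[2]])
  expect_equal(ts$sigma2_gxg[2], one$sigma2[["gxg"]])
  expect_equal(ts$ms_error[2], one$mean_squares[["error"]])
  expect_error(component_timeseries(list()), "non-empty")
})

test_that("a CONST survey shows no statistical GxG beyond noise", {
  set.seed(48)
  params <- sim_params(N = 2000, K = 3, s_h = .67, s_p = .69,
                       model = infection_matrix("CONST", 3),
                       generations = 200, seed = 13)
  tr <- run_simulation(params)
  tabs <- longitudinal_survey(tr, experiment_design(
    15, 15, 5, 5, sampling_interval = 20, error_rate = 0.05))
  ts <- component_timeseries(tabs)
  ## raw (untruncated) interaction estimates center on zero
  se <- sd(ts$sigma2_gxg_raw) / sqrt(nrow(ts))
  expect_lt(abs(mean(ts$sigma2_gxg_raw)), 3 * se + 0.01)
  expect_lt(mean(ts$sigma2_gxg), 0.05 * mean(ts$sigma2_error))
})
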