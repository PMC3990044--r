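test_that("exact likelihood matches literal joint enumeration", {
  set.seed(51)
  tab <- simulate_table(c(.6, .4), c(.5, .5), "MA", 3, 3, 5, 2, 0.05)
  hyp <- gxg_hypothesis("MA", 2, epsilon = 0.05)
  ll <- log_likelihood_exact(tab, hyp)
  oracle <- brute_force_loglik(as.data.frame(tab), hyp$matrix$alpha,
                               hyp$f, hyp$g, 0.05, 5)
  expect_equal(ll, oracle, tolerance = 1e-10)

  ## property: random small instances, several models and K
  for (i in 1:6) {
    K <- sample(2:3, 1)
    model <- sample(c("MA", "IMA", "GFG"), 1)
    G <- sample(2:3, 1); H <- sample(2:3, 1)
    f <- as.vector(rmultinom(1, 20, rep(1, K))) / 20
    f <- (f + 0.05) / sum(f + 0.05)   # keep away from the boundary
    g <- rep(1 / K, K)
    tab_i <- simulate_table(f, g, model, G, H, 3, 2, 0.1)
    hyp_i <- gxg_hypothesis(model, K, f = f, g = g, epsilon = 0.1)
    expect_equal(
      log_likelihood_exact(tab_i, hyp_i),
      brute_force_loglik(as.data.frame(tab_i), hyp_i$matrix$alpha,
                         f, g, 0.1, 3),
      tolerance = 1e-8, info = paste(model, K, G, H))
  }
})

test_that("exact likelihood is invariant under isolate relabeling", {
  set.seed(52)
  tab <- simulate_table(c(.5, .5), c(.7, .3), "IMA", 4, 3, 5, 2, 0.05)
  hyp <- gxg_hypothesis("IMA", 2, epsilon = 0.05)
  ll <- log_likelihood_exact(tab, hyp)
  df <- as.data.frame(tab)
  perm <- sample(4)
  df$host_isolate <- perm[df$host_isolate]
  tab2 <- structure(df, class = class(tab), design = attr(tab, "design"))
  expect_equal(log_likelihood_exact(tab2, hyp), ll, tolerance = 1e-10)
})

test_that("symmetric genotype relabeling leaves the likelihood unchanged", {
  ## the MA matrix maps to itself under any simultaneous permutation;
  ## permuting f and g together must not change the likelihood
  set.seed(53)
  tab <- simulate_table(c(.6, .3, .1), rep(1 / 3, 3), "MA", 3, 3, 4, 2, 0.05)
  f <- c(.5, .3, .2); g <- c(.2, .2, .6)
  ll1 <- log_likelihood_exact(tab, gxg_hypothesis("MA", 3, f, g,
                                                  epsilon = 0.05))
  perm <- c(3, 1, 2)
  ll2 <- log_likelihood_exact(tab, gxg_hypothesis("MA", 3, f[perm], g[perm],
                                                  epsilon = 0.05))
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("epsilon = 0 on contradictory data flags -Inf", {
  d <- experiment_design(2, 2, 5, 2, error_rate = 0)
  tab <- run_cross_infection(c(1, 2), c(1, 2), infection_matrix("MA", 2), d)
  df <- as.data.frame(tab)
  df$infections[1] <- 5 - df$infections[1]   # impossible under eps = 0
  tab2 <- structure(df, class = class(tab), design = d)
  expect_warning(
    ll <- log_likelihood_exact(tab2, gxg_hypothesis("MA", 2, epsilon = 0)),
    "-Inf")
  expect_identical(ll, -Inf)
})

test_that("the enumeration guard redirects oversized instances", {
  set.seed(54)
  tab <- simulate_table(c(.5, .5), c(.5, .5), "MA", 15, 15, 2, 2, 0.05)
  expect_error(log_likelihood_exact(tab, gxg_hypothesis("MA", 2)),
               "fit_model")
})

test_that("CONST fits reduce to the closed-form iid binomial likelihood", {
  set.seed(55)
  tab <- simulate_table(c(.5, .5), c(.5, .5), "MA", 5, 5, 5, 3, 0.05)
  fit <- fit_model(tab, "CONST", 2, epsilon = 0.01, seed = 1)
  df <- as.data.frame(tab)
  pi_hat <- sum(df$infections) / (nrow(df) * 5)
  expect_equal(fit$logLik, sum(dbinom(df$infections, 5, pi_hat, log = TRUE)),
               tolerance = 1e-10)
  expect_equal(fit$n_params, 1L)
})

test_that("EM improves on the uniform start and recovers frequencies", {
  set.seed(56)
  tab <- simulate_table(c(.7, .3), c(.7, .3), "MA", 20, 20, 5, 5, 0.02)
  fit <- fit_model(tab, "MA", 2, epsilon = 0.02, seed = 10)
  ## up to simultaneous genotype relabeling
  err_id <- max(abs(fit$f - c(.7, .3)), abs(fit$g - c(.7, .3)))
  err_sw <- max(abs(fit$f - c(.3, .7)), abs(fit$g - c(.3, .7)))
  expect_lt(min(err_id, err_sw), 0.1)
  expect_identical(fit$objective, "elbo")  # 2^40 assignments: beyond guard
  expect_true(fit$converged)

  ## small instance: fitted logLik dominates the uniform-frequency start
  set.seed(57)
  small <- simulate_table(c(.8, .2), c(.5, .5), "MA", 5, 5, 5, 3, 0.05)
  fit_s <- fit_model(small, "MA", 2, epsilon = 0.05, seed = 11)
  ll_uniform <- log_likelihood_exact(small, gxg_hypothesis("MA", 2,
                                                           epsilon = 0.05))
  expect_identical(fit_s$objective, "exact")
  expect_gte(fit_s$logLik, ll_uniform - 1e-9)
})

test_that("fit attains the profile maximum found by exhaustive grid search", {
  set.seed(58)
  tab <- simulate_table(c(.7, .3), c(.4, .6), "MA", 3, 2, 5, 3, 0.05)
  fit <- fit_model(tab, "MA", 2, epsilon = 0.05, seed = 12)
  xs <- seq(0.01, 0.99, by = 0.01)
  grid_best <- max(vapply(xs, function(x) {
    max(vapply(xs, function(y) {
      log_likelihood_exact(tab, gxg_hypothesis("MA", 2, c(x, 1 - x),
                                               c(y, 1 - y), epsilon = 0.05))
    }, 0))
  }, 0))
  expect_gte(fit$logLik, grid_best - 1e-6)
})

test_that("posterior genotype assignments identify the true latent classes", {
  set.seed(59)
  tab <- simulate_table(c(.5, .5), c(.5, .5), "MA", 12, 12, 5, 5, 0.02)
  fit <- fit_model(tab, "MA", 2, epsilon = 0.02, seed = 13)
  truth <- attr(tab, "host_genotypes")
  map <- apply(fit$host_posterior, 1, which.max)
  acc <- max(mean(map == truth), mean((3L - map) == truth))
  expect_gte(acc, 0.9)
})

test_that("model comparison ranks by AIC with order-stable tie breaking", {
  set.seed(60)
  tab <- simulate_table(c(.6, .4), c(.6, .4), "MA", 8, 8, 5, 3, 0.02)
  cmp <- compare_models(tab, list(list(model_name = "MA", K = 2),
                                  list(model_name = "CONST", K = 2),
                                  list(model_name = "MA", K = 2)),
                        seed = 14, n_restarts = 4)
  expect_equal(cmp$table$logLik[1], cmp$table$logLik[3])
  expect_equal(cmp$selected, 1L)   # first of the AIC tie
  expect_lt(cmp$table$AIC[1], cmp$table$AIC[2])
  ## nested duplicate pair appears in the LRT table with statistic 0
  dup <- cmp$lrt[cmp$lrt$df == 0, ]
  expect_true(all(abs(dup$statistic) < 1e-9))
})

test_that("nested K pairs give non-negative LRT statistics", {
  set.seed(61)
  tab <- simulate_table(c(.5, .3, .2), c(.5, .3, .2), "MA", 8, 8, 5, 3, 0.02)
  cmp <- compare_models(tab, list(list(model_name = "MA", K = 2),
                                  list(model_name = "MA", K = 3)),
                        seed = 15, n_restarts = 4)
  row <- cmp$lrt[cmp$lrt$null == 1 & cmp$lrt$alternative == 2, ]
  expect_equal(nrow(row), 1)
  expect_gte(row$statistic, -1e-6)
  expect_equal(row$df, 2)
})

test_that("selection accuracy grows with design size", {
  set.seed(62)
  run_design <- function(n_iso, trials, reps, n_rep) {
    mean(vapply(seq_len(n_rep), function(i) {
      tab <- simulate_table(rep(1 / 3, 3), rep(1 / 3, 3), "MA",
                            n_iso, n_iso, trials, reps, 0.01)
      cmp <- compare_models(tab,
                            list(list(model_name = "MA", K = 3),
                                 list(model_name = "GFG", K = 3),
                                 list(model_name = "CONST", K = 3)),
                            seed = 100 + i, n_restarts = 4)
      cmp$table$model[cmp$selected] == "MA"
    }, logical(1)))
  }
  acc_small <- run_design(4, 1, 2, 8)
  acc_big <- run_design(12, 5, 5, 8)
  expect_gte(acc_big, acc_small)
  expect_gte(acc_big, 0.9)
})

test_that("comparison reports round-trip to JSON and posterior CSV", {
  set.seed(63)
  tab <- simulate_table(c(.5, .5), c(.5, .5), "MA", 6, 6, 5, 3, 0.02)
  cmp <- compare_models(tab, list(list(model_name = "MA", K = 2),
                                  list(model_name = "CONST", K = 2)),
                        seed = 16, n_restarts = 3)
  jp <- file.path(tempdir(), "cmp.json")
  pp <- file.path(tempdir(), "post.csv")
  write_model_comparison(cmp, jp, posterior_csv = pp)
  rep <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(rep$selected$model, cmp$table$model[cmp$selected])
  post <- read.csv(pp)
  expect_setequal(unique(post$species), c("host", "parasite"))
  sums <- tapply(post$posterior, list(post$species, post$isolate), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
})
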