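# Independent oracles and fixture generators. These deliberately use the
# slowest, most literal formulations so they share no code path with the
# package implementation.

# Two-way ANOVA sums of squares by direct summation over raw deviations.
brute_force_anova <- function(df) {
  hosts <- sort(unique(df$host_isolate))
  paras <- sort(unique(df$parasite_isolate))
  reps <- sort(unique(df$replicate))
  a <- length(hosts); b <- length(paras); n <- length(reps)
  y <- function(g, h, r) {
    df$infections[df$host_isolate == g & df$parasite_isolate == h &
                    df$replicate == r]
  }
  grand <- mean(df$infections)
  ybar_g <- sapply(hosts, function(g) mean(df$infections[df$host_isolate == g]))
  ybar_h <- sapply(paras, function(h)
    mean(df$infections[df$parasite_isolate == h]))
  ybar_gh <- outer(hosts, paras, Vectorize(function(g, h)
    mean(df$infections[df$host_isolate == g & df$parasite_isolate == h])))
  ss_A <- ss_B <- ss_AB <- ss_E <- 0
  for (gi in seq_along(hosts)) {
    ss_A <- ss_A + b * n * (ybar_g[gi] - grand)^2
    for (hi in seq_along(paras)) {
      ss_AB <- ss_AB + n * (ybar_gh[gi, hi] - ybar_g[gi] - ybar_h[hi] +
                              grand)^2
      for (r in reps) {
        ss_E <- ss_E + (y(hosts[gi], paras[hi], r) - ybar_gh[gi, hi])^2
      }
    }
  }
  for (hi in seq_along(paras)) ss_B <- ss_B + a * n * (ybar_h[hi] - grand)^2
  ms <- c(host = ss_A / (a - 1), parasite = ss_B / (b - 1),
          gxg = ss_AB / ((a - 1) * (b - 1)), error = ss_E / (a * b * (n - 1)))
  c(host = (ms[["host"]] - ms[["gxg"]]) / (b * n),
    parasite = (ms[["parasite"]] - ms[["gxg"]]) / (a * n),
    gxg = (ms[["gxg"]] - ms[["error"]]) / n,
    error = ms[["error"]])
}

# Literal joint-enumeration log-likelihood: sums over every assignment of
# genotypes to ALL isolates (host and parasite) at once.
brute_force_loglik <- function(df, alpha, f, g, epsilon, trials) {
  G <- max(df$host_isolate)
  H <- max(df$parasite_isolate)
  K <- length(f)
  pi_adj <- alpha * (1 - epsilon) + (1 - alpha) * epsilon
  assign_grid <- expand.grid(rep(list(seq_len(K)), G + H))
  terms <- apply(as.matrix(assign_grid), 1, function(z) {
    zh <- z[seq_len(G)]
    zp <- z[G + seq_len(H)]
    lp <- sum(log(f[zh])) + sum(log(g[zp]))
    for (row in seq_len(nrow(df))) {
      pi <- pi_adj[zh[df$host_isolate[row]], zp[df$parasite_isolate[row]]]
      lp <- lp + dbinom(df$infections[row], trials, pi, log = TRUE)
    }
    lp
  })
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Balanced table drawn from a Gaussian two-way random-effects model with
# known variance components.
gaussian_fixture <- function(a = 30, b = 30, n = 5,
                             s2_host = 1, s2_parasite = 0.5, s2_gxg = 2,
                             s2_error = 4) {
  A <- rnorm(a, 0, sqrt(s2_host))
  B <- rnorm(b, 0, sqrt(s2_parasite))
  AB <- matrix(rnorm(a * b, 0, sqrt(s2_gxg)), a, b)
  grid <- expand.grid(host_isolate = seq_len(a), parasite_isolate = seq_len(b),
                      replicate = seq_len(n))
  grid$infections <- A[grid$host_isolate] + B[grid$parasite_isolate] +
    AB[cbind(grid$host_isolate, grid$parasite_isolate)] +
    rnorm(nrow(grid), 0, sqrt(s2_error))
  grid$trials <- 1L
  structure(grid, class = c("cross_infection_table", "data.frame"),
            design = experiment_design(a, b, 1, n),
            generation = NA_integer_)
}

# Random small integer-count table (not tied to any infection model).
random_small_table <- function(a = 4, b = 3, n = 3, t = 5) {
  grid <- expand.grid(host_isolate = seq_len(a), parasite_isolate = seq_len(b),
                      replicate = seq_len(n))
  grid$infections <- sample(0:t, nrow(grid), replace = TRUE)
  grid$trials <- t
  structure(grid, class = c("cross_infection_table", "data.frame"),
            design = experiment_design(a, b, t, n),
            generation = NA_integer_)
}

# Cross-infection table simulated from known genotype frequencies.
simulate_table <- function(f, g, model, n_host, n_para, trials, reps,
                           epsilon) {
  K <- length(f)
  hosts <- sample_isolates(f, n_host)
  paras <- sample_isolates(g, n_para)
  run_cross_infection(hosts, paras, infection_matrix(model, K),
                      experiment_design(n_host, n_para, trials, reps,
                                        error_rate = epsilon))
}
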