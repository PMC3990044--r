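#' Specify a functional-model hypothesis for likelihood inference
#'
#' A hypothesis fixes an infection-model family and genotype number K; the
#' genotype frequencies `f` (host) and `g` (parasite) are the free
#' parameters estimated from the cross-infection data alone, with the latent
#' genotype of each isolate integrated out. The outcome error rate `epsilon`
#' keeps the likelihood finite when a 0/1 infection matrix meets a
#' discordant count.
#'
#' @param model_name `"MA"`, `"IMA"`, `"GFG"` or `"CONST"`.
#' @param K candidate number of segregating genotypes per species.
#' @param f,g genotype frequency vectors (default uniform 1/K).
#' @param epsilon outcome error rate in (0, 0.5) (default 0.01).
#' @param const_prob infection probability of the `CONST` matrix.
#' @return An object of class `gxg_hypothesis`.
#' @export
gxg_hypothesis <- function(model_name, K, f = rep(1 / K, K),
                           g = rep(1 / K, K), epsilon = 0.01,
                           const_prob = 0.5) {
  matrix <- infection_matrix(model_name, K, c = const_prob)
  check_simplex(f, "f")
  check_simplex(g, "g")
  stopifnot(length(f) == K, length(g) == K, epsilon >= 0, epsilon < 0.5)
  structure(list(model_name = model_name, K = as.integer(K),
                 matrix = matrix, f = as.numeric(f), g = as.numeric(g),
                 epsilon = epsilon, const_prob = const_prob),
            class = "gxg_hypothesis")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## per-cell genotype log-likelihoods summed over replicates:
## ll[g, h, i, j] = sum_r log Binom(y_ghr ; t, pi'_ij)
## -Inf terms are floored at -1e300 so matrix products stay defined.
cell_loglik_array <- function(table, hyp) {
  df <- as.data.frame(table)
  G <- max(df$host_isolate)
  H <- max(df$parasite_isolate)
  t <- df$trials[1]
  K <- hyp$K
  pi_adj <- adjust_error(hyp$matrix$alpha, hyp$epsilon)
  cell <- df$host_isolate + (df$parasite_isolate - 1L) * G
  cnt <- unclass(table(factor(cell, levels = seq_len(G * H)),
                       factor(df$infections, levels = 0:t)))
  logdb <- vapply(as.vector(pi_adj),
                  function(pp) stats::dbinom(0:t, t, pp, log = TRUE),
                  numeric(t + 1L))
  logdb[!is.finite(logdb)] <- -1e300
  ll <- cnt %*% logdb                    # (G*H) x (K*K)
  array(ll, dim = c(G, H, K, K))
}

enumeration_guard_ok <- function(G, H, K, limit = 1e7) {
  (G + H) * log(K) <= log(limit)
}

#' Exact log-likelihood of a cross-infection table under a hypothesis
#'
#' Computes `log L = log sum_z P(z) P(data | z)` where the sum runs over all
#' joint assignments `z` of latent genotypes to isolates, host isolates
#' drawn i.i.d. from `f` and parasite isolates from `g`, and each cell count
#' is `Binomial(trials, pi')` with `pi'` the error-adjusted matrix entry for
#' the assigned genotype pair. Feasible only for small instances: the guard
#' requires `K^(G+H) <= 1e7` joint assignments. Internally the sum
#' marginalizes one margin exactly (isolates on one side are conditionally
#' independent given the other side's assignment), which is algebraically
#' identical to the full joint sum.
#'
#' @param table a `cross_infection_table`.
#' @param hyp a [gxg_hypothesis()].
#' @return the log-likelihood (scalar). `-Inf` (with a warning) if
#'   `epsilon = 0` and the data contain an outcome the matrix forbids.
#' @export
log_likelihood_exact <- function(table, hyp) {
  stopifnot(inherits(hyp, "gxg_hypothesis"))
  df <- as.data.frame(table)
  G <- max(df$host_isolate)
  H <- max(df$parasite_isolate)
  K <- hyp$K
  if (!enumeration_guard_ok(G, H, K)) {
    stop("K^(G+H) exceeds the enumeration guard (1e7); use fit_model()")
  }
  ll <- cell_loglik_array(table, hyp)
  f <- hyp$f
  g <- hyp$g
  if (G > H) {                      # enumerate over the smaller margin
    ll <- aperm(ll, c(2, 1, 4, 3))
    tmp <- f; f <- g; g <- tmp
    tmp <- G; G <- H; H <- tmp
  }
  z_grid <- as.matrix(expand.grid(rep(list(seq_len(K)), G)))
  log_g <- log(pmax(g, 1e-300))
  log_f <- log(pmax(f, 1e-300))
  per_z <- apply(z_grid, 1L, function(z) {
    M <- matrix(0, H, K)            # M[h, j] = sum_g ll[g, h, z_g, j]
    for (gi in seq_len(G)) {
      M <- M + ll[gi, , z[gi], , drop = TRUE]
    }
    M <- M + matrix(log_g, H, K, byrow = TRUE)
    sum(log_f[z]) + sum(apply(M, 1L, logsumexp))
  })
  out <- logsumexp(per_z)
  if (!is.finite(out) || out < -1e250) {
    out <- -Inf
    warning("log-likelihood is -Inf: data contain outcomes the ",
            "error-free matrix forbids (epsilon = 0?)")
  }
  out
}

## mean-field evidence lower bound for the latent-genotype model
elbo_value <- function(Rh, Rp, f, g, LLh, G, H, K) {
  log_f <- log(pmax(f, 1e-300))
  log_g <- log(pmax(g, 1e-300))
  ent <- function(R) -sum(R[R > 0] * log(R[R > 0]))
  cross <- sum((LLh %*% as.vector(Rp)) * as.vector(Rh))
  cross + sum(Rh %*% log_f) + sum(Rp %*% log_g) + ent(Rh) + ent(Rp)
}

row_softmax <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Fit a functional-model hypothesis to cross-infection data
#'
#' Maximizes the latent-genotype likelihood over the genotype frequencies
#' `f` and `g` (and optionally `epsilon`) by mean-field variational EM:
#' each host isolate carries a posterior distribution over the K genotypes,
#' updated holding the parasite posteriors fixed, and vice versa, with the
#' frequency estimates refreshed from the posterior means. Each coordinate
#' update cannot decrease the evidence lower bound (ELBO), which is asserted
#' at every iteration. Multiple restarts (the first from uniform
#' frequencies, the rest random) guard against local optima.
#'
#' On instances small enough for exact enumeration the returned `logLik` is
#' the exact likelihood at the fitted parameters (`objective = "exact"`);
#' otherwise it is the ELBO, a lower bound (`objective = "elbo"`).
#'
#' @param table a `cross_infection_table`.
#' @param model_name,K,epsilon,const_prob as in [gxg_hypothesis()].
#' @param estimate_epsilon also maximize over `epsilon` (ignored for
#'   `CONST`, whose single infection probability already absorbs it).
#' @param n_restarts number of EM initializations (default 10).
#' @param max_iter,tol iteration cap and absolute ELBO convergence
#'   tolerance per restart.
#' @param seed integer seed for the random restarts (same seed, same fit).
#' @return An object of class `gxg_fit`: the fitted hypothesis plus
#'   `logLik`, `objective`, `elbo`, `n_params`, posterior genotype matrices
#'   `host_posterior` (G x K) and `parasite_posterior` (H x K), `converged`
#'   and `iterations`.
#' @export
fit_model <- function(table, model_name, K, epsilon = 0.01,
                      estimate_epsilon = FALSE, const_prob = NULL,
                      n_restarts = 10, max_iter = 500, tol = 1e-8,
                      seed = NULL) {
  df <- as.data.frame(table)
  G <- max(df$host_isolate)
  H <- max(df$parasite_isolate)
  t <- df$trials[1]
  K <- as.integer(K)
  if (!is.null(seed)) set.seed(seed)

  if (model_name == "CONST") {
    ## closed form: all cells share one success probability
    pi_hat <- sum(df$infections) / (nrow(df) * t)
    pi_hat <- min(max(pi_hat, epsilon), 1 - epsilon)
    ll <- sum(stats::dbinom(df$infections, t, pi_hat, log = TRUE))
    chat <- (pi_hat - epsilon) / (1 - 2 * epsilon)
    hyp <- gxg_hypothesis("CONST", max(K, 2L), epsilon = epsilon,
                          const_prob = chat)
    return(structure(
      c(hyp, list(logLik = ll, objective = "exact", elbo = ll,
                  n_params = 1L,
                  host_posterior = matrix(1 / hyp$K, G, hyp$K),
                  parasite_posterior = matrix(1 / hyp$K, H, hyp$K),
                  converged = TRUE, iterations = 0L)),
      class = "gxg_fit"))
  }

  run_em <- function(hyp, f, g, Rp) {
    LL <- cell_loglik_array(table, hyp)
    LLh <- matrix(aperm(LL, c(1, 3, 2, 4)), G * K, H * K)
    LLp <- matrix(aperm(LL, c(2, 4, 1, 3)), H * K, G * K)
    Rh <- matrix(1 / K, G, K)
    elbo_old <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      Rh <- row_softmax(matrix(LLh %*% as.vector(Rp), G, K) +
                          matrix(log(pmax(f, 1e-300)), G, K, byrow = TRUE))
      f <- colMeans(Rh)
      Rp <- row_softmax(matrix(LLp %*% as.vector(Rh), H, K) +
                          matrix(log(pmax(g, 1e-300)), H, K, byrow = TRUE))
      g <- colMeans(Rp)
      elbo <- elbo_value(Rh, Rp, f, g, LLh, G, H, K)
      if (elbo < elbo_old - 1e-6 * (1 + abs(elbo_old))) {
        stop("internal error: ELBO decreased during EM")
      }
      if (abs(elbo - elbo_old) < tol) {
        converged <- TRUE
        break
      }
      elbo_old <- elbo
    }
    list(f = f, g = g, Rh = Rh, Rp = Rp, elbo = elbo,
         converged = converged, iterations = iter)
  }

  rdirichlet1 <- function(K) {
    x <- stats::rgamma(K, 1)
    x / sum(x)
  }

  best <- NULL
  eps <- epsilon
  for (r in seq_len(n_restarts)) {
    f0 <- if (r == 1L) rep(1 / K, K) else rdirichlet1(K)
    g0 <- if (r == 1L) rep(1 / K, K) else rdirichlet1(K)
    Rp0 <- if (r == 1L) matrix(1 / K, H, K) else
      t(replicate(H, rdirichlet1(K)))
    hyp <- gxg_hypothesis(model_name, K, epsilon = eps)
    res <- run_em(hyp, f0, g0, Rp0)
    if (estimate_epsilon) {
      for (outer in 1:3) {
        opt <- stats::optimize(function(e) {
          h2 <- gxg_hypothesis(model_name, K, epsilon = e)
          LL <- cell_loglik_array(table, h2)
          LLh <- matrix(aperm(LL, c(1, 3, 2, 4)), G * K, H * K)
          elbo_value(res$Rh, res$Rp, res$f, res$g, LLh, G, H, K)
        }, interval = c(1e-4, 0.499), maximum = TRUE)
        eps_new <- opt$maximum
        res <- run_em(gxg_hypothesis(model_name, K, epsilon = eps_new),
                      res$f, res$g, res$Rp)
        if (abs(eps_new - eps) < 1e-5) { eps <- eps_new; break }
        eps <- eps_new
      }
    }
    if (is.null(best) || res$elbo > best$res$elbo) {
      best <- list(res = res, epsilon = eps)
    }
    eps <- epsilon
  }
  res <- best$res
  if (!res$converged) {
    warning("EM did not converge within max_iter; best value returned")
  }
  hyp <- gxg_hypothesis(model_name, K, f = res$f, g = res$g,
                        epsilon = best$epsilon)
  if (enumeration_guard_ok(G, H, K)) {
    logLik <- log_likelihood_exact(table, hyp)
    objective <- "exact"
  } else {
    logLik <- res$elbo
    objective <- "elbo"
  }
  n_params <- 2L * (K - 1L) + as.integer(estimate_epsilon)
  structure(
    c(hyp, list(logLik = logLik, objective = objective, elbo = res$elbo,
                n_params = n_params,
                host_posterior = res$Rh, parasite_posterior = res$Rp,
                converged = res$converged, iterations = res$iterations)),
    class = "gxg_fit")
}

#' @export
print.gxg_fit <- function(x, ...) {
  cat("Fitted", x$model_name, "hypothesis, K =", x$K, "\n")
  cat("  logLik =", format(x$logLik), paste0("(", x$objective, ")"),
      " params =", x$n_params, "\n")
  cat("  f =", round(x$f, 4), "\n  g =", round(x$g, 4),
      "\n  epsilon =", x$epsilon, "\n")
  invisible(x)
}

## smaller-K fits of the same family are nested in larger-K fits (pad the
## extra genotype frequencies with zeros); families are not nested in each
## other for K >= 2 (the 0/1 patterns cannot represent one another)
is_nested_pair <- function(fit_small, fit_big) {
  fit_small$model_name == fit_big$model_name && fit_small$K <= fit_big$K
}

#' Fit and compare several functional-model hypotheses
#'
#' Fits each candidate with [fit_model()], ranks them by
#' `AIC = 2 k - 2 logLik`, and reports likelihood-ratio statistics for
#' nested pairs (same model family, smaller or equal K). The selected model
#' is the lowest-AIC fit; AIC ties are broken in favor of fewer parameters,
#' then input order.
#'
#' @param table a `cross_infection_table`.
#' @param hypotheses a list; each element a list with `model_name` and `K`
#'   (plus optional `epsilon`, `estimate_epsilon`, `const_prob`).
#' @param seed seed passed to every fit (so identical hypotheses give
#'   identical fits).
#' @param ... further arguments passed to [fit_model()].
#' @return An object of class `gxg_model_comparison`: `fits` (list of
#'   `gxg_fit`), `table` (data.frame with model, K, logLik, objective,
#'   n_params, AIC, delta_AIC), `lrt` (data.frame of nested-pair tests) and
#'   `selected` (index of the chosen hypothesis).
#' @export
compare_models <- function(table, hypotheses, seed = NULL, ...) {
  if (length(hypotheses) < 2) stop("need at least two hypotheses")
  fits <- lapply(hypotheses, function(h) {
    do.call(fit_model,
            c(list(table = table, seed = seed), h, list(...)))
  })
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model_name"),
    K = vapply(fits, `[[`, 0L, "K"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    objective = vapply(fits, `[[`, "", "objective"),
    n_params = vapply(fits, `[[`, 0L, "n_params"))
  tab$AIC <- 2 * tab$n_params - 2 * tab$logLik
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  ord <- order(tab$AIC, tab$n_params, seq_len(nrow(tab)))
  selected <- ord[1L]

  lrt <- NULL
  n <- length(fits)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (is_nested_pair(fits[[i]], fits[[j]]) &&
          tab$n_params[i] <= tab$n_params[j]) {
        stat <- 2 * (tab$logLik[j] - tab$logLik[i])
        dfree <- tab$n_params[j] - tab$n_params[i]
        p <- if (dfree > 0) stats::pchisq(stat, dfree, lower.tail = FALSE)
             else NA_real_
        lrt <- rbind(lrt, data.frame(
          null = i, alternative = j, statistic = stat, df = dfree,
          p_value = p))
      }
    }
  }
  structure(list(fits = fits, table = tab, lrt = lrt, selected = selected),
            class = "gxg_model_comparison")
}

#' @export
print.gxg_model_comparison <- function(x, ...) {
  cat("Model comparison (selected: ", x$table$model[x$selected],
      ", K = ", x$table$K[x$selected], ")\n", sep = "")
  print(x$table)
  if (!is.null(x$lrt)) {
    cat("Likelihood-ratio tests (nested pairs):\n")
    print(x$lrt)
  }
  invisible(x)
}

#' Write a model-comparison report (JSON) and posterior assignments (CSV)
#'
#' @param x a `gxg_model_comparison`.
#' @param json_path path for the JSON report (per-model logLik, parameter
#'   counts, AIC, selected model).
#' @param posterior_csv optional path for the selected fit's posterior
#'   genotype probabilities per isolate.
#' @return `json_path`, invisibly.
#' @export
write_model_comparison <- function(x, json_path, posterior_csv = NULL) {
  report <- list(
    models = x$table,
    selected = list(model = x$table$model[x$selected],
                    K = x$table$K[x$selected]),
    lrt = x$lrt)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(posterior_csv)) {
    fit <- x$fits[[x$selected]]
    Rh <- fit$host_posterior
    Rp <- fit$parasite_posterior
    post <- rbind(
      data.frame(species = "host", isolate = rep(seq_len(nrow(Rh)),
                                                 ncol(Rh)),
                 genotype = rep(seq_len(ncol(Rh)), each = nrow(Rh)),
                 posterior = as.vector(Rh)),
      data.frame(species = "parasite", isolate = rep(seq_len(nrow(Rp)),
                                                     ncol(Rp)),
                 genotype = rep(seq_len(ncol(Rp)), each = nrow(Rp)),
                 posterior = as.vector(Rp)))
    utils::write.csv(post, posterior_csv, row.names = FALSE)
  }
  invisible(json_path)
}
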