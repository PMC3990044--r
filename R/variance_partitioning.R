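#' Partition cross-infection variance into random-effects components
#'
#' Fits the balanced two-way random-effects model
#' `y_ghr = mu + A_g + B_h + (AB)_gh + e_ghr` to the per-cell infection
#' counts of a reciprocal cross-infection table, treating host and parasite
#' isolates as random factors, and solves the expected-mean-squares (EMS)
#' equations for the variance components:
#' \deqn{\hat\sigma^2_e = MS_E,\quad
#'       \hat\sigma^2_{G\times G} = (MS_{AB} - MS_E)/n,\quad
#'       \hat\sigma^2_{host} = (MS_A - MS_{AB})/(bn),\quad
#'       \hat\sigma^2_{parasite} = (MS_B - MS_{AB})/(an),}
#' where a and b are the isolate counts and n the replicate count. Negative
#' method-of-moments solutions are truncated to zero in `sigma2`; the
#' untruncated values are kept in `sigma2_raw`.
#'
#' The interaction component `sigma2_gxg` is the experiment's estimate of
#' statistical G-by-G. Isolates sharing a latent genotype are still distinct
#' factor levels — the analyst cannot know genotypes, only isolates.
#'
#' @param table a `cross_infection_table` (balanced, complete factorial,
#'   `replicates >= 2`).
#' @param response `"count"` (default) analyzes the per-cell infection count
#'   in 0..trials; `"binary"` expands each trial to a 0/1 outcome, so the
#'   error stratum then holds `replicates * trials - 1` df per cell.
#' @param method `"EMS"` (closed-form, default) or `"REML"`
#'   (via \pkg{lme4}, offered as a cross-check).
#' @return An object of class `variance_components`: list with `sigma2`
#'   (named vector host/parasite/gxg/error, truncated at 0), `sigma2_raw`,
#'   `mean_squares`, `df`, `method`, `generation`.
#' @export
anova_decompose <- function(table, response = c("count", "binary"),
                            method = c("EMS", "REML")) {
  response <- match.arg(response)
  method <- match.arg(method)
  df <- as.data.frame(table)
  a <- length(unique(df$host_isolate))
  b <- length(unique(df$parasite_isolate))
  t <- df$trials[1]

  if (response == "binary") {
    ## one 0/1 row per trial; trial index folded into the replicate stratum
    idx <- rep(seq_len(nrow(df)), each = t)
    succ <- sequence(rep(t, nrow(df))) <= df$infections[idx]
    df <- data.frame(host_isolate = df$host_isolate[idx],
                     parasite_isolate = df$parasite_isolate[idx],
                     replicate = (df$replicate[idx] - 1L) * t +
                       sequence(rep(t, nrow(df))),
                     infections = as.numeric(succ))
  }
  n <- length(unique(df$replicate))
  if (n < 2) stop("replicates must be >= 2 to estimate the error stratum")
  if (nrow(df) != a * b * n) {
    stop("table must be a complete balanced factorial")
  }

  if (method == "REML") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("method = 'REML' requires the lme4 package")
    }
    fit <- lme4::lmer(
      infections ~ 1 + (1 | host_isolate) + (1 | parasite_isolate) +
        (1 | host_isolate:parasite_isolate),
      data = transform(df,
                       host_isolate = factor(host_isolate),
                       parasite_isolate = factor(parasite_isolate)),
      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) vc$vcov[match(g, vc$grp)]
    s2 <- c(host = get("host_isolate"), parasite = get("parasite_isolate"),
            gxg = get("host_isolate:parasite_isolate"),
            error = get("Residual"))
    return(structure(list(sigma2 = pmax(s2, 0), sigma2_raw = s2,
                          mean_squares = NULL, df = NULL, method = "REML",
                          generation = attr(table, "generation")),
                     class = "variance_components"))
  }

  y <- df$infections
  grand <- mean(y)
  ## balanced closed-form sums of squares from the marginal cell means
  mean_A <- tapply(y, df$host_isolate, mean)
  mean_B <- tapply(y, df$parasite_isolate, mean)
  mean_AB <- tapply(y, list(df$host_isolate, df$parasite_isolate), mean)
  ss_A <- b * n * sum((mean_A - grand)^2)
  ss_B <- a * n * sum((mean_B - grand)^2)
  ss_AB <- n * sum((mean_AB - outer(mean_A, rep(1, b)) -
                      outer(rep(1, a), mean_B) + grand)^2)
  cell_of <- mean_AB[cbind(as.character(df$host_isolate),
                           as.character(df$parasite_isolate))]
  ss_E <- sum((y - cell_of)^2)

  dfs <- c(host = a - 1, parasite = b - 1, gxg = (a - 1) * (b - 1),
           error = a * b * (n - 1))
  ms <- c(host = ss_A / dfs[["host"]],
          parasite = ss_B / dfs[["parasite"]],
          gxg = ss_AB / dfs[["gxg"]],
          error = ss_E / dfs[["error"]])
  s2 <- c(host = (ms[["host"]] - ms[["gxg"]]) / (b * n),
          parasite = (ms[["parasite"]] - ms[["gxg"]]) / (a * n),
          gxg = (ms[["gxg"]] - ms[["error"]]) / n,
          error = ms[["error"]])
  structure(list(sigma2 = pmax(s2, 0), sigma2_raw = s2,
                 mean_squares = ms, df = dfs, method = "EMS",
                 generation = attr(table, "generation")),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$method, ")\n", sep = "")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' Expected variance components for a design and population (analytic)
#'
#' Infinite-sample oracle used for validation: maps the frequency-weighted
#' decomposition of the infection matrix (see
#' [interaction_variance_components()]) onto the count scale of a given
#' design. With isolates drawn i.i.d. from genotype frequencies (p, q), the
#' per-cell mean count for a host of genotype i and parasite of genotype j
#' is `t * pi'_ij` (t trials, error-adjusted probability), so the expected
#' host/parasite/interaction components are the decomposition variances of
#' the matrix `t * pi'`, and the error component is the average within-cell
#' binomial variance `sum_ij p_i q_j t pi'_ij (1 - pi'_ij)`.
#'
#' @param alpha an [infection_matrix()] or probability matrix.
#' @param p,q genotype frequency vectors.
#' @param design an [experiment_design()].
#' @return a `variance_components` object with `method = "analytic"`.
#' @export
expected_components <- function(alpha, p, q, design = experiment_design()) {
  A <- as_alpha(alpha)
  t <- design$trials_per_cell
  Aadj <- adjust_error(A, design$error_rate)
  dec <- interaction_variance_components(t * Aadj, p, q)
  err <- sum(outer(p, q) * (t * Aadj * (1 - Aadj)))
  s2 <- c(host = dec$var_host, parasite = dec$var_parasite,
          gxg = dec$var_interaction, error = err)
  structure(list(sigma2 = s2, sigma2_raw = s2, mean_squares = NULL,
                 df = NULL, method = "analytic", generation = NA_integer_),
            class = "variance_components")
}

#' Variance-component time series across a longitudinal survey
#'
#' Applies [anova_decompose()] to each table of a survey and stacks the
#' results into one CSV-writable data.frame — the right-hand panel of a
#' coevolution figure: statistical G-by-G waxing and waning as genotype
#' frequencies cycle.
#'
#' @param tables non-empty list of `cross_infection_table` (e.g. from
#'   [longitudinal_survey()]).
#' @param ... passed to [anova_decompose()].
#' @return data.frame with columns `generation`, `sigma2_host`,
#'   `sigma2_parasite`, `sigma2_gxg`, `sigma2_error`, the raw (untruncated)
#'   components, mean squares and degrees of freedom.
#' @export
component_timeseries <- function(tables, ...) {
  if (length(tables) == 0) stop("tables must be a non-empty list")
  rows <- lapply(tables, function(tab) {
    vc <- anova_decompose(tab, ...)
    out <- data.frame(
      generation = if (is.null(vc$generation) || is.na(vc$generation))
        NA_integer_ else vc$generation,
      sigma2_host = vc$sigma2[["host"]],
      sigma2_parasite = vc$sigma2[["parasite"]],
      sigma2_gxg = vc$sigma2[["gxg"]],
      sigma2_error = vc$sigma2[["error"]],
      sigma2_host_raw = vc$sigma2_raw[["host"]],
      sigma2_parasite_raw = vc$sigma2_raw[["parasite"]],
      sigma2_gxg_raw = vc$sigma2_raw[["gxg"]])
    if (!is.null(vc$mean_squares)) {
      out <- cbind(out,
                   ms_host = vc$mean_squares[["host"]],
                   ms_parasite = vc$mean_squares[["parasite"]],
                   ms_gxg = vc$mean_squares[["gxg"]],
                   ms_error = vc$mean_squares[["error"]],
                   df_host = vc$df[["host"]],
                   df_parasite = vc$df[["parasite"]],
                   df_gxg = vc$df[["gxg"]],
                   df_error = vc$df[["error"]])
    }
    out
  })
  do.call(rbind, rows)
}
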