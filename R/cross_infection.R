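#' Design of a reciprocal cross-infection experiment
#'
#' Defaults follow the simulated empirical design of the study: every 20
#' generations, 30 host and 30 parasite isolates are sampled at random from
#' the populations and challenged in a full factorial; each host x parasite
#' pair receives 5 trial exposures, and the whole factorial is replicated 5
#' times.
#'
#' @param n_isolates_host,n_isolates_parasite isolates sampled per species.
#' @param trials_per_cell exposures per host x parasite x replicate cell.
#' @param replicates independent repeats of the full factorial (the
#'   within-cell error stratum of the ANOVA).
#' @param sampling_interval generations between successive experiments in a
#'   longitudinal survey.
#' @param error_rate probability `epsilon` that a single infection outcome is
#'   recorded flipped (0 <= epsilon < 0.5). With a 0/1 infection matrix,
#'   epsilon = 0 gives deterministic cells.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_isolates_host = 30, n_isolates_parasite = 30,
                              trials_per_cell = 5, replicates = 5,
                              sampling_interval = 20, error_rate = 0) {
  stopifnot(n_isolates_host >= 1, n_isolates_parasite >= 1,
            trials_per_cell >= 1, replicates >= 1, sampling_interval >= 1,
            error_rate >= 0, error_rate < 0.5)
  structure(list(n_isolates_host = as.integer(n_isolates_host),
                 n_isolates_parasite = as.integer(n_isolates_parasite),
                 trials_per_cell = as.integer(trials_per_cell),
                 replicates = as.integer(replicates),
                 sampling_interval = as.integer(sampling_interval),
                 error_rate = error_rate),
            class = "experiment_design")
}

#' Sample isolate genotypes from a population
#'
#' Draws `n` isolates independently from the genotype frequency distribution
#' (sampling with replacement — the infinite-population approximation of
#' picking a few dozen individuals out of 100,000). Rare genotypes are
#' frequently missed: with frequencies (0.99, 0.01) and n = 30, the rare
#' genotype is absent from the sample with probability 0.99^30 ~ 0.74 — the
#' sampling-error mechanism that erodes statistical G-by-G.
#'
#' @param state a [population_state()], or a bare frequency vector.
#' @param n number of isolates.
#' @param species `"host"` or `"parasite"` (which frequency vector to use
#'   when `state` is a `population_state`).
#' @return integer vector of latent genotype indices, length `n`.
#' @export
sample_isolates <- function(state, n, species = c("host", "parasite")) {
  freqs <- if (inherits(state, "population_state")) {
    species <- match.arg(species)
    if (species == "host") state$p else state$q
  } else {
    check_simplex(state, "frequencies")
  }
  sample.int(length(freqs), n, replace = TRUE, prob = freqs)
}

## epsilon-adjusted infection probability
adjust_error <- function(pi, eps) pi * (1 - eps) + (1 - pi) * eps

#' Simulate a reciprocal cross-infection experiment
#'
#' Challenges every sampled host isolate against every sampled parasite
#' isolate. For host isolate g (latent genotype i) and parasite isolate h
#' (latent genotype j), the infection count in one replicate is
#' `Binomial(trials_per_cell, pi')` with
#' `pi' = alpha[i, j] (1 - eps) + (1 - alpha[i, j]) eps`.
#' The latent genotypes are carried as attributes for validation but are
#' never used by the statistical modules.
#'
#' @param host_isolates,parasite_isolates integer genotype vectors from
#'   [sample_isolates()].
#' @param alpha an [infection_matrix()] or probability matrix.
#' @param design an [experiment_design()].
#' @param generation generation label recorded with the table (optional).
#' @return A `cross_infection_table`: a data.frame with columns
#'   `host_isolate`, `parasite_isolate`, `replicate`, `infections`, `trials`
#'   (one row per cell x replicate, full factorial), with attributes
#'   `host_genotypes`, `parasite_genotypes`, `design`, `generation`.
#' @export
run_cross_infection <- function(host_isolates, parasite_isolates, alpha,
                                design = experiment_design(),
                                generation = NA_integer_) {
  stopifnot(length(host_isolates) >= 1, length(parasite_isolates) >= 1)
  A <- as_alpha(alpha)
  G <- length(host_isolates)
  H <- length(parasite_isolates)
  R <- design$replicates
  t <- design$trials_per_cell
  grid <- expand.grid(host_isolate = seq_len(G),
                      parasite_isolate = seq_len(H),
                      replicate = seq_len(R))
  pi <- A[cbind(host_isolates[grid$host_isolate],
                parasite_isolates[grid$parasite_isolate])]
  pi_adj <- adjust_error(pi, design$error_rate)
  grid$infections <- stats::rbinom(nrow(grid), t, pi_adj)
  grid$trials <- t
  structure(grid,
            class = c("cross_infection_table", "data.frame"),
            host_genotypes = as.integer(host_isolates),
            parasite_genotypes = as.integer(parasite_isolates),
            design = design,
            generation = as.integer(generation))
}

#' @export
print.cross_infection_table <- function(x, ...) {
  d <- attr(x, "design")
  cat("Cross-infection table:", d$n_isolates_host, "x",
      d$n_isolates_parasite, "isolates,", d$replicates, "replicates of",
      d$trials_per_cell, "trials per cell")
  g <- attr(x, "generation")
  if (!is.na(g)) cat(", generation", g)
  cat("\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Longitudinal survey of cross-infection experiments along a trajectory
#'
#' Runs one full cross-infection experiment (fresh isolate samples, fresh
#' binomial draws) at every `sampling_interval`-th generation of a
#' simulation, inclusive of generation 0 and of the final generation when it
#' falls on the grid.
#'
#' @param trajectory a `coev_trajectory` from [run_simulation()].
#' @param design an [experiment_design()].
#' @return list of `cross_infection_table`, one per sampled generation.
#' @export
longitudinal_survey <- function(trajectory, design = experiment_design()) {
  G <- nrow(trajectory$p) - 1L
  if (design$sampling_interval > G) {
    stop("sampling_interval (", design$sampling_interval,
         ") exceeds trajectory length (", G, ")")
  }
  alpha <- trajectory$params$model
  lapply(seq(0L, G, by = design$sampling_interval), function(gen) {
    st <- state_at(trajectory, gen)
    hosts <- sample_isolates(st, design$n_isolates_host, "host")
    paras <- sample_isolates(st, design$n_isolates_parasite, "parasite")
    run_cross_infection(hosts, paras, alpha, design, generation = gen)
  })
}

#' Write / read a cross-infection table as CSV
#'
#' The main CSV holds the observable data only (`host_isolate`,
#' `parasite_isolate`, `replicate`, `infections`, `trials`). The latent
#' isolate genotypes — known to the simulator but hidden from any analyst —
#' can be written to a separate truth CSV that inference code never reads.
#'
#' @param x a `cross_infection_table`.
#' @param path CSV path for the observable table.
#' @param truth_path optional CSV path for the latent genotypes.
#' @return `write_cross_infection_table` returns `path` invisibly;
#'   `read_cross_infection_table` returns a `cross_infection_table` (without
#'   latent genotypes).
#' @export
write_cross_infection_table <- function(x, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(x)[, c("host_isolate", "parasite_isolate",
                                        "replicate", "infections", "trials")],
                   path, row.names = FALSE)
  if (!is.null(truth_path)) {
    hg <- attr(x, "host_genotypes")
    pg <- attr(x, "parasite_genotypes")
    truth <- rbind(
      data.frame(species = "host", isolate = seq_along(hg), genotype = hg),
      data.frame(species = "parasite", isolate = seq_along(pg),
                 genotype = pg))
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cross_infection_table
#' @export
read_cross_infection_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("host_isolate", "parasite_isolate", "replicate", "infections",
            "trials")
  if (!all(need %in% names(df))) {
    stop("cross-infection CSV must have columns: ",
         paste(need, collapse = ", "))
  }
  t <- unique(df$trials)
  if (length(t) != 1L) stop("all cells must share the same trial count")
  design <- experiment_design(
    n_isolates_host = max(df$host_isolate),
    n_isolates_parasite = max(df$parasite_isolate),
    trials_per_cell = t,
    replicates = max(df$replicate))
  structure(df[need],
            class = c("cross_infection_table", "data.frame"),
            host_genotypes = NULL, parasite_genotypes = NULL,
            design = design, generation = NA_integer_)
}
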