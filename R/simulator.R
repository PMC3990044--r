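#' Parameters for a coevolution simulation
#'
#' Bundles everything one run of the discrete-generation host-parasite
#' coevolution model needs. Defaults reproduce the strong-coevolution
#' matching-alleles configuration of the simulation study: populations of
#' 100,000 individuals in each species, symmetric mutation at 1e-5 per
#' generation, three genotypes per species, infection costs s_h = 0.67 for
#' hosts and s_p = 0.69 for parasites, 1000 generations.
#'
#' `selection = FALSE` sets the fitness effects of infection (and of
#' resistance/virulence costs) to zero — the no-coevolution control.
#' `drift = FALSE` runs the deterministic recursion (infinite-population
#' limit); with drift on, genotype counts are resampled each generation as a
#' multinomial draw of size `N`.
#'
#' @param N population size of each species.
#' @param mu per-generation symmetric mutation rate (a mutating allele
#'   becomes each of the other K - 1 genotypes with equal probability).
#' @param K number of genotypes per species.
#' @param s_h fitness cost of infection to the host.
#' @param s_p fitness cost to the parasite of failing to infect.
#' @param tau_h,tau_p per-level multiplicative costs of resistance and
#'   virulence (used by the gene-for-gene model's cost exponents; irrelevant
#'   when all cost exponents are 0).
#' @param model an [infection_matrix()]; default `infection_matrix("MA", K)`.
#' @param generations number of generations to iterate.
#' @param seed integer RNG seed recorded with the run; `NULL` leaves the RNG
#'   stream untouched.
#' @param drift logical, multinomial resampling of size `N` each generation.
#' @param selection logical, apply coevolutionary selection.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(N = 100000, mu = 1e-5, K = 3,
                       s_h = 0.67, s_p = 0.69,
                       tau_h = 0, tau_p = 0,
                       model = infection_matrix("MA", K),
                       generations = 1000, seed = NULL,
                       drift = TRUE, selection = TRUE) {
  stopifnot(N >= 1, N == round(N),
            mu >= 0, mu <= 1,
            s_h >= 0, s_h <= 1, s_p >= 0, s_p <= 1,
            tau_h >= 0, tau_h <= 1, tau_p >= 0, tau_p <= 1,
            generations >= 1,
            inherits(model, "infection_matrix"))
  if (nrow(model$alpha) != K || ncol(model$alpha) != K) {
    stop("model matrix must be K x K")
  }
  structure(list(N = as.integer(N), mu = mu, K = as.integer(K),
                 s_h = s_h, s_p = s_p, tau_h = tau_h, tau_p = tau_p,
                 model = model, generations = as.integer(generations),
                 seed = seed, drift = isTRUE(drift),
                 selection = isTRUE(selection)),
            class = "sim_params")
}

#' A population state: host and parasite genotype frequencies
#'
#' @param p,q host and parasite genotype frequency vectors (each summing
#'   to 1).
#' @param generation generation counter.
#' @return An object of class `population_state`.
#' @export
population_state <- function(p, q, generation = 0L) {
  check_simplex(p, "p", tol = 1e-9)
  check_simplex(q, "q", tol = 1e-9)
  structure(list(generation = as.integer(generation),
                 p = as.numeric(p), q = as.numeric(q)),
            class = "population_state")
}

#' Host and parasite fitness under the mean-field encounter model
#'
#' Each host of genotype i meets the parasite population in proportion to
#' its genotype frequencies, so its expected infection probability is
#' `sum_j q_j alpha[i, j]` and
#' \deqn{w_h[i] = (1 - s_h \sum_j q_j \alpha_{ij}) (1 - \tau_h)^{r_i},}
#' and symmetrically the parasite is penalized for failing to infect:
#' \deqn{w_p[j] = (1 - s_p \sum_i p_i (1 - \alpha_{ij})) (1 - \tau_p)^{v_j}.}
#' With `selection = FALSE` both vectors are all ones.
#'
#' @param state a [population_state()].
#' @param params a [sim_params()].
#' @return list with numeric vectors `w_host` and `w_parasite`, all entries
#'   in \[0, 1\].
#' @export
fitness_vectors <- function(state, params) {
  K <- params$K
  if (!params$selection) {
    return(list(w_host = rep(1, K), w_parasite = rep(1, K)))
  }
  A <- params$model$alpha
  r <- params$model$host_cost_exponents
  v <- params$model$parasite_cost_exponents
  w_h <- (1 - params$s_h * as.numeric(A %*% state$q)) *
    (1 - params$tau_h)^r
  w_p <- (1 - params$s_p * as.numeric(state$p %*% (1 - A))) *
    (1 - params$tau_p)^v
  stopifnot(all(w_h >= 0), all(w_p >= 0))
  list(w_host = w_h, w_parasite = w_p)
}

## selection -> mutation (-> drift) on one frequency vector
advance_freqs <- function(freq, w, params) {
  if (params$selection) {
    wm <- sum(freq * w)
    if (wm <= 0) stop("mean fitness is zero; population inviable")
    freq <- freq * w / wm
  }
  K <- params$K
  mu <- params$mu
  freq <- (1 - mu) * freq + mu * (1 - freq) / (K - 1)
  if (params$drift) {
    counts <- stats::rmultinom(1, params$N, freq)[, 1]
    freq <- counts / params$N
  } else {
    freq[freq < 0 & freq > -1e-12] <- 0
    freq <- freq / sum(freq)
  }
  freq
}

#' Advance a population state by one generation
#'
#' Applies, in order: coevolutionary selection (frequencies reweighted by
#' fitness and renormalized), symmetric mutation, and — if enabled — genetic
#' drift as one multinomial draw of `N` individuals per species.
#'
#' @inheritParams fitness_vectors
#' @return the [population_state()] one generation later.
#' @export
step_population <- function(state, params) {
  w <- fitness_vectors(state, params)
  population_state(advance_freqs(state$p, w$w_host, params),
                   advance_freqs(state$q, w$w_parasite, params),
                   generation = state$generation + 1L)
}

## uniform frequencies plus a small seeded perturbation so deterministic
## runs leave the unstable symmetric equilibrium
default_initial_state <- function(K, magnitude = 0.01) {
  perturb <- function() {
    d <- stats::runif(K, -magnitude, magnitude)
    d <- d - mean(d)
    f <- 1 / K + d
    f <- pmax(f, 0)
    f / sum(f)
  }
  population_state(perturb(), perturb(), generation = 0L)
}

#' Run a coevolution simulation
#'
#' Iterates [step_population()] for `params$generations` generations and
#' records the full genotype-frequency trajectory. The run is deterministic
#' given `params$seed`: the seed drives the initial perturbation and (when
#' drift is on) every multinomial draw.
#'
#' @param params a [sim_params()].
#' @param init optional [population_state()] to start from; by default
#'   uniform frequencies 1/K plus a seeded perturbation of magnitude 0.01.
#' @return An object of class `coev_trajectory`: a list with matrices `p`
#'   and `q` of dimension (generations + 1) x K (row g + 1 holds generation
#'   g) and the `params` used.
#' @export
run_simulation <- function(params, init = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- if (is.null(init)) default_initial_state(params$K) else init
  G <- params$generations
  K <- params$K
  P <- matrix(NA_real_, G + 1L, K)
  Q <- matrix(NA_real_, G + 1L, K)
  P[1L, ] <- state$p
  Q[1L, ] <- state$q
  for (g in seq_len(G)) {
    state <- step_population(state, params)
    P[g + 1L, ] <- state$p
    Q[g + 1L, ] <- state$q
  }
  colnames(P) <- paste0("H", seq_len(K))
  colnames(Q) <- paste0("P", seq_len(K))
  structure(list(p = P, q = Q, params = params), class = "coev_trajectory")
}

#' @export
print.coev_trajectory <- function(x, ...) {
  cat("Coevolution trajectory:", nrow(x$p) - 1L, "generations,",
      x$params$K, "genotypes,", x$params$model$model_name, "model\n")
  invisible(x)
}

#' Extract the population state at one generation of a trajectory
#'
#' @param trajectory a `coev_trajectory` from [run_simulation()].
#' @param generation generation to extract (0-based, inclusive of 0).
#' @return a [population_state()].
#' @export
state_at <- function(trajectory, generation) {
  n <- nrow(trajectory$p) - 1L
  if (generation < 0 || generation > n) {
    stop("generation must be in 0..", n)
  }
  population_state(trajectory$p[generation + 1L, ],
                   trajectory$q[generation + 1L, ],
                   generation = generation)
}

#' @export
as.data.frame.coev_trajectory <- function(x, ...) {
  K <- x$params$K
  gens <- 0:(nrow(x$p) - 1L)
  rbind(
    data.frame(generation = rep(gens, K),
               species = "host",
               genotype = rep(seq_len(K), each = length(gens)),
               frequency = as.vector(x$p)),
    data.frame(generation = rep(gens, K),
               species = "parasite",
               genotype = rep(seq_len(K), each = length(gens)),
               frequency = as.vector(x$q)))
}

#' Write a trajectory to CSV (with a JSON parameter sidecar)
#'
#' Columns: `generation`, `species`, `genotype`, `frequency`. Parameters
#' (including the seed and the infection matrix) are echoed to the sidecar
#' `<path>.json`.
#'
#' @param trajectory a `coev_trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  p <- trajectory$params
  meta <- list(N = p$N, mu = p$mu, K = p$K, s_h = p$s_h, s_p = p$s_p,
               tau_h = p$tau_h, tau_p = p$tau_p,
               model = p$model$model_name,
               alpha = p$model$alpha,
               generations = p$generations, seed = p$seed,
               drift = p$drift, selection = p$selection)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
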