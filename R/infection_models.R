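#' Build a functional genotype-by-genotype infection matrix
#'
#' Constructs the K_h x K_p matrix of infection probabilities `alpha` that
#' encodes a functional model of host-parasite infection genetics, together
#' with its fitness-cost structure. Supported models:
#'
#' * `"MA"` (matching alleles): a parasite infects only the host genotype it
#'   matches; `alpha` is the identity matrix.
#' * `"IMA"` (inverse matching alleles): a genotype match triggers host
#'   recognition and defense; infection succeeds everywhere except the
#'   diagonal.
#' * `"GFG"` (gene-for-gene, nested multi-level form): host genotype i carries
#'   resistance level r_i = i - 1 and parasite genotype j virulence level
#'   v_j = j - 1; infection succeeds iff v_j >= r_i. Resistance and virulence
#'   levels carry multiplicative fitness costs (see [fitness_vectors()]).
#' * `"CONST"`: every entry equals `c`; no genotype dependence at all.
#' * `"ADDITIVE"`: `alpha[i, j] = clamp(beta[i] + gamma[j], 0, 1)`; host and
#'   parasite main effects but (before clamping) no interaction.
#'
#' `CONST` and `ADDITIVE` are the no-functional-G-by-G controls: their
#' interaction variance is zero for every genotype-frequency vector
#' (exactly for `CONST`, and for `ADDITIVE` whenever no entry is clamped).
#'
#' @param model_name one of `"MA"`, `"IMA"`, `"GFG"`, `"CONST"`, `"ADDITIVE"`.
#' @param K number of genotypes per species (>= 2).
#' @param c constant infection probability for `CONST` (default 0.5).
#' @param beta,gamma numeric vectors of length `K` of host and parasite
#'   additive effects (required for `ADDITIVE`).
#' @return An object of class `infection_matrix`: a list with elements
#'   `alpha` (K x K numeric matrix in \[0, 1\]), `model_name`,
#'   `host_cost_exponents` (integer resistance levels r_i, 0 for non-GFG) and
#'   `parasite_cost_exponents` (virulence levels v_j, 0 for non-GFG).
#' @examples
#' infection_matrix("MA", 3)
#' infection_matrix("GFG", 3)$alpha
#' @export
infection_matrix <- function(model_name, K,
                             c = 0.5, beta = NULL, gamma = NULL) {
  valid <- c("MA", "IMA", "GFG", "CONST", "ADDITIVE")
  if (!is.character(model_name) || length(model_name) != 1L ||
      !model_name %in% valid) {
    stop("unknown model '", paste(model_name, collapse = ","),
         "'; valid models are: ", paste(valid, collapse = ", "))
  }
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K)) {
    stop("K must be a single integer >= 2")
  }
  K <- as.integer(K)
  r <- integer(K)
  v <- integer(K)
  alpha <- switch(model_name,
    MA = diag(1, K),
    IMA = 1 - diag(1, K),
    GFG = {
      r <- 0:(K - 1L)
      v <- 0:(K - 1L)
      outer(r, v, function(ri, vj) as.numeric(vj >= ri))
    },
    CONST = {
      if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 1) {
        stop("CONST requires a single probability c in [0, 1]")
      }
      matrix(c, K, K)
    },
    ADDITIVE = {
      if (is.null(beta) || is.null(gamma) ||
          length(beta) != K || length(gamma) != K) {
        stop("ADDITIVE requires beta and gamma vectors of length K")
      }
      pmin(pmax(outer(beta, gamma, `+`), 0), 1)
    }
  )
  dimnames(alpha) <- list(host = paste0("H", seq_len(K)),
                          parasite = paste0("P", seq_len(K)))
  structure(
    list(alpha = alpha, model_name = model_name,
         host_cost_exponents = r, parasite_cost_exponents = v),
    class = "infection_matrix")
}

#' @export
print.infection_matrix <- function(x, ...) {
  cat("Infection matrix (", x$model_name, "), ",
      nrow(x$alpha), " host x ", ncol(x$alpha), " parasite genotypes\n",
      sep = "")
  print(x$alpha)
  if (any(x$host_cost_exponents != 0) || any(x$parasite_cost_exponents != 0)) {
    cat("resistance levels r:", x$host_cost_exponents,
        "  virulence levels v:", x$parasite_cost_exponents, "\n")
  }
  invisible(x)
}

## accept an infection_matrix or a bare probability matrix
as_alpha <- function(alpha) {
  if (inherits(alpha, "infection_matrix")) alpha <- alpha$alpha
  alpha <- as.matrix(alpha)
  if (any(alpha < 0 | alpha > 1)) stop("alpha entries must lie in [0, 1]")
  alpha
}

check_simplex <- function(x, name, tol = 1e-8) {
  if (any(x < 0)) stop(name, " must be non-negative")
  if (abs(sum(x) - 1) > tol) {
    stop(name, " must sum to 1 (got ", format(sum(x)), ")")
  }
  invisible(x)
}

#' Frequency-weighted two-way decomposition of an infection matrix
#'
#' Decomposes an infection matrix `alpha` under host genotype frequencies
#' `p` and parasite frequencies `q` into a grand mean, host and parasite
#' main effects and a pure interaction term:
#' \deqn{\mu = \sum_{ij} p_i q_j \alpha_{ij},\quad
#'       a_i = \sum_j q_j \alpha_{ij} - \mu,\quad
#'       b_j = \sum_i p_i \alpha_{ij} - \mu,\quad
#'       e_{ij} = \alpha_{ij} - \mu - a_i - b_j.}
#' The reported variances are the frequency-weighted second moments of each
#' term (e.g. interaction variance \eqn{\sum_{ij} p_i q_j e_{ij}^2}). This is
#' the population-level quantity that a factorial cross-infection experiment
#' estimates: it depends on the genotype frequencies, not just on `alpha`,
#' which is why statistical G-by-G can vanish while functional G-by-G is
#' strong.
#'
#' @param alpha an [infection_matrix()] or plain probability matrix.
#' @param p,q host and parasite genotype frequency vectors (non-negative,
#'   summing to 1).
#' @return A list with `grand_mean`, `var_host`, `var_parasite`,
#'   `var_interaction`, and the effect vectors/matrix `a`, `b`, `e`.
#'   The decomposition is exact: `grand_mean + a[i] + b[j] + e[i, j]`
#'   reconstructs `alpha[i, j]`, and the weighted main effects average to 0.
#' @examples
#' m <- infection_matrix("MA", 2)
#' interaction_variance_components(m, c(0.5, 0.5), c(0.5, 0.5))$var_interaction
#' @export
interaction_variance_components <- function(alpha, p, q) {
  ## the decomposition itself is scale-free: accept any numeric matrix
  ## (e.g. count-scale t * alpha), not just probabilities
  A <- if (inherits(alpha, "infection_matrix")) alpha$alpha
       else as.matrix(alpha)
  check_simplex(p, "p")
  check_simplex(q, "q")
  if (length(p) != nrow(A) || length(q) != ncol(A)) {
    stop("frequency vectors must match the matrix dimensions")
  }
  mu <- as.numeric(p %*% A %*% q)
  a <- as.numeric(A %*% q) - mu
  b <- as.numeric(p %*% A) - mu
  e <- A - mu - outer(a, rep(1, length(q))) - outer(rep(1, length(p)), b)
  w <- outer(p, q)
  list(grand_mean = mu,
       var_host = sum(p * a^2),
       var_parasite = sum(q * b^2),
       var_interaction = sum(w * e^2),
       a = a, b = b, e = e)
}

#' Write / read an infection matrix as CSV
#'
#' The CSV has parasite genotype labels as the header row and host genotype
#' labels in the first column. Model name and cost exponents travel in a JSON
#' sidecar written next to the CSV (same path with extension `.json`).
#'
#' @param x an [infection_matrix()].
#' @param path CSV file path.
#' @return `write_infection_matrix` returns `path` invisibly;
#'   `read_infection_matrix` returns an `infection_matrix`.
#' @export
write_infection_matrix <- function(x, path) {
  stopifnot(inherits(x, "infection_matrix"))
  df <- data.frame(host = rownames(x$alpha), x$alpha, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model_name = x$model_name,
               host_cost_exponents = x$host_cost_exponents,
               parasite_cost_exponents = x$parasite_cost_exponents)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_infection_matrix
#' @export
read_infection_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  alpha <- as.matrix(df[, -1, drop = FALSE])
  rownames(alpha) <- df[[1]]
  names(dimnames(alpha)) <- c("host", "parasite")
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(model_name = "CUSTOM",
         host_cost_exponents = integer(nrow(alpha)),
         parasite_cost_exponents = integer(ncol(alpha)))
  }
  structure(
    list(alpha = alpha, model_name = meta$model_name,
         host_cost_exponents = as.integer(meta$host_cost_exponents),
         parasite_cost_exponents = as.integer(meta$parasite_cost_exponents)),
    class = "infection_matrix")
}
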