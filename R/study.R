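#' Default scenario set for the in-silico cross-infection study
#'
#' Strong and moderate coevolution for each functional model (matching
#' alleles, inverse matching alleles, gene-for-gene), plus the two controls:
#' a `CONST` matrix (no functional G-by-G, hence no coevolution however
#' strong selection is) and a selection-off run (functional G-by-G present,
#' fitness effects of infection set to zero). Strong selection is
#' s_h = 0.67, s_p = 0.69 with GFG costs tau_h = 0.12, tau_p = 0.09;
#' moderate selection is s_h = 0.37, s_p = 0.39 with tau_h = 0.08,
#' tau_p = 0.05.
#'
#' @return named list of scenario descriptions.
#' @export
default_scenarios <- function() {
  list(
    ma_strong = list(model = "MA", s_h = 0.67, s_p = 0.69,
                     tau_h = 0, tau_p = 0, selection = TRUE),
    ma_moderate = list(model = "MA", s_h = 0.37, s_p = 0.39,
                       tau_h = 0, tau_p = 0, selection = TRUE),
    ima_strong = list(model = "IMA", s_h = 0.67, s_p = 0.69,
                      tau_h = 0, tau_p = 0, selection = TRUE),
    ima_moderate = list(model = "IMA", s_h = 0.37, s_p = 0.39,
                        tau_h = 0, tau_p = 0, selection = TRUE),
    gfg_strong = list(model = "GFG", s_h = 0.67, s_p = 0.69,
                      tau_h = 0.12, tau_p = 0.09, selection = TRUE),
    gfg_moderate = list(model = "GFG", s_h = 0.37, s_p = 0.39,
                        tau_h = 0.08, tau_p = 0.05, selection = TRUE),
    const_control = list(model = "CONST", s_h = 0.67, s_p = 0.69,
                         tau_h = 0, tau_p = 0, selection = TRUE),
    no_selection = list(model = "MA", s_h = 0.67, s_p = 0.69,
                        tau_h = 0, tau_p = 0, selection = FALSE))
}

scenario_fields <- c("model", "s_h", "s_p", "tau_h", "tau_p", "selection")
config_fields <- c("seed", "N", "mu", "K", "generations", "drift",
                   "design", "scenarios", "analyses", "out_dir")

#' Configure the full simulation study
#'
#' One configuration drives every scenario of the study: simulate
#' coevolution, survey it with cross-infection experiments, and partition
#' the outcome variance (optionally also run likelihood-based model
#' comparison on the final experiment of each scenario). Per-scenario RNG
#' seeds are derived deterministically from the master seed.
#'
#' @param seed master seed.
#' @param N,mu,K,generations,drift simulation settings shared across
#'   scenarios (see [sim_params()]).
#' @param design an [experiment_design()].
#' @param scenarios named list of scenario descriptions, each with fields
#'   `model`, `s_h`, `s_p`, `tau_h`, `tau_p`, `selection` (see
#'   [default_scenarios()]).
#' @param analyses character subset of `c("anova", "likelihood")`.
#' @param out_dir optional output directory; when set, [run_study()] writes
#'   CSV/JSON outputs there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1, N = 100000, mu = 1e-5, K = 3,
                         generations = 1000, drift = TRUE,
                         design = experiment_design(),
                         scenarios = default_scenarios(),
                         analyses = "anova", out_dir = NULL) {
  if (is.null(names(scenarios)) || anyDuplicated(names(scenarios))) {
    stop("scenarios must be a uniquely named list")
  }
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    bad <- setdiff(names(sc), scenario_fields)
    if (length(bad)) {
      stop("invalid scenario keys in '", nm, "': ",
           paste(bad, collapse = ", "),
           "; valid keys are: ", paste(scenario_fields, collapse = ", "))
    }
    miss <- setdiff("model", names(sc))
    if (length(miss)) stop("scenario '", nm, "' needs a 'model' field")
  }
  if (!all(analyses %in% c("anova", "likelihood"))) {
    stop("analyses must be a subset of: anova, likelihood")
  }
  structure(list(seed = as.integer(seed), N = N, mu = mu, K = as.integer(K),
                 generations = as.integer(generations), drift = drift,
                 design = design, scenarios = scenarios,
                 analyses = analyses, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [study_config()]; `design` is a
#' mapping with [experiment_design()] fields and `scenarios` a mapping of
#' scenario name to scenario fields. Unknown keys raise an error naming the
#' valid schema.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ## YAML 1.1 reads a bare key `N` as boolean; map it back
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "N"
  bad <- setdiff(names(raw), config_fields)
  if (length(bad)) {
    stop("invalid config keys: ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(config_fields, collapse = ", "))
  }
  if (!is.null(raw$design)) raw$design <- do.call(experiment_design,
                                                  raw$design)
  do.call(study_config, raw)
}

scenario_params <- function(config, sc, seed) {
  model <- infection_matrix(sc$model, config$K)
  sim_params(N = config$N, mu = config$mu, K = config$K,
             s_h = sc$s_h %||% 0, s_p = sc$s_p %||% 0,
             tau_h = sc$tau_h %||% 0, tau_p = sc$tau_p %||% 0,
             model = model, generations = config$generations,
             seed = seed, drift = config$drift,
             selection = isTRUE(sc$selection))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full in-silico cross-infection study
#'
#' For every scenario in the configuration: simulate the coevolutionary
#' trajectory, run the longitudinal cross-infection survey, estimate the
#' variance-component time series, and (if requested) run likelihood-based
#' model comparison on the final experiment. All randomness derives from the
#' master seed, so reruns with the same configuration are byte-identical.
#' When `config$out_dir` is set, per-scenario trajectory and component CSVs
#' plus a manifest JSON (all seeds, parameters and file names) are written.
#'
#' @param config a [study_config()].
#' @param keep_tables retain the raw cross-infection tables in the report
#'   (memory-hungry for full-size studies; default `FALSE`).
#' @param write_tables also write every cross-infection table as CSV.
#' @return An object of class `study_report`: list with `config`,
#'   per-scenario results (`trajectory`, `components`, `seed`, optionally
#'   `tables` and `model_comparison`) and `manifest`.
#' @export
run_study <- function(config, keep_tables = FALSE, write_tables = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, length(config$scenarios))
  names(seeds) <- names(config$scenarios)
  scenarios <- list()
  manifest <- list(master_seed = config$seed, scenario_seeds = as.list(seeds),
                   files = list())
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    params <- scenario_params(config, sc, seeds[[nm]])
    traj <- run_simulation(params)
    tables <- longitudinal_survey(traj, config$design)
    res <- list(seed = seeds[[nm]], params = params, trajectory = traj)
    if ("anova" %in% config$analyses) {
      res$components <- component_timeseries(tables)
    }
    if ("likelihood" %in% config$analyses) {
      final <- tables[[length(tables)]]
      res$model_comparison <- compare_models(
        final,
        list(list(model_name = "MA", K = config$K),
             list(model_name = "GFG", K = config$K),
             list(model_name = "CONST", K = config$K)),
        seed = seeds[[nm]])
    }
    if (keep_tables) res$tables <- tables
    if (!is.null(out_dir)) {
      files <- list()
      tp <- file.path(out_dir, paste0(nm, "_trajectory.csv"))
      write_trajectory(traj, tp)
      files$trajectory <- basename(tp)
      if (!is.null(res$components)) {
        cp <- file.path(out_dir, paste0(nm, "_components.csv"))
        utils::write.csv(res$components, cp, row.names = FALSE)
        files$components <- basename(cp)
      }
      if (!is.null(res$model_comparison)) {
        jp <- file.path(out_dir, paste0(nm, "_model_comparison.json"))
        write_model_comparison(res$model_comparison, jp)
        files$model_comparison <- basename(jp)
      }
      if (write_tables) {
        tdir <- file.path(out_dir, paste0(nm, "_tables"))
        dir.create(tdir, showWarnings = FALSE)
        files$tables <- vapply(tables, function(tab) {
          f <- file.path(tdir, sprintf("gen%04d.csv",
                                       attr(tab, "generation")))
          write_cross_infection_table(tab, f)
          file.path(basename(tdir), basename(f))
        }, "")
      }
      manifest$files[[nm]] <- files
    }
    scenarios[[nm]] <- res
  }
  if (!is.null(out_dir)) {
    manifest$parameters <- list(N = config$N, mu = config$mu, K = config$K,
                                generations = config$generations,
                                drift = config$drift,
                                design = unclass(config$design))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(config = config, scenarios = scenarios,
                 manifest = manifest),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(x$scenarios), "scenarios,",
      x$config$generations, "generations each\n")
  for (nm in names(x$scenarios)) {
    comp <- x$scenarios[[nm]]$components
    if (!is.null(comp)) {
      cat(sprintf("  %-14s mean sigma2_gxg = %.4f, mean sigma2_error = %.4f\n",
                  nm, mean(comp$sigma2_gxg), mean(comp$sigma2_error)))
    }
  }
  invisible(x)
}

#' Fraction of sampled generations with negligible statistical G-by-G
#'
#' A sampled generation counts as a detection failure when its estimated
#' `sigma2_gxg` falls below `threshold_frac` times the scenario's mean error
#' variance (a scale-free threshold tied to the error stratum that dominates
#' every scenario). The seemingly paradoxical signature of strong
#' coevolution is that this fraction is *higher* under strong selection than
#' under moderate selection: stronger coevolutionary cycles spend more time
#' near fixation, where statistical G-by-G vanishes.
#'
#' @param report a `study_report` from [run_study()] (with ANOVA results).
#' @param threshold_frac threshold as a fraction of mean error variance
#'   (default 0.05).
#' @return data.frame with columns `scenario`, `threshold`,
#'   `fraction_negligible`.
#' @export
summarize_gxg_detection <- function(report, threshold_frac = 0.05) {
  stopifnot(inherits(report, "study_report"))
  if (length(report$scenarios) == 0) stop("report contains no scenarios")
  rows <- lapply(names(report$scenarios), function(nm) {
    comp <- report$scenarios[[nm]]$components
    if (is.null(comp)) stop("scenario '", nm, "' has no ANOVA components")
    thr <- threshold_frac * mean(comp$sigma2_error)
    data.frame(scenario = nm, threshold = thr,
               fraction_negligible = mean(comp$sigma2_gxg < thr))
  })
  do.call(rbind, rows)
}

#' Plot one scenario: allele frequencies and variance components
#'
#' Draws the two-panel view of a scenario on the current graphics device:
#' host genotype frequency trajectories on the left, the variance-component
#' time series from the simulated cross-infection surveys on the right.
#'
#' @param report a `study_report`.
#' @param scenario scenario name.
#' @export
plot_scenario <- function(report, scenario) {
  res <- report$scenarios[[scenario]]
  if (is.null(res)) stop("unknown scenario '", scenario, "'")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  P <- res$trajectory$p
  gens <- 0:(nrow(P) - 1L)
  graphics::matplot(gens, P, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(P), "Dark 3"),
                    xlab = "generation", ylab = "host genotype frequency",
                    main = scenario, ylim = c(0, 1))
  comp <- res$components
  cols <- c(sigma2_host = "steelblue", sigma2_parasite = "darkorange",
            sigma2_gxg = "firebrick", sigma2_error = "grey40")
  graphics::matplot(comp$generation,
                    as.matrix(comp[, names(cols)]),
                    type = "l", lty = 1, col = cols,
                    xlab = "generation", ylab = "variance component",
                    main = "cross-infection survey")
  graphics::legend("topright", legend = sub("sigma2_", "", names(cols)),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(NULL)
}
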