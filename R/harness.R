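## Experiment harness: YAML-configured runs, shared summary statistics,
## CSV output and genetic-algorithm parameter fitting.

#' Load and validate an experiment configuration
#'
#' Reads a YAML file describing a single experiment run.  Recognised
#' top-level keys:
#' * `experiment` (required): `"bee"`, `"rtd"`, `"delayed"`, `"reversal"`.
#' * `seed` (default 1) and `n_agents` (default 100).
#' * `params`: any of `alpha`, `beta`, `gamma`, `eta_q`, `eta_h`;
#'   unspecified fields take the experiment's defaults
#'   ([default_agent_params()]).
#' * `task`: experiment-specific options forwarded to the task runner
#'   (e.g. `reversal_trial` for `bee`, `n_per_state` for `rtd`,
#'   `n_passes` for `delayed`, `n_blocks` for `reversal`).
#' * `output`: optional CSV path for [write_results()].
#'
#' Unknown keys at the top level or inside `params` raise an error rather
#' than being silently ignored.
#'
#' @param path Path to a YAML file.
#' @return An `rsrl_config` list.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("experiment: bee", "n_agents: 50",
#'              "params:", "  alpha: 1.5"), cfg_file)
#' load_config(cfg_file)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML mapping.")
  allowed <- c("experiment", "seed", "n_agents", "params", "task", "output")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("bee", "rtd", "delayed", "reversal")) {
    abort("`experiment` must be one of bee, rtd, delayed, reversal.")
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$n_agents <- if (is.null(cfg$n_agents)) 100L else as.integer(cfg$n_agents)
  cfg$params <- if (is.null(cfg$params)) list() else cfg$params
  cfg$task <- if (is.null(cfg$task)) list() else cfg$task
  bad <- setdiff(names(cfg$params),
                 c("alpha", "beta", "gamma", "eta_q", "eta_h"))
  if (length(bad)) {
    abort(sprintf("unknown params key(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "rsrl_config")
}

## Merge experiment defaults with config overrides into agent_params.
config_params <- function(config) {
  p <- default_agent_params(config$experiment)
  fields <- modifyList(unclass(p)[c("alpha", "beta", "gamma",
                                    "eta_q", "eta_h")],
                       config$params)
  do.call(agent_params, fields)
}

#' Run the experiment described by a configuration
#'
#' Dispatches to the task runner named by `config$experiment`, with the
#' merged agent parameters, seed, agent count and any `task` options.
#' Unknown `task` options for the chosen runner raise an error.
#'
#' @param config An `rsrl_config` from [load_config()].
#' @return The task's simulation object (`bee_sim`, `rtd_sim`,
#'   `delayed_sim`, or `reversal_sim`).
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("experiment: bee", "n_agents: 20"), cfg_file)
#' run_experiment(load_config(cfg_file))
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "rsrl_config")) {
    abort("`config` must come from load_config().")
  }
  p <- config_params(config)
  task <- config$task
  runner <- switch(config$experiment,
    bee = function() {
      spec <- do.call(bee_task, task)
      run_bee_experiment(params = p, n_agents = config$n_agents,
                         spec = spec, seed = config$seed)
    },
    rtd = function() {
      do.call(run_rtd_experiment, c(list(
        alpha = p$alpha, params = p, n_agents = config$n_agents,
        seed = config$seed), task))
    },
    delayed = function() {
      do.call(run_delayed_experiment, c(list(
        alpha = p$alpha, gamma = p$gamma, params = p,
        n_agents = config$n_agents, seed = config$seed), task))
    },
    reversal = function() {
      do.call(run_reversal_experiment, c(list(
        alpha = p$alpha, params = p, n_agents = config$n_agents,
        seed = config$seed), task))
    }
  )
  runner()
}

#' Summarise agent-level values
#'
#' Groups a tibble of per-agent values and reports, per group, the mean,
#' the standard error of the mean (`sd / sqrt(n)`; 0 when `n = 1`), and
#' the number of non-missing values.  Missing values are dropped.
#'
#' @param data A data frame with one row per agent (or replicate).
#' @param value Name of the numeric column to summarise (a string).
#' @param by Character vector of grouping columns (may be empty).
#' @return A tibble with the `by` columns plus `mean`, `se`, `n`.
#' @examples
#' summarize_agents(tibble::tibble(g = c("a", "a", "b"), x = c(1, 3, 5)),
#'                  value = "x", by = "g")
#' @export
summarize_agents <- function(data, value, by = character()) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!value %in% names(data)) {
    abort(sprintf("column `%s` not found.", value))
  }
  missing_by <- setdiff(by, names(data))
  if (length(missing_by)) {
    abort(sprintf("grouping column(s) not found: %s",
                  paste(missing_by, collapse = ", ")))
  }
  data |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      se = if (dplyr::n() > 1L) {
        sd(.data[[value]]) / sqrt(dplyr::n())
      } else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Standard summary rows of a simulation
#'
#' Reduces a simulation object to a tibble of named statistics with one
#' row per (condition, statistic): columns `condition`, `statistic`,
#' `mean`, `se`, `n`.  This is the table [write_results()] writes out.
#'
#' @param sim A simulation object from one of the `run_*_experiment()`
#'   functions.
#' @param ... Unused.
#' @return A tibble with columns `condition`, `statistic`, `mean`, `se`,
#'   `n`.
#' @examples
#' summarize_experiment(run_bee_experiment(n_agents = 20))
#' @export
summarize_experiment <- function(sim, ...) UseMethod("summarize_experiment")

#' @export
summarize_experiment.bee_sim <- function(sim, ...) {
  pre <- sim$choice$phase == "pre-reversal"
  agent_phase <- tibble(
    agent = rep(seq_len(sim$n_agents), times = 2L),
    condition = rep(c("pre-reversal", "post-reversal"),
                    each = sim$n_agents),
    p_blue = c(rowMeans(sim$probs[, pre, drop = FALSE]),
               if (any(!pre)) rowMeans(sim$probs[, !pre, drop = FALSE])
               else rep(NA_real_, sim$n_agents))
  )
  out <- summarize_agents(agent_phase, "p_blue", "condition")
  out$statistic <- "p_blue"
  finals <- summarize_agents(sim$final, "q", "arm")
  finals$statistic <- "final_q"
  finals_h <- summarize_agents(sim$final, "h", "arm")
  finals_h$statistic <- "final_h"
  finals <- dplyr::rename(dplyr::bind_rows(finals, finals_h),
                          condition = "arm")
  lat <- if (is.finite(sim$spec$reversal_trial)) {
    tibble(condition = "overall", statistic = "switch_latency",
           mean = as.numeric(reversal_switch_latency(sim)), se = 0, n = 1L)
  } else NULL
  dplyr::bind_rows(out, finals, lat)[, c("condition", "statistic",
                                         "mean", "se", "n")]
}

#' @export
summarize_experiment.rtd_sim <- function(sim, ...) {
  purrr::map2(
    c("p_safe", "p_safe_eev", "p_safe_uev"),
    c("overall", "EEV", "UEV"),
    function(col, cond) {
      if (all(is.na(sim$agents[[col]]))) return(NULL)
      out <- summarize_agents(sim$agents, col)
      tibble(condition = cond, statistic = "p_safe",
             mean = out$mean, se = out$se, n = out$n)
    }
  ) |> dplyr::bind_rows()
}

#' @export
summarize_experiment.delayed_sim <- function(sim, ...) {
  cells <- summarize_agents(sim$choice, "p_yellow")
  tibble(condition = sprintf("gamma=%g", sim$gamma),
         statistic = "p_yellow",
         mean = sim$p_yellow, se = cells$se, n = cells$n)
}

#' @export
summarize_experiment.reversal_sim <- function(sim, ...) {
  out <- summarize_agents(sim$agents, "sqrt_errors",
                          c("condition", "trial_type"))
  tibble(condition = out$condition,
         statistic = paste0("sqrt_errors_", out$trial_type),
         mean = out$mean, se = out$se, n = out$n)
}

## Effective agent parameters of a sim (task alpha overrides params).
sim_param_row <- function(sim) {
  p <- sim$params
  tibble(alpha = if (is.null(sim$alpha)) p$alpha else sim$alpha,
         beta = p$beta,
         gamma = if (is.null(sim$gamma)) p$gamma else sim$gamma,
         eta_q = p$eta_q, eta_h = p$eta_h)
}

#' Write a simulation summary to CSV
#'
#' Writes one row per (condition, statistic) with the columns
#' `experiment`, `condition`, `statistic`, `mean`, `se`, `n`, `seed`,
#' `alpha`, `beta`, `gamma`, `eta_q`, `eta_h`.
#'
#' @param sim A simulation object.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @examples
#' out <- tempfile(fileext = ".csv")
#' write_results(run_bee_experiment(n_agents = 20), out)
#' read.csv(out)[1:3, ]
#' @export
write_results <- function(sim, path) {
  experiment <- switch(class(sim)[1L],
                       bee_sim = "bee", rtd_sim = "rtd",
                       delayed_sim = "delayed", reversal_sim = "reversal",
                       abort("`sim` is not a recognised simulation object."))
  out <- summarize_experiment(sim)
  out <- dplyr::bind_cols(
    tibble(experiment = experiment),
    out,
    tibble(seed = sim$seed),
    sim_param_row(sim)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Genetic-algorithm settings
#'
#' @param pop_size Individuals per generation.
#' @param generations Number of generations.
#' @param crossover_prob Probability that a child is produced by uniform
#'   crossover of two tournament-selected parents (otherwise it clones
#'   one parent).
#' @param mutation_prob Per-gene probability of Gaussian mutation.
#' @param mutation_sd Mutation standard deviation as a fraction of each
#'   parameter's range.
#' @param tournament_size Individuals entering each selection tournament.
#' @param elitism Top individuals copied unchanged into the next
#'   generation.
#' @return A `ga_control` list.
#' @examples
#' ga_control(generations = 20)
#' @export
ga_control <- function(pop_size = 50, generations = 100,
                       crossover_prob = 0.7, mutation_prob = 0.2,
                       mutation_sd = 0.1, tournament_size = 3,
                       elitism = 2) {
  ctl <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              crossover_prob = crossover_prob,
              mutation_prob = mutation_prob,
              mutation_sd = mutation_sd,
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism))
  if (ctl$pop_size < 2L) abort("`pop_size` must be >= 2.")
  if (ctl$generations < 1L) abort("`generations` must be >= 1.")
  if (ctl$elitism >= ctl$pop_size) abort("`elitism` must be < `pop_size`.")
  structure(ctl, class = "ga_control")
}

#' Fit parameters by a genetic algorithm
#'
#' Minimises `objective` over a box-bounded parameter space with a real
#' -coded genetic algorithm: tournament selection, uniform crossover,
#' per-gene Gaussian mutation (scaled to each parameter's range, clipped
#' to the bounds) and elitism.  Used to fit agent parameters to observed
#' choice statistics, but `objective` can be any function of a named
#' parameter vector.
#'
#' @param objective Function taking a named numeric vector (names from
#'   `lower`) and returning a single finite loss to minimise.
#' @param lower,upper Named numeric vectors of identical names giving the
#'   parameter bounds.
#' @param control A [ga_control()] list.
#' @param seed Seed for the GA's random draws.
#' @return A list with `par` (best parameters found), `value` (its loss),
#'   and `history` (tibble of per-generation best and mean loss).
#' @examples
#' fit <- fit_parameters(function(p) (p[["x"]] - 0.7)^2,
#'                       lower = c(x = 0), upper = c(x = 1),
#'                       control = ga_control(generations = 25), seed = 1)
#' fit$par
#' @export
fit_parameters <- function(objective, lower, upper,
                           control = ga_control(), seed = 1) {
  if (!is.function(objective)) abort("`objective` must be a function.")
  if (!is.numeric(lower) || !is.numeric(upper) ||
      is.null(names(lower)) || !identical(names(lower), names(upper)) ||
      any(upper <= lower)) {
    abort("`lower`/`upper` must share names and satisfy lower < upper.")
  }
  if (!inherits(control, "ga_control")) {
    abort("`control` must come from ga_control().")
  }
  set.seed(seed)
  d <- length(lower)
  rng <- upper - lower
  nm <- names(lower)
  evaluate <- function(x) {
    v <- objective(setNames(x, nm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("`objective` must return a single finite number.")
    }
    v
  }
  pop <- matrix(runif(control$pop_size * d, lower, upper),
                control$pop_size, d, byrow = TRUE)
  fit <- apply(pop, 1L, evaluate)
  history <- vector("list", control$generations)
  for (g in seq_len(control$generations)) {
    ord <- order(fit)
    new_pop <- matrix(0, control$pop_size, d)
    n_elite <- control$elitism
    if (n_elite > 0L) new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    pick <- function() {
      cand <- sample.int(control$pop_size, control$tournament_size)
      pop[cand[which.min(fit[cand])], ]
    }
    for (k in seq.int(n_elite + 1L, control$pop_size)) {
      child <- if (runif(1) < control$crossover_prob) {
        p1 <- pick(); p2 <- pick()
        ifelse(runif(d) < 0.5, p1, p2)
      } else {
        pick()
      }
      mut <- runif(d) < control$mutation_prob
      if (any(mut)) {
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, control$mutation_sd * rng[mut])
        child <- pmin(pmax(child, lower), upper)
      }
      new_pop[k, ] <- child
    }
    pop <- new_pop
    fit <- apply(pop, 1L, evaluate)
    history[[g]] <- tibble(generation = g, best = min(fit),
                           mean = mean(fit))
  }
  best <- which.min(fit)
  list(par = setNames(pop[best, ], nm), value = fit[best],
       history = dplyr::bind_rows(history))
}
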