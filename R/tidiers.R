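## broom-style tidiers: `tidy()` returns the observation-level tibble of a
## simulation, `glance()` a one-row model-level summary.

#' Tidiers for simulation objects
#'
#' `tidy()` returns the observation-level tibble of a simulation:
#' per-trial choice frequencies for `bee_sim`, per-agent choice
#' frequencies for `rtd_sim`, per-(pass, trial-type) frequencies for
#' `delayed_sim`, and per-(agent, condition, trial-type) error counts for
#' `reversal_sim`.  `glance()` returns a one-row summary with the run's
#' parameters, seed, and headline statistics.
#'
#' @param x A simulation object from one of the `run_*_experiment()`
#'   functions.
#' @param ... Unused; for generic consistency.
#' @return A tibble; `glance()` always has exactly one row.
#' @examples
#' sim <- run_bee_experiment(n_agents = 20)
#' tidy(sim)
#' glance(sim)
#' @name rsrl-tidiers
NULL

#' @rdname rsrl-tidiers
#' @method tidy bee_sim
#' @export
tidy.bee_sim <- function(x, ...) x$choice

#' @rdname rsrl-tidiers
#' @method glance bee_sim
#' @export
glance.bee_sim <- function(x, ...) {
  pre <- x$choice$phase == "pre-reversal"
  tibble(
    n_agents = x$n_agents,
    n_trials = x$spec$total_trials,
    alpha = x$params$alpha, beta = x$params$beta,
    eta_q = x$params$eta_q, eta_h = x$params$eta_h,
    p_blue_pre = mean(x$choice$p_blue[pre]),
    p_blue_post = if (any(!pre)) mean(x$choice$p_blue[!pre]) else NA_real_,
    switch_latency = if (is.finite(x$spec$reversal_trial)) {
      as.numeric(reversal_switch_latency(x))
    } else NA_real_,
    seed = x$seed
  )
}

#' @rdname rsrl-tidiers
#' @method tidy rtd_sim
#' @export
tidy.rtd_sim <- function(x, ...) x$agents

#' @rdname rsrl-tidiers
#' @method glance rtd_sim
#' @export
glance.rtd_sim <- function(x, ...) {
  tibble(
    n_agents = x$n_agents, n_per_state = x$n_per_state,
    alpha = x$alpha, beta = x$params$beta,
    p_safe = mean(x$agents$p_safe),
    p_safe_eev = mean(x$agents$p_safe_eev, na.rm = TRUE),
    p_safe_uev = mean(x$agents$p_safe_uev, na.rm = TRUE),
    seed = x$seed
  )
}

#' @rdname rsrl-tidiers
#' @method tidy delayed_sim
#' @export
tidy.delayed_sim <- function(x, ...) x$choice

#' @rdname rsrl-tidiers
#' @method glance delayed_sim
#' @export
glance.delayed_sim <- function(x, ...) {
  tibble(
    n_agents = x$n_agents, n_passes = x$n_passes,
    alpha = x$alpha, gamma = x$gamma, beta = x$params$beta,
    p_yellow = x$p_yellow,
    incomplete = x$incomplete,
    seed = x$seed
  )
}

#' @rdname rsrl-tidiers
#' @method tidy reversal_sim
#' @export
tidy.reversal_sim <- function(x, ...) x$agents

#' @rdname rsrl-tidiers
#' @method glance reversal_sim
#' @export
glance.reversal_sim <- function(x, ...) {
  tibble(
    n_agents = x$n_agents, alpha = x$alpha, beta = x$params$beta,
    sign_term = x$sign_term,
    errors_reward = mean(x$totals$errors_reward),
    errors_punishment = mean(x$totals$errors_punishment),
    errors_total = mean(x$totals$errors_total),
    stages_completed = mean(x$totals$stages_completed),
    seed = x$seed
  )
}
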