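## ggplot2 autoplot() methods: one default diagnostic plot per simulation
## class, plus a utility-profile plot for the patch-clearing task.

#' Plot methods for simulation objects
#'
#' `autoplot()` draws the standard diagnostic figure for each simulation
#' class:
#' * `bee_sim`: population choice frequency of the blue flower over
#'   trials, with the contingency reversal marked;
#' * `rtd_sim`: distribution of per-agent P(safe) split by variance class
#'   (equal vs unequal expected value);
#' * `delayed_sim`: yellow-panel clearance frequency per trial type and
#'   pass;
#' * `reversal_sim`: mean square-root error counts (with standard-error
#'   bars) by probe condition and trial type.
#'
#' @param object A simulation object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @examples
#' ggplot2::autoplot(run_bee_experiment(n_agents = 20))
#' @name rsrl-autoplot
NULL

#' @rdname rsrl-autoplot
#' @method autoplot bee_sim
#' @export
autoplot.bee_sim <- function(object, ...) {
  p <- ggplot2::ggplot(object$choice,
                       ggplot2::aes(x = .data$trial, y = .data$p_blue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Trial", y = "P(choose blue)",
                  title = "Foraging bandit: choice of the blue flower")
  if (is.finite(object$spec$reversal_trial)) {
    p <- p + ggplot2::geom_vline(xintercept = object$spec$reversal_trial,
                                 linetype = "dashed")
  }
  p
}

#' @rdname rsrl-autoplot
#' @method autoplot rtd_sim
#' @export
autoplot.rtd_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$agents, dplyr::all_of(c("p_safe_eev", "p_safe_uev")),
    names_to = "class", values_to = "p_safe_class")
  long$class <- ifelse(long$class == "p_safe_eev",
                       "equal EV", "unequal EV")
  long <- dplyr::filter(long, !is.na(.data$p_safe_class))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class,
                                     y = .data$p_safe_class)) +
    ggplot2::geom_boxplot() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "P(choose sure target)",
                  title = sprintf("Saccade gambling task (alpha = %g)",
                                  object$alpha))
}

#' @rdname rsrl-autoplot
#' @method autoplot delayed_sim
#' @export
autoplot.delayed_sim <- function(object, ...) {
  d <- object$choice
  d$trial_type <- sprintf("w%d/y%d", d$removal_white, d$removal_yellow)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial,
                                  y = .data$p_yellow,
                                  colour = factor(.data$pass))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Trial type", y = "P(clear yellow panel)",
                  colour = "Pass",
                  title = sprintf(
                    "Patch clearing (alpha = %g, gamma = %g)",
                    object$alpha, object$gamma))
}

#' @rdname rsrl-autoplot
#' @method autoplot reversal_sim
#' @export
autoplot.reversal_sim <- function(object, ...) {
  d <- summarize_agents(object$agents, "sqrt_errors",
                        c("condition", "trial_type"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial_type, y = .data$mean,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::labs(x = "Trial type", y = "sqrt(error count)",
                  fill = "Post-reversal probe",
                  title = sprintf("Reversal learning (alpha = %g)",
                                  object$alpha))
}

#' Plot the learned utility profile of the patch-clearing panels
#'
#' Shows the sign-dependent utility of every (panel, patches-remaining)
#' state from the simulation's final population-mean tables, which makes
#' visible where the yellow panel's delayed large reward out-competes the
#' white panel's quick small one.
#'
#' @param sim A `delayed_sim` from [run_delayed_experiment()].
#' @param alpha Risk weight to evaluate the profile at; defaults to the
#'   simulated one.
#' @return A `ggplot` object.
#' @examples
#' sim <- run_delayed_experiment(alpha = 1, gamma = 0.7, n_agents = 100)
#' plot_utility_profile(sim)
#' @export
plot_utility_profile <- function(sim, alpha = sim$alpha) {
  prof <- utility_difference_profile(sim, alpha)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$patches,
                                     y = .data$utility,
                                     colour = .data$panel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Patches remaining", y = "Utility",
                  colour = "Panel",
                  title = sprintf(
                    "Learned utility by state (alpha = %g, gamma = %g)",
                    alpha, sim$gamma))
}
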