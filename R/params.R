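#' Agent parameters
#'
#' Bundle the five free parameters of the risk-sensitive agent into a single
#' validated record.
#'
#' @param alpha Risk weight (dimensionless, \eqn{\ge 0}).  Trades expected
#'   value against the standard deviation of the reward prediction error in
#'   the utility; the model's serotonin correlate.  `alpha = 0` recovers a
#'   classical value-only agent.
#' @param beta Inverse temperature of the softmax policy (\eqn{\ge 0}).
#'   `beta = 0` makes all actions equiprobable; large `beta` approaches
#'   greedy selection.
#' @param gamma Discount factor in `[0, 1)`.  Only used by tasks with
#'   delayed rewards; immediate-reward tasks use `gamma = 0`.
#' @param eta_q Learning rate of the value function, in `(0, 1)`.
#' @param eta_h Learning rate of the risk function, in `(0, 1)`.
#'
#' @return An object of class `agent_params`: a named list with the five
#'   fields above.
#'
#' @examples
#' agent_params(alpha = 1.5, beta = 10, eta_q = 0.001, eta_h = 0.051)
#' @export
agent_params <- function(alpha = 1, beta = 1, gamma = 0,
                         eta_q = 0.1, eta_h = 0.1) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma,
            eta_q = eta_q, eta_h = eta_h)
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

validate_agent_params <- function(p) {
  for (nm in c("alpha", "beta", "gamma", "eta_q", "eta_h")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number, got %s.",
                    nm, deparse(v)))
    }
  }
  if (p$alpha < 0) abort("`alpha` must be >= 0.")
  if (p$beta < 0) abort("`beta` must be >= 0.")
  if (p$gamma < 0 || p$gamma >= 1) abort("`gamma` must be in [0, 1).")
  if (p$eta_q <= 0 || p$eta_q >= 1) abort("`eta_q` must be in (0, 1).")
  if (p$eta_h <= 0 || p$eta_h >= 1) abort("`eta_h` must be in (0, 1).")
  invisible(p)
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>",
      sprintf("alpha = %g, beta = %g, gamma = %g, eta_q = %g, eta_h = %g\n",
              x$alpha, x$beta, x$gamma, x$eta_q, x$eta_h))
  invisible(x)
}

#' Per-experiment default agent parameters
#'
#' The parameter sets used to simulate each behavioural paradigm.  The
#' learning rates default to 0.1 except where an experiment-specific fit is
#' reported (the foraging bandit).
#'
#' @param experiment One of `"bee"`, `"rtd"`, `"delayed"`, `"reversal"`.
#'
#' @details
#' * `bee` (foraging bandit): `eta_q = 0.001`, `eta_h = 0.051`,
#'   `alpha = 1.5`, `beta = 10`.
#' * `rtd` (tryptophan-depletion saccade task): `beta = 0.044`,
#'   `alpha = 1.985` in the baseline condition (`alpha = 1.658` models the
#'   depleted condition; pass it explicitly).
#' * `delayed` (patch-clearing task): `beta = 20`, `gamma = 0.7`,
#'   `alpha = 1` as a mid-range default (both are swept in practice).
#' * `reversal` (reward/punishment prediction): `beta = 10`, `alpha = 0.5`
#'   in the balanced condition (`alpha = 0.3` models depletion).
#'
#' @return An [agent_params()] object.
#' @examples
#' default_agent_params("bee")
#' @export
default_agent_params <- function(experiment = c("bee", "rtd", "delayed",
                                                "reversal")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    bee      = agent_params(alpha = 1.5,   beta = 10,    gamma = 0,
                            eta_q = 0.001, eta_h = 0.051),
    rtd      = agent_params(alpha = 1.985, beta = 0.044, gamma = 0),
    delayed  = agent_params(alpha = 1,     beta = 20,    gamma = 0.7),
    reversal = agent_params(alpha = 0.5,   beta = 10,    gamma = 0)
  )
}

## Alpha values used to model the serotonin manipulation in each paradigm.
rtd_alpha <- c(baseline = 1.985, depleted = 1.658)
reversal_alpha <- c(balanced = 0.5, depleted = 0.3)
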