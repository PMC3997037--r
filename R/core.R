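## Core learning rules: TD errors, value/risk updates, sign-dependent
## utility and the softmax policy.  All functions are vectorised over their
## numeric arguments and validate the contracts the task engines rely on.

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and non-empty.", name))
  }
  invisible(x)
}

#' Temporal-difference error for immediate rewards
#'
#' For a single-decision ("immediate reward") problem the TD error is the
#' difference between the reward just received and the current value
#' estimate of the chosen state-action pair:
#' \eqn{\delta_t = r_t - Q_t(s_t, a_t)}.  This quantity is the model's
#' dopamine correlate.
#'
#' @param reward Reward received (reward units).
#' @param q Current value estimate for the chosen pair.
#' @return `reward - q`.
#' @seealso [td_error_discounted()] for multi-step tasks.
#' @examples
#' td_error_immediate(1, 0)
#' td_error_immediate(150 - 193.2, 0)
#' @export
td_error_immediate <- function(reward, q) {
  check_finite(reward, "reward")
  check_finite(q, "q")
  reward - q
}

#' Temporal-difference error with discounting
#'
#' For delayed-reward tasks the TD error bootstraps on the value of the
#' successor state: \eqn{\delta_t = r_{t+1} + \gamma Q_t(s_{t+1}) -
#' Q_t(s_t)}.  Pass `q_next = 0` for a terminal successor.
#'
#' @param reward Reward on the transition.
#' @param q_next Value estimate of the successor state (0 if terminal).
#' @param q_curr Value estimate of the current state.
#' @param gamma Discount factor in `[0, 1)`.
#' @return `reward + gamma * q_next - q_curr`.
#' @examples
#' td_error_discounted(0, 2, 1, 0.5)   # 0
#' td_error_discounted(4, 0, 0, 0.7)   # terminal transition
#' @export
td_error_discounted <- function(reward, q_next, q_curr, gamma) {
  check_finite(reward, "reward")
  check_finite(q_next, "q_next")
  check_finite(q_curr, "q_curr")
  if (!is.numeric(gamma) || any(gamma < 0) || any(gamma >= 1)) {
    abort("`gamma` must be in [0, 1).")
  }
  reward + gamma * q_next - q_curr
}

#' Incremental value update
#'
#' Moves the value estimate a fraction `eta_q` of the way along the TD
#' error: \eqn{Q_{t+1} = Q_t + \eta_Q \delta_t}.
#'
#' @param q Current value.
#' @param delta TD error (see [td_error_immediate()]).
#' @param eta_q Learning rate in `(0, 1)`.
#' @return Updated value.
#' @examples
#' update_value(0, 1, 0.1)
#' @export
update_value <- function(q, delta, eta_q) {
  check_finite(q, "q")
  check_finite(delta, "delta")
  if (!is.numeric(eta_q) || any(eta_q <= 0) || any(eta_q >= 1)) {
    abort("`eta_q` must be in (0, 1).")
  }
  q + eta_q * delta
}

#' Risk prediction error
#'
#' The risk function `h` tracks the running expectation of the squared TD
#' error.  Its own prediction error is \eqn{\xi_t = \delta_t^2 - h_t}.
#'
#' @param delta TD error of the current trial.
#' @param h Current risk estimate (must be \eqn{\ge 0}).
#' @return `delta^2 - h`.
#' @examples
#' risk_error(-2, 1)   # 3
#' @export
risk_error <- function(delta, h) {
  check_finite(delta, "delta")
  check_finite(h, "h")
  if (any(h < 0)) abort("`h` must be >= 0 (risk estimates are variances).")
  delta^2 - h
}

#' Incremental risk update
#'
#' \eqn{h_{t+1} = h_t + \eta_h \xi_t = (1 - \eta_h) h_t + \eta_h
#' \delta_t^2}: a convex combination of the old estimate and a squared
#' error, so the result is always non-negative when the inputs respect
#' their contracts.
#'
#' @param h Current risk estimate (\eqn{\ge 0}).
#' @param xi Risk prediction error produced by [risk_error()] from this `h`.
#' @param eta_h Learning rate in `(0, 1)`.
#' @return Updated risk estimate, \eqn{\ge 0}.
#' @examples
#' update_risk(0, 1, 0.1)
#' @export
update_risk <- function(h, xi, eta_h) {
  check_finite(h, "h")
  check_finite(xi, "xi")
  if (!is.numeric(eta_h) || any(eta_h <= 0) || any(eta_h >= 1)) {
    abort("`eta_h` must be in (0, 1).")
  }
  if (any(h < 0)) abort("`h` must be >= 0.")
  out <- h + eta_h * xi
  if (any(out < -1e-12)) {
    abort("risk update produced a negative estimate; `xi` was not derived from this `h`.")
  }
  pmax(out, 0)
}

#' Sign-dependent mean-variance utility
#'
#' The utility an action is selected on:
#' \deqn{U = Q - \alpha\, \mathrm{sign}(Q)\, \sqrt{h}.}
#' For positive expected value the risk term is a penalty (risk aversion in
#' gains); for negative expected value it is a bonus (risk seeking in
#' losses).  `sign(0) = 0`, so the risk term vanishes at the neutral value.
#'
#' @param q Value estimate(s).
#' @param h Risk estimate(s), \eqn{\ge 0}.
#' @param alpha Risk weight, \eqn{\ge 0}.
#' @param risk_transform How the risk estimate enters the utility:
#'   `"sqrt"` (default; risk enters as a standard deviation) or
#'   `"identity"` (raw variance), provided for sensitivity checks.
#' @return Utility, same length as `q`.
#' @examples
#' utility(1, 0.25, 1.5)    #  0.25
#' utility(-1, 0.25, 1.5)   # -0.25
#' utility(3, 0.25, 0)      #  3  (classical limit)
#' @export
utility <- function(q, h, alpha, risk_transform = c("sqrt", "identity")) {
  risk_transform <- match.arg(risk_transform)
  check_finite(q, "q")
  check_finite(h, "h")
  if (any(h < 0)) abort("`h` must be >= 0.")
  if (!is.numeric(alpha) || any(alpha < 0)) abort("`alpha` must be >= 0.")
  r <- if (risk_transform == "sqrt") sqrt(h) else h
  q - alpha * sign(q) * r
}

#' Softmax choice probabilities
#'
#' \eqn{P(a_i) = \exp(\beta U_i) / \sum_j \exp(\beta U_j)}, computed with
#' max-subtraction so large utilities cannot overflow.  `beta = 0` yields
#' the uniform distribution.
#'
#' @param utilities Non-empty numeric vector of action utilities.
#' @param beta Inverse temperature, \eqn{\ge 0}.
#' @return Probability vector summing to 1 (within 1e-12).
#' @examples
#' softmax_probs(c(1, 0), beta = 1)
#' @export
softmax_probs <- function(utilities, beta) {
  if (length(utilities) == 0L) abort("`utilities` must be non-empty.")
  check_finite(utilities, "utilities")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    abort("`beta` must be a single number >= 0.")
  }
  z <- beta * utilities
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample an action from choice probabilities
#'
#' Draws one action index from the distribution `probs` using the current
#' RNG stream (so results are reproducible under `set.seed()`).
#'
#' @param probs Probability vector: non-negative, summing to 1 within 1e-8.
#' @return An integer action index in `1:length(probs)`.
#' @examples
#' set.seed(1)
#' sample_action(c(0.7, 0.3))
#' @export
sample_action <- function(probs) {
  if (!is.numeric(probs) || length(probs) == 0L || any(!is.finite(probs)) ||
      any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("`probs` must be non-negative and sum to 1.")
  }
  findInterval(runif(1), cumsum(probs), left.open = TRUE) + 1L
}

## Derive a per-agent seed from a run-level seed so each simulated agent
## has its own reproducible substream, independent of batch size.
## Consecutive raw seeds fed to set.seed() yield noticeably correlated
## streams, so the combined seed is scrambled through three rounds of a
## Lehmer step (a bijection on 1..2^31-2, so distinct agents keep
## distinct seeds).  All arithmetic stays below 2^53 and is exact.
agent_seed <- function(seed, agent) {
  m <- 2147483647
  x <- ((seed %% m) * 48271 + agent) %% m
  if (x == 0) x <- m - 1
  for (k in 1:3) x <- (48271 * x) %% m
  x
}
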