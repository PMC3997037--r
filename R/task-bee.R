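## Foraging bandit: blue flowers deliver a constant 1 ul of nectar, yellow
## flowers deliver 3 ul with probability 1/3 (same mean, higher variance).
## The contingencies swap at the reversal trial.  A stateless two-armed
## bandit with immediate-reward TD learning.

#' Foraging-bandit task specification
#'
#' @param reward_safe Nectar volume of the constant arm (reward units).
#' @param reward_risky_high High outcome of the variable arm.
#' @param p_risky_high Probability of the high outcome on the variable arm;
#'   otherwise the arm delivers 0.  The defaults give both arms the same
#'   mean reward (1) but variance 0 vs 2.
#' @param reversal_trial Trial (1-based, inclusive) from which the two
#'   contingencies are swapped.  Use `Inf` for no reversal.
#' @param total_trials Number of decisions per agent.
#'
#' @return A `bee_task` object.
#' @examples
#' bee_task()
#' bee_task(reversal_trial = Inf, total_trials = 5000)
#' @export
bee_task <- function(reward_safe = 1, reward_risky_high = 3,
                     p_risky_high = 1 / 3, reversal_trial = 15,
                     total_trials = 40) {
  if (p_risky_high < 0 || p_risky_high > 1) {
    abort("`p_risky_high` must be a probability.")
  }
  if (is.finite(reversal_trial) && reversal_trial >= total_trials) {
    abort("`reversal_trial` must be < `total_trials` (or Inf for none).")
  }
  if (abs(p_risky_high * reward_risky_high - reward_safe) > 1e-9) {
    abort("the two arms must have equal mean reward (matched-mean design).")
  }
  structure(list(reward_safe = reward_safe,
                 reward_risky_high = reward_risky_high,
                 p_risky_high = p_risky_high,
                 reversal_trial = reversal_trial,
                 total_trials = total_trials),
            class = "bee_task")
}

## Which arm is the variable one on a given trial: yellow (2) before the
## reversal, blue (1) from the reversal trial onward.
bee_risky_arm <- function(trial, spec) {
  ifelse(trial >= spec$reversal_trial, 1L, 2L)
}

#' Draw nectar rewards from one flower arm
#'
#' Before the reversal trial the blue arm pays `reward_safe`
#' deterministically and the yellow arm pays `reward_risky_high` with
#' probability `p_risky_high` (else 0); from the reversal trial onward the
#' two contingencies are swapped.  Draws use the current RNG stream.
#'
#' @param arm `"blue"` or `"yellow"`.
#' @param trial Trial index (1-based).
#' @param spec A [bee_task()].
#' @param n Number of independent draws.
#' @return Numeric vector of `n` rewards.
#' @examples
#' set.seed(1)
#' bee_reward("blue", trial = 5)         # always 1
#' mean(bee_reward("yellow", trial = 5, n = 1e4))  # ~1
#' @export
bee_reward <- function(arm, trial, spec = bee_task(), n = 1) {
  arm <- match.arg(arm, c("blue", "yellow"))
  if (trial < 1 || trial > spec$total_trials) {
    abort("`trial` must lie within the task's trial range.")
  }
  arm_id <- if (arm == "blue") 1L else 2L
  if (arm_id == bee_risky_arm(trial, spec)) {
    ifelse(runif(n) < spec$p_risky_high, spec$reward_risky_high, 0)
  } else {
    rep(spec$reward_safe, n)
  }
}

#' Simulate the foraging bandit
#'
#' Runs `n_agents` independent agents through the two-armed flower bandit.
#' Each trial the agent computes the sign-dependent utility of both arms
#' from its value and risk tables, draws an arm from the softmax policy,
#' receives nectar, and updates the chosen arm's tables with the
#' immediate-reward TD rule.  Each agent consumes its own RNG substream
#' (derived from `seed` and the agent index), so trajectories do not depend
#' on how many agents run alongside.
#'
#' @param params [agent_params()]; defaults to the task's fitted set
#'   (`eta_q = 0.001`, `eta_h = 0.051`, `alpha = 1.5`, `beta = 10`).
#' @param n_agents Number of simulated bees.
#' @param spec [bee_task()] describing rewards and the reversal.
#' @param seed Run-level seed.
#' @param policy `"utility"` (default) selects on the sign-dependent
#'   utility; `"value"` selects on Q directly (classical reference agent;
#'   risk tables are still learned but do not influence choice).
#' @param risk_transform Passed to [utility()].
#'
#' @return A `bee_sim` object with elements
#'   * `choice`: tibble of per-trial selection frequencies (`trial`,
#'     `p_blue`, `p_yellow`, `phase`),
#'   * `trajectories`: tibble of per-trial population means of Q and h per
#'     arm,
#'   * `final`: tibble of each agent's final Q and h per arm,
#'   * `probs`: matrix of per-agent, per-trial P(blue) under the policy,
#'   * call metadata (`params`, `spec`, `n_agents`, `seed`, `policy`).
#'
#' @examples
#' sim <- run_bee_experiment(n_agents = 50, seed = 1)
#' head(tidy(sim))
#' reversal_switch_latency(sim)
#' @export
run_bee_experiment <- function(params = default_agent_params("bee"),
                               n_agents = 1000, spec = bee_task(), seed = 1,
                               policy = c("utility", "value"),
                               risk_transform = c("sqrt", "identity")) {
  policy <- match.arg(policy)
  risk_transform <- match.arg(risk_transform)
  validate_agent_params(params)
  if (n_agents < 1) abort("`n_agents` must be >= 1.")
  nt <- spec$total_trials

  ## per-agent substreams: one uniform for the choice and one for the
  ## reward on every trial, pregenerated so streams stay aligned across
  ## parameter settings (common random numbers)
  u_act <- matrix(0, n_agents, nt)
  u_rew <- matrix(0, n_agents, nt)
  for (i in seq_len(n_agents)) {
    set.seed(agent_seed(seed, i))
    u <- runif(2L * nt)
    u_act[i, ] <- u[seq_len(nt)]
    u_rew[i, ] <- u[nt + seq_len(nt)]
  }

  Q <- matrix(0, n_agents, 2L)  # cols: blue, yellow
  H <- matrix(0, n_agents, 2L)
  choice_blue <- matrix(FALSE, n_agents, nt)
  p_blue_mat <- matrix(0, n_agents, nt)
  traj <- array(0, c(nt, 2L, 2L))  # trial x arm x (q, h)

  for (t in seq_len(nt)) {
    U <- if (policy == "value") Q else {
      Q - params$alpha * sign(Q) *
        (if (risk_transform == "sqrt") sqrt(H) else H)
    }
    p_blue <- 1 / (1 + exp(-params$beta * (U[, 1L] - U[, 2L])))
    blue <- u_act[, t] < p_blue
    arm <- ifelse(blue, 1L, 2L)
    risky <- bee_risky_arm(t, spec)
    r <- ifelse(arm == risky,
                ifelse(u_rew[, t] < spec$p_risky_high,
                       spec$reward_risky_high, 0),
                spec$reward_safe)
    idx <- cbind(seq_len(n_agents), arm)
    d <- r - Q[idx]
    xi <- d^2 - H[idx]
    Q[idx] <- Q[idx] + params$eta_q * d
    H[idx] <- H[idx] + params$eta_h * xi
    choice_blue[, t] <- blue
    p_blue_mat[, t] <- p_blue
    traj[t, , 1L] <- colMeans(Q)
    traj[t, , 2L] <- colMeans(H)
  }

  arms <- c("blue", "yellow")
  structure(list(
    choice = tibble(
      trial = seq_len(nt),
      p_blue = colMeans(choice_blue),
      p_yellow = 1 - colMeans(choice_blue),
      phase = ifelse(seq_len(nt) >= spec$reversal_trial,
                     "post-reversal", "pre-reversal")
    ),
    trajectories = tibble(
      trial = rep(seq_len(nt), times = 2L),
      arm = rep(arms, each = nt),
      q_mean = c(traj[, 1L, 1L], traj[, 2L, 1L]),
      h_mean = c(traj[, 1L, 2L], traj[, 2L, 2L])
    ),
    final = tibble(
      agent = rep(seq_len(n_agents), times = 2L),
      arm = rep(arms, each = n_agents),
      q = c(Q[, 1L], Q[, 2L]),
      h = c(H[, 1L], H[, 2L])
    ),
    probs = p_blue_mat,
    params = params, spec = spec, n_agents = n_agents, seed = seed,
    policy = policy
  ), class = "bee_sim")
}

#' Trials needed for the population to switch arms after the reversal
#'
#' Finds the first trial at or after the contingency reversal on which the
#' majority of agents choose the newly safe (yellow) arm, and reports how
#' many trials after the reversal that is (0 = switched on the reversal
#' trial itself, `NA` if the majority never switches).
#'
#' @param sim A `bee_sim` from [run_bee_experiment()].
#' @return Integer number of trials elapsed since the reversal.
#' @export
reversal_switch_latency <- function(sim) {
  spec <- sim$spec
  if (!is.finite(spec$reversal_trial)) abort("task has no reversal.")
  post <- sim$choice[sim$choice$trial >= spec$reversal_trial, ]
  hit <- which(post$p_blue < 0.5)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(post$trial[hit[1L]] - spec$reversal_trial)
}

#' @export
print.bee_sim <- function(x, ...) {
  cat(sprintf("<bee_sim> %d agents, %d trials (reversal at %s), alpha = %g\n",
              x$n_agents, x$spec$total_trials,
              format(x$spec$reversal_trial), x$params$alpha))
  pre <- mean(x$choice$p_blue[x$choice$phase == "pre-reversal"])
  post <- mean(x$choice$p_blue[x$choice$phase == "post-reversal"])
  cat(sprintf("  mean P(blue): %.3f pre-reversal, %.3f post-reversal\n",
              pre, if (is.nan(post)) NA else post))
  invisible(x)
}
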