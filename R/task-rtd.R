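## Saccade gambling task used in the tryptophan-depletion study: on each
## trial one of six stimulus pairs ("states") appears and the agent
## saccades to either a sure target or a 50/50 gamble.  Rewards are juice
## volumes recoded relative to a subjective neutral point, so small wins
## feel like losses.

#' Reward schedule of the saccade gambling task
#'
#' Six states, each pairing a sure juice volume against an equiprobable
#' two-outcome gamble.  In states 1-4 the gamble's expected volume equals
#' the sure volume (equal expected value, "EEV"); in states 5-6 the sure
#' volume is lower than the gamble's mean (unequal expected value, "UEV").
#'
#' @return A tibble with columns `state`, `reward_safe`,
#'   `reward_risky_low`, `reward_risky_high`, `ev_risky`, and
#'   `variance_class` (`"EEV"` or `"UEV"`).
#' @examples
#' rtd_schedule()
#' @export
rtd_schedule <- function() {
  out <- tibble(
    state = 1:6,
    reward_safe = c(150, 150, 150, 140, 200, 210),
    reward_risky_low = c(125, 100, 50, 40, 40, 40),
    reward_risky_high = c(175, 200, 250, 240, 240, 240)
  )
  out$ev_risky <- (out$reward_risky_low + out$reward_risky_high) / 2
  out$variance_class <- ifelse(abs(out$ev_risky - out$reward_safe) < 1e-9,
                               "EEV", "UEV")
  out
}

#' Subjective reward of a juice volume
#'
#' The model assumes choices are driven not by raw juice volume but by its
#' distance from a subjective neutral point: `reward = juice - base`.  With
#' the default neutral point of 193.2 ul, the sure options of the
#' equal-expected-value states are experienced as losses.
#'
#' @param juice Juice volume(s) in ul.
#' @param base Neutral point in ul.
#' @return Subjective reward, same length as `juice`.
#' @examples
#' subjective_reward(150)   # -43.2
#' subjective_reward(250)   #  56.8
#' @export
subjective_reward <- function(juice, base = 193.2) {
  check_finite(juice, "juice")
  check_finite(base, "base")
  juice - base
}

#' Simulate the saccade gambling task
#'
#' Runs independent agents through randomised blocks of the six-state
#' schedule.  Each trial the agent picks the sure or risky target by
#' softmax over sign-dependent utilities, receives the subjective reward,
#' and updates the (state, action) value and risk tables with the
#' immediate-reward TD rule.  Each agent has its own RNG substream derived
#' from `seed`, so runs with different `alpha` but the same seed are
#' matched trial for trial (common random numbers) — useful for paired
#' comparisons between serotonin conditions.
#'
#' @param alpha Risk weight; `rtd_alpha` holds the fitted values for the
#'   baseline (1.985) and tryptophan-depleted (1.658) conditions.
#' @param params Remaining [agent_params()] (`beta`, learning rates);
#'   its `alpha` field is overridden by the `alpha` argument.
#' @param n_agents Number of agents.
#' @param n_per_state Presentations of each state per agent.  States are
#'   interleaved in shuffled blocks containing each state once.
#' @param states Subset of states (1-6) to present; defaults to all six.
#' @param measure_last If given, agent-level choice frequencies are
#'   computed over only the final `measure_last` presentations per agent
#'   (after learning has settled); default uses every trial.
#' @param seed Run-level seed.
#' @param reward_base Subjective neutral point passed to
#'   [subjective_reward()].
#'
#' @return An `rtd_sim` object with elements
#'   * `agents`: tibble with one row per agent: `p_safe` overall and split
#'     by variance class (`p_safe_eev`, `p_safe_uev`; `NA` when a class
#'     was not presented), over the measurement window,
#'   * `by_state`: tibble of per-agent, per-state P(safe) over the window,
#'   * `final`: tibble of final Q and h per (agent, state, action),
#'   * call metadata (`alpha`, `params`, `n_agents`, `n_per_state`,
#'     `states`, `measure_last`, `seed`, `reward_base`).
#'
#' @examples
#' sim <- run_rtd_experiment(n_agents = 20, n_per_state = 50, seed = 1)
#' glance(sim)
#' @export
run_rtd_experiment <- function(alpha = rtd_alpha[["baseline"]],
                               params = default_agent_params("rtd"),
                               n_agents = 100, n_per_state = 200,
                               states = 1:6, measure_last = NULL,
                               seed = 1, reward_base = 193.2) {
  validate_agent_params(params)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    abort("`alpha` must be a single number >= 0.")
  }
  states <- as.integer(states)
  if (length(states) == 0L || anyDuplicated(states) ||
      any(!states %in% 1:6)) {
    abort("`states` must be a non-empty duplicate-free subset of 1:6.")
  }
  sched <- rtd_schedule()
  n_trials <- length(states) * n_per_state
  if (is.null(measure_last)) measure_last <- n_trials
  if (measure_last < 1 || measure_last > n_trials) {
    abort("`measure_last` must be in 1..(length(states) * n_per_state).")
  }
  eev_state <- sched$variance_class == "EEV"

  agents <- vector("list", n_agents)
  by_state <- vector("list", n_agents)
  finals <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    set.seed(agent_seed(seed, i))
    seq_states <- if (length(states) == 1L) {
      rep(states, n_per_state)
    } else {
      as.vector(vapply(seq_len(n_per_state), function(b) sample(states),
                       integer(length(states))))
    }
    u_act <- runif(n_trials)
    u_out <- runif(n_trials)
    Q <- matrix(0, 6L, 2L)  # cols: safe, risky
    H <- matrix(0, 6L, 2L)
    safe_ch <- logical(n_trials)
    for (k in seq_len(n_trials)) {
      s <- seq_states[k]
      U <- utility(Q[s, ], H[s, ], alpha)
      p_safe <- 1 / (1 + exp(-params$beta * (U[1L] - U[2L])))
      a <- if (u_act[k] < p_safe) 1L else 2L
      juice <- if (a == 1L) sched$reward_safe[s] else if (u_out[k] < 0.5) {
        sched$reward_risky_low[s]
      } else {
        sched$reward_risky_high[s]
      }
      r <- subjective_reward(juice, reward_base)
      d <- r - Q[s, a]
      xi <- d^2 - H[s, a]
      Q[s, a] <- Q[s, a] + params$eta_q * d
      H[s, a] <- H[s, a] + params$eta_h * xi
      safe_ch[k] <- a == 1L
    }
    win <- seq.int(n_trials - measure_last + 1L, n_trials)
    s_win <- seq_states[win]
    c_win <- safe_ch[win]
    eev <- eev_state[s_win]
    agents[[i]] <- tibble(
      agent = i,
      p_safe = mean(c_win),
      p_safe_eev = if (any(eev)) mean(c_win[eev]) else NA_real_,
      p_safe_uev = if (any(!eev)) mean(c_win[!eev]) else NA_real_
    )
    by_state[[i]] <- tibble(
      agent = i, state = states,
      p_safe = vapply(states, function(s) mean(c_win[s_win == s]),
                      numeric(1))
    )
    finals[[i]] <- tibble(
      agent = i,
      state = rep(states, times = 2L),
      action = rep(c("safe", "risky"), each = length(states)),
      q = c(Q[states, 1L], Q[states, 2L]),
      h = c(H[states, 1L], H[states, 2L])
    )
  }

  structure(list(
    agents = dplyr::bind_rows(agents),
    by_state = dplyr::bind_rows(by_state),
    final = dplyr::bind_rows(finals),
    alpha = alpha, params = params, n_agents = n_agents,
    n_per_state = n_per_state, states = states,
    measure_last = measure_last, seed = seed, reward_base = reward_base
  ), class = "rtd_sim")
}

#' @export
print.rtd_sim <- function(x, ...) {
  cat(sprintf("<rtd_sim> %d agents x %d presentations/state, alpha = %g\n",
              x$n_agents, x$n_per_state, x$alpha))
  cat(sprintf("  mean P(safe): %.3f overall, %.3f EEV, %.3f UEV\n",
              mean(x$agents$p_safe),
              mean(x$agents$p_safe_eev, na.rm = TRUE),
              mean(x$agents$p_safe_uev, na.rm = TRUE)))
  invisible(x)
}
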