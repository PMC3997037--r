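## Probabilistic-free reversal learning: two stimuli, two responses.  One
## stimulus is currently "rewarding" (the correct response earns +1), the
## other "punishing" (the correct response avoids -1).  After a criterion
## run of correct responses the contingency silently reverses.  The value
## table is constrained to be complementary across both stimuli and
## responses, so a single free value parameterises it; the risk tables are
## unconstrained.

#' Project a 2 x 2 value table onto the complementary subspace
#'
#' The task's value table obeys two complementarity constraints:
#' `Q(s, a1) = -Q(s, a2)` within each stimulus and `Q(s1, a) = -Q(s2, a)`
#' across stimuli.  This function orthogonally projects an arbitrary 2 x 2
#' table (rows = stimuli, columns = responses) onto that one-dimensional
#' subspace.  It is idempotent, and tables already satisfying the
#' constraints pass through unchanged.
#'
#' @param q_matrix A numeric 2 x 2 matrix.
#' @return A 2 x 2 matrix of the form `[[q, -q], [-q, q]]`.
#' @examples
#' enforce_complementarity(matrix(c(1, 0, 0, 0), 2, 2))
#' @export
enforce_complementarity <- function(q_matrix) {
  if (!is.matrix(q_matrix) || !all(dim(q_matrix) == 2L) ||
      !is.numeric(q_matrix) || any(!is.finite(q_matrix))) {
    abort("`q_matrix` must be a finite numeric 2 x 2 matrix.")
  }
  q <- (q_matrix[1L, 1L] - q_matrix[1L, 2L] -
          q_matrix[2L, 1L] + q_matrix[2L, 2L]) / 4
  matrix(c(q, -q, -q, q), 2L, 2L)
}

#' Run a single reversal-learning trial
#'
#' Given the agent's free value `q`, its risk table `h`, the stimulus shown
#' and the currently rewarding stimulus, selects a response by softmax over
#' sign-dependent utilities, scores it, and applies the value and risk
#' updates.  Rewards are correctness-coded: +1 for a correct response
#' (obtaining the reward, or correctly avoiding the punishment) and -1
#' otherwise.  The value update is applied to the free parameter so the
#' complementarity constraints hold by construction.  Response sampling
#' uses the current RNG stream.
#'
#' @param q Free value scalar; the full table is `[[q, -q], [-q, q]]`.
#' @param h 2 x 2 non-negative risk table (rows = stimuli, columns =
#'   responses); unlike the value table it is not constrained.
#' @param stim Stimulus shown this trial (1 or 2).
#' @param rewarding Which stimulus is currently the rewarding one (1 or 2).
#' @param alpha,beta,eta_q,eta_h Agent parameters (see [agent_params()]).
#' @param sign_term If `FALSE`, the risk term enters the utility without
#'   the `sign(Q)` factor (a uniform risk penalty), for testing the role of
#'   sign-dependence.
#' @return A list with the updated `q` and `h`, plus `action` (1 or 2),
#'   `correct` (logical), and `reward` (+1 or -1).
#' @examples
#' set.seed(1)
#' run_reversal_trial(q = 0, h = matrix(0, 2, 2), stim = 1, rewarding = 1,
#'                    alpha = 0.5, beta = 10)
#' @export
run_reversal_trial <- function(q, h, stim, rewarding, alpha, beta = 10,
                               eta_q = 0.1, eta_h = 0.1, sign_term = TRUE) {
  check_finite(q, "q")
  if (!is.matrix(h) || !all(dim(h) == 2L) || any(!is.finite(h)) ||
      any(h < 0)) {
    abort("`h` must be a non-negative 2 x 2 matrix.")
  }
  if (!stim %in% 1:2 || !rewarding %in% 1:2) {
    abort("`stim` and `rewarding` must each be 1 or 2.")
  }
  qs <- if (stim == 1L) c(q, -q) else c(-q, q)
  risk <- alpha * sqrt(h[stim, ])
  u <- if (sign_term) qs - sign(qs) * risk else qs - risk
  a <- if (runif(1) < 1 / (1 + exp(-beta * (u[1L] - u[2L])))) 1L else 2L
  correct <- (a == 1L) == (stim == rewarding)
  r <- if (correct) 1 else -1
  d <- r - qs[a]
  h[stim, a] <- h[stim, a] + eta_h * (d^2 - h[stim, a])
  new_q <- qs[a] + eta_q * d
  q <- if ((stim == 1L) == (a == 1L)) new_q else -new_q
  list(q = q, h = h, action = a, correct = correct, reward = r)
}

#' Simulate the reversal-learning experiment
#'
#' Each agent completes four blocks of up to 16 reversal stages (120 trials
#' per block).  Within a stage the contingency is fixed; after a criterion
#' number of correct responses — drawn uniformly from 5 to 9 per stage —
#' it reverses.  Blocks alternate between two probe conditions that differ
#' only in the first stimulus shown after each reversal: the newly
#' rewarding stimulus (`"rewarding-first"`) or the newly punishing one
#' (`"punishing-first"`).  After an error the same stimulus is repeated on
#' the next trial.
#'
#' Errors are tallied separately for rewarding-stimulus trials (failing to
#' obtain reward) and punishing-stimulus trials (failing to avoid
#' punishment).  To exclude trivially uninformed responses, errors on the
#' first two trials after a reversal are not counted (all trials count in
#' the first, acquisition, stage).  Each agent consumes its own RNG
#' substream derived from `seed`, so runs at different `alpha` with the
#' same seed are paired.
#'
#' @param alpha Risk weight; `reversal_alpha` holds the values modelling
#'   the balanced (0.5) and tryptophan-depleted (0.3) conditions.
#' @param params Remaining [agent_params()]; its `alpha` field is
#'   overridden by the `alpha` argument.
#' @param n_agents Number of agents.
#' @param seed Run-level seed.
#' @param sign_term Passed to [run_reversal_trial()].
#' @param n_blocks Blocks per agent (conditions alternate across blocks).
#' @param max_stages,max_trials Per-block caps on completed reversals and
#'   trials.
#' @param criterion_range Integer range the per-stage correct-response
#'   criterion is drawn from.
#'
#' @return A `reversal_sim` object with elements
#'   * `agents`: tibble with one row per (agent, condition, trial type):
#'     `errors` and `sqrt_errors` (error counts are square-root transformed
#'     for summary, as is conventional for these counts),
#'   * `totals`: tibble with one row per agent: total errors at each trial
#'     type and the number of completed stages,
#'   * call metadata (`alpha`, `params`, `n_agents`, `seed`, `sign_term`).
#'
#' @examples
#' sim <- run_reversal_experiment(alpha = 0.5, n_agents = 20, seed = 1)
#' tidy(sim)
#' @export
run_reversal_experiment <- function(alpha = reversal_alpha[["balanced"]],
                                    params = default_agent_params("reversal"),
                                    n_agents = 100, seed = 1,
                                    sign_term = TRUE, n_blocks = 4,
                                    max_stages = 16, max_trials = 120,
                                    criterion_range = 5:9) {
  validate_agent_params(params)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    abort("`alpha` must be a single number >= 0.")
  }
  if (n_agents < 1) abort("`n_agents` must be >= 1.")
  criterion_range <- as.integer(criterion_range)
  conds <- c("rewarding-first", "punishing-first")

  rows <- vector("list", n_agents)
  totals <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    set.seed(agent_seed(seed, i))
    tally <- matrix(0, 2L, 2L)  # condition x trial type (reward, punish)
    stages_done_total <- 0L
    for (block in seq_len(n_blocks)) {
      cond <- if (block %% 2L == 1L) 1L else 2L
      q <- 0
      h <- matrix(0, 2L, 2L)
      rewarding <- sample(1:2, 1L)
      target <- sample(criterion_range, 1L)
      correct_in_stage <- 0L
      trial_in_stage <- 0L
      n_stages_done <- 0L
      first_stage <- TRUE
      forced_stim <- NA_integer_
      prev_err_stim <- NA_integer_
      for (trial in seq_len(max_trials)) {
        stim <- if (!is.na(prev_err_stim)) prev_err_stim else
          if (!is.na(forced_stim)) forced_stim else sample(1:2, 1L)
        forced_stim <- NA_integer_
        trial_in_stage <- trial_in_stage + 1L
        st <- run_reversal_trial(q, h, stim, rewarding, alpha,
                                 beta = params$beta, eta_q = params$eta_q,
                                 eta_h = params$eta_h,
                                 sign_term = sign_term)
        q <- st$q
        h <- st$h
        if ((first_stage || trial_in_stage >= 3L) && !st$correct) {
          type <- if (stim == rewarding) 1L else 2L
          tally[cond, type] <- tally[cond, type] + 1
        }
        prev_err_stim <- if (!st$correct) stim else NA_integer_
        if (st$correct) {
          correct_in_stage <- correct_in_stage + 1L
          if (correct_in_stage >= target) {
            rewarding <- 3L - rewarding
            n_stages_done <- n_stages_done + 1L
            if (n_stages_done >= max_stages) break
            first_stage <- FALSE
            target <- sample(criterion_range, 1L)
            correct_in_stage <- 0L
            trial_in_stage <- 0L
            forced_stim <- if (cond == 1L) rewarding else 3L - rewarding
          }
        }
      }
      stages_done_total <- stages_done_total + n_stages_done
    }
    rows[[i]] <- tibble(
      agent = i,
      condition = rep(conds, times = 2L),
      trial_type = rep(c("reward", "punishment"), each = 2L),
      errors = c(tally[, 1L], tally[, 2L]),
      sqrt_errors = sqrt(c(tally[, 1L], tally[, 2L]))
    )
    totals[[i]] <- tibble(
      agent = i,
      errors_reward = sum(tally[, 1L]),
      errors_punishment = sum(tally[, 2L]),
      errors_total = sum(tally),
      stages_completed = stages_done_total
    )
  }

  structure(list(
    agents = dplyr::bind_rows(rows),
    totals = dplyr::bind_rows(totals),
    alpha = alpha, params = params, n_agents = n_agents, seed = seed,
    sign_term = sign_term
  ), class = "reversal_sim")
}

#' @export
print.reversal_sim <- function(x, ...) {
  cat(sprintf("<reversal_sim> %d agents, alpha = %g, sign term: %s\n",
              x$n_agents, x$alpha, x$sign_term))
  cat(sprintf(
    "  mean errors: %.1f reward trials, %.1f punishment trials\n",
    mean(x$totals$errors_reward), mean(x$totals$errors_punishment)))
  invisible(x)
}
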