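## Delayed-reward patch-clearing task: two panels of coloured patches are
## presented side by side.  Each peck at a panel removes a random number of
## its patches; when a panel is fully cleared its reward is delivered and
## the trial ends.  The white panel is small and pays little (cleared
## quickly); the yellow panel is large and pays more (cleared slowly), so
## preferring yellow means tolerating a longer delay.  State is the number
## of patches remaining on a panel; learning uses the discounted TD rule.

#' Panel definitions for the patch-clearing task
#'
#' @return A tibble with one row per panel: `panel`, `initial_mean` and
#'   `initial_spread` (starting patch count is an integer drawn uniformly
#'   from mean +/- spread), and `reward` delivered when the panel is
#'   cleared.
#' @examples
#' delayed_panels()
#' @export
delayed_panels <- function() {
  tibble(
    panel = c("white", "yellow"),
    initial_mean = c(18L, 72L),
    initial_spread = c(9L, 24L),
    reward = c(1, 4)
  )
}

#' Trial schedule of the patch-clearing task
#'
#' Each block ("pass") consists of eight trial types that cross slow/fast
#' clearing rates of the two panels.  The removal rate is the mean number
#' of patches removed per peck; each peck removes that mean +/- 2 patches
#' (integer uniform).
#'
#' @return A tibble with columns `trial` (1-8), `removal_white`, and
#'   `removal_yellow`.
#' @examples
#' delayed_schedule()
#' @export
delayed_schedule <- function() {
  tibble(
    trial = 1:8,
    removal_white = c(6L, 6L, 6L, 6L, 6L, 6L, 14L, 14L),
    removal_yellow = c(8L, 8L, 8L, 8L, 16L, 16L, 8L, 16L)
  )
}

#' Draw integer counts uniformly from mean +/- spread
#'
#' Used for both initial patch counts and per-peck removals.  Draws are
#' integer uniform on `[mean - spread, mean + spread]`, floored at `min`.
#'
#' @param mean,spread Integer centre and half-width.
#' @param n Number of draws.
#' @param min Lower floor applied after sampling.
#' @return Integer vector of `n` counts.
#' @examples
#' set.seed(1)
#' sample_count(6, 2, n = 5)
#' @export
sample_count <- function(mean, spread, n = 1, min = 1L) {
  check_finite(mean, "mean")
  check_finite(spread, "spread")
  if (any(spread < 0)) abort("`spread` must be >= 0.")
  lo <- as.integer(round(mean - spread))
  wid <- as.integer(round(2 * spread)) + 1L
  pmax(lo + as.integer(floor(runif(n) * wid)), as.integer(min))
}

#' Simulate the patch-clearing task
#'
#' Runs agents through `n_passes` blocks of the eight-trial schedule,
#' learning from scratch.  On every peck the agent previews the state each
#' panel would reach if pecked (current patches minus a fresh removal
#' draw), scores both prospects by sign-dependent utility — adding the
#' panel's reward when the prospect is full clearance — and picks a panel
#' by softmax.  Only the pecked panel advances.  The pecked panel's value
#' and risk tables are updated with the discounted TD rule
#' (`delta = r + gamma * Q(next) - Q(current)`, terminal `Q(next) = 0`);
#' clearing delivers the panel reward and ends the trial.
#'
#' Choice behaviour is measured during learning: the recorded choice of a
#' trial is the panel the agent ultimately cleared.  All agents advance in
#' lockstep from one run-level RNG stream seeded with `seed`.
#'
#' @param alpha Risk weight.
#' @param gamma Discount factor in `[0, 1)`; lower values discount the
#'   yellow panel's longer clearance time more steeply.
#' @param params Remaining [agent_params()]; `alpha` and `gamma` fields
#'   are overridden by the arguments above.
#' @param n_agents Number of agents.
#' @param n_passes Blocks of the eight-trial schedule per agent.
#' @param seed Run-level seed.
#' @param max_steps Safety cap on pecks per trial (never reached under the
#'   default panels; an uncleared trial is recorded as no choice).
#'
#' @return A `delayed_sim` object with elements
#'   * `choice`: tibble of per-(pass, trial-type) yellow-clearance
#'     frequencies with the schedule's removal rates attached,
#'   * `p_yellow`: overall fraction of trials cleared on the yellow panel,
#'   * `values`: tibble of final population-mean Q and h per panel and
#'     patches-remaining state,
#'   * `incomplete`: number of trials that hit `max_steps` uncleared,
#'   * call metadata (`alpha`, `gamma`, `params`, `n_agents`, `n_passes`,
#'     `seed`).
#'
#' @examples
#' sim <- run_delayed_experiment(alpha = 1, gamma = 0.7, n_agents = 200)
#' sim$p_yellow
#' @export
run_delayed_experiment <- function(alpha, gamma,
                                   params = default_agent_params("delayed"),
                                   n_agents = 1000, n_passes = 4, seed = 1,
                                   max_steps = 400) {
  validate_agent_params(params)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    abort("`alpha` must be a single number >= 0.")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1) {
    abort("`gamma` must be in [0, 1).")
  }
  if (n_agents < 1) abort("`n_agents` must be >= 1.")
  if (n_passes < 1) abort("`n_passes` must be >= 1.")
  panels <- delayed_panels()
  sched <- delayed_schedule()
  beta <- params$beta
  eta_q <- params$eta_q
  eta_h <- params$eta_h
  rw <- panels$reward[1L]
  ry <- panels$reward[2L]
  ## state tables indexed by patches remaining + 1 (state 0 = exposed)
  n_sw <- panels$initial_mean[1L] + panels$initial_spread[1L] + 1L
  n_sy <- panels$initial_mean[2L] + panels$initial_spread[2L] + 1L

  set.seed(seed)
  Qw <- matrix(0, n_agents, n_sw); Hw <- matrix(0, n_agents, n_sw)
  Qy <- matrix(0, n_agents, n_sy); Hy <- matrix(0, n_agents, n_sy)
  choice_tab <- matrix(0, n_passes, 8L)  # yellow clearances
  done_tab <- matrix(0, n_passes, 8L)    # cleared trials
  incomplete <- 0L

  for (pass in seq_len(n_passes)) {
    for (tr in 1:8) {
      sw <- sample_count(panels$initial_mean[1L], panels$initial_spread[1L],
                         n_agents)
      sy <- sample_count(panels$initial_mean[2L], panels$initial_spread[2L],
                         n_agents)
      act <- rep(TRUE, n_agents)
      choice <- integer(n_agents)
      for (step in seq_len(max_steps)) {
        ia <- which(act)
        if (length(ia) == 0L) break
        n <- length(ia)
        dw <- sample_count(sched$removal_white[tr], 2L, n)
        dy <- sample_count(sched$removal_yellow[tr], 2L, n)
        nw <- pmax(sw[ia] - dw, 0L)
        ny <- pmax(sy[ia] - dy, 0L)
        ## prospective utilities of the post-peck states; clearing adds
        ## the panel reward to the terminal state's (zero) tables
        iw_next <- cbind(ia, nw + 1L)
        iy_next <- cbind(ia, ny + 1L)
        Uw <- (nw == 0L) * rw +
          Qw[iw_next] - alpha * sign(Qw[iw_next]) * sqrt(Hw[iw_next])
        Uy <- (ny == 0L) * ry +
          Qy[iy_next] - alpha * sign(Qy[iy_next]) * sqrt(Hy[iy_next])
        ch <- runif(n) < 1 / (1 + exp(-beta * (Uy - Uw)))
        iy <- ia[ch]; iw <- ia[!ch]
        if (length(iy)) {
          s0 <- sy[iy]; s1 <- ny[ch]
          r <- (s1 == 0L) * ry
          i0 <- cbind(iy, s0 + 1L)
          qn <- ifelse(s1 == 0L, 0, Qy[cbind(iy, s1 + 1L)])
          d <- r + gamma * qn - Qy[i0]
          Hy[i0] <- Hy[i0] + eta_h * (d^2 - Hy[i0])
          Qy[i0] <- Qy[i0] + eta_q * d
          sy[iy] <- s1
          dn <- iy[s1 == 0L]
          act[dn] <- FALSE; choice[dn] <- 2L
        }
        if (length(iw)) {
          s0 <- sw[iw]; s1 <- nw[!ch]
          r <- (s1 == 0L) * rw
          i0 <- cbind(iw, s0 + 1L)
          qn <- ifelse(s1 == 0L, 0, Qw[cbind(iw, s1 + 1L)])
          d <- r + gamma * qn - Qw[i0]
          Hw[i0] <- Hw[i0] + eta_h * (d^2 - Hw[i0])
          Qw[i0] <- Qw[i0] + eta_q * d
          sw[iw] <- s1
          dn <- iw[s1 == 0L]
          act[dn] <- FALSE; choice[dn] <- 1L
        }
      }
      incomplete <- incomplete + sum(act)
      choice_tab[pass, tr] <- sum(choice == 2L)
      done_tab[pass, tr] <- sum(choice > 0L)
    }
  }

  choice <- tibble(
    pass = rep(seq_len(n_passes), each = 8L),
    trial = rep(1:8, times = n_passes),
    removal_white = rep(sched$removal_white, times = n_passes),
    removal_yellow = rep(sched$removal_yellow, times = n_passes),
    n_cleared = as.vector(t(done_tab)),
    p_yellow = as.vector(t(choice_tab)) /
      pmax(as.vector(t(done_tab)), 1L)
  )
  values <- dplyr::bind_rows(
    tibble(panel = "white", patches = seq_len(n_sw) - 1L,
           q_mean = colMeans(Qw), h_mean = colMeans(Hw)),
    tibble(panel = "yellow", patches = seq_len(n_sy) - 1L,
           q_mean = colMeans(Qy), h_mean = colMeans(Hy))
  )
  structure(list(
    choice = choice,
    p_yellow = sum(choice_tab) / max(sum(done_tab), 1L),
    values = values,
    incomplete = incomplete,
    alpha = alpha, gamma = gamma, params = params,
    n_agents = n_agents, n_passes = n_passes, seed = seed
  ), class = "delayed_sim")
}

#' Utility profile over patches remaining
#'
#' Evaluates the sign-dependent utility of each (panel, patches-remaining)
#' state from a simulation's final population-mean value and risk tables,
#' using the simulation's own `alpha` by default.  Useful for inspecting
#' why one panel out-competes the other at the point of choice.
#'
#' @param sim A `delayed_sim` from [run_delayed_experiment()].
#' @param alpha Risk weight to evaluate at; defaults to the one simulated.
#' @return `sim$values` with a `utility` column appended.
#' @examples
#' sim <- run_delayed_experiment(alpha = 1, gamma = 0.7, n_agents = 100)
#' head(utility_difference_profile(sim))
#' @export
utility_difference_profile <- function(sim, alpha = sim$alpha) {
  if (!inherits(sim, "delayed_sim")) abort("`sim` must be a `delayed_sim`.")
  out <- sim$values
  out$utility <- utility(out$q_mean, out$h_mean, alpha)
  out
}

#' Sweep the patch-clearing task over alpha and gamma
#'
#' Runs [run_delayed_experiment()] on the full grid of the supplied risk
#' weights and discount factors, reusing the same seed so all cells share
#' random numbers.
#'
#' @param alphas,gammas Numeric vectors defining the grid.
#' @param ... Passed on to [run_delayed_experiment()].
#' @return A tibble with columns `alpha`, `gamma`, `p_yellow`.
#' @examples
#' run_delayed_sweep(alphas = c(0, 2), gammas = 0.7, n_agents = 100)
#' @export
run_delayed_sweep <- function(alphas = c(0, 0.5, 1, 1.5, 2),
                              gammas = c(0.5, 0.6, 0.7), ...) {
  grid <- tidyr::expand_grid(alpha = alphas, gamma = gammas)
  grid$p_yellow <- purrr::pmap_dbl(grid, function(alpha, gamma) {
    run_delayed_experiment(alpha = alpha, gamma = gamma, ...)$p_yellow
  })
  grid
}

#' @export
print.delayed_sim <- function(x, ...) {
  cat(sprintf(
    "<delayed_sim> %d agents x %d passes, alpha = %g, gamma = %g\n",
    x$n_agents, x$n_passes, x$alpha, x$gamma))
  cat(sprintf("  P(clear yellow) = %.3f\n", x$p_yellow))
  invisible(x)
}
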