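test_that("enforce_complementarity projects onto the constrained subspace", {
  expect_equal(enforce_complementarity(matrix(c(1, 0, 0, 0), 2, 2)),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2))
  q <- matrix(c(0.6, -0.6, -0.6, 0.6), 2, 2)
  expect_equal(enforce_complementarity(q), q)   # fixed point
  set.seed(TEST_SEED)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm(4), 2, 2)
    p <- enforce_complementarity(m)
    expect_equal(enforce_complementarity(p), p)  # idempotent
    expect_equal(p[1, 1], -p[1, 2])
    expect_equal(p[1, 1], -p[2, 1])
    expect_equal(p[1, 1], p[2, 2])
  }
  expect_error(enforce_complementarity(matrix(0, 3, 3)), "2 x 2")
})

test_that("a single trial selects, scores and updates as documented", {
  ## near-greedy agent with q = 0.5 on the rewarding stimulus
  set.seed(TEST_SEED)
  out <- run_reversal_trial(q = 0.5, h = matrix(0, 2, 2), stim = 1,
                            rewarding = 1, alpha = 0, beta = 100)
  expect_equal(out$action, 1L)
  expect_true(out$correct)
  expect_equal(out$reward, 1)
  expect_equal(out$q, 0.5 + 0.1 * (1 - 0.5))
  expect_equal(out$h[1, 1], 0.1 * (1 - 0.5)^2)
  expect_equal(out$h[2, ], c(0, 0))
  ## mirrored stimulus: same q, opposite table row
  set.seed(TEST_SEED)
  out2 <- run_reversal_trial(q = 0.5, h = matrix(0, 2, 2), stim = 2,
                             rewarding = 1, alpha = 0, beta = 100)
  expect_equal(out2$action, 2L)   # avoid the punishing stimulus
  expect_true(out2$correct)
  expect_equal(out2$q, out$q)
  expect_error(run_reversal_trial(0, matrix(0, 2, 2), 3, 1, 0.5), "stim")
  expect_error(run_reversal_trial(0, matrix(-1, 2, 2), 1, 1, 0.5), "h")
})

test_that("complementarity identities hold after every update", {
  set.seed(TEST_SEED)
  q <- 0
  h <- matrix(0, 2, 2)
  for (t in 1:200) {
    st <- run_reversal_trial(q, h, stim = sample(1:2, 1),
                             rewarding = sample(1:2, 1),
                             alpha = 0.5, beta = 10)
    q <- st$q
    h <- st$h
    full_q <- matrix(c(q, -q, -q, q), 2, 2)
    expect_equal(enforce_complementarity(full_q), full_q)
    expect_true(all(h >= 0))
    expect_true(abs(q) <= 1)  # rewards are +/-1, so |q| stays below 1
  }
})

test_that("experiments are reproducible and agents independent of batch size", {
  a <- run_reversal_experiment(n_agents = 6, seed = TEST_SEED)
  b <- run_reversal_experiment(n_agents = 6, seed = TEST_SEED)
  expect_equal(a$agents, b$agents)
  small <- run_reversal_experiment(n_agents = 3, seed = TEST_SEED)
  expect_equal(small$agents, dplyr::filter(a$agents, agent <= 3))
})

test_that("tallies are internally consistent", {
  sim <- run_reversal_experiment(n_agents = 10, seed = TEST_SEED)
  expect_equal(nrow(sim$agents), 10 * 4)
  expect_equal(sim$agents$sqrt_errors, sqrt(sim$agents$errors))
  by_agent <- summarize_agents(sim$agents, "errors", "agent")
  expect_equal(by_agent$mean * 4, sim$totals$errors_total)
  expect_equal(sim$totals$errors_reward + sim$totals$errors_punishment,
               sim$totals$errors_total)
  expect_true(all(sim$totals$stages_completed <= 4 * 16))
  expect_true(all(sim$totals$stages_completed > 0))
  expect_equal(nrow(glance(sim)), 1)
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
})

test_that("lowering the risk weight reduces total errors (paired agents)", {
  hi <- run_reversal_experiment(alpha = 0.5, n_agents = 50,
                                seed = TEST_SEED)
  lo <- run_reversal_experiment(alpha = 0.3, n_agents = 50,
                                seed = TEST_SEED)
  drop <- hi$totals$errors_total - lo$totals$errors_total
  expect_gt(mean(drop), 5)
})

test_that("the no-sign variant runs and still tallies coherently", {
  sim <- run_reversal_experiment(alpha = 0.5, n_agents = 10,
                                 seed = TEST_SEED, sign_term = FALSE)
  expect_false(sim$sign_term)
  expect_true(all(is.finite(sim$agents$errors)))
  expect_true(all(sim$agents$errors >= 0))
})
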