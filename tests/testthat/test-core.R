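test_that("immediate TD error is reward minus prediction", {
  expect_equal(td_error_immediate(1, 0), 1)
  expect_equal(td_error_immediate(150 - 193.2, 0), -43.2)
  expect_equal(td_error_immediate(c(1, 3), c(0.5, 1)), c(0.5, 2))
  expect_error(td_error_immediate(NA, 0), "finite")
})

test_that("discounted TD error bootstraps on the successor value", {
  expect_equal(td_error_discounted(0, 2, 1, 0.5), 0)
  expect_equal(td_error_discounted(4, 0, 0, 0.7), 4)
  expect_equal(td_error_discounted(1, 2, 0.5, 0.9), 1 + 1.8 - 0.5)
  expect_error(td_error_discounted(1, 0, 0, 1), "gamma")
  expect_error(td_error_discounted(1, 0, 0, -0.1), "gamma")
})

test_that("value update moves a fraction eta_q along delta", {
  expect_equal(update_value(0, 1, 0.1), 0.1)
  expect_equal(update_value(2, -1, 0.5), 1.5)
  expect_error(update_value(0, 1, 0), "eta_q")
  expect_error(update_value(0, 1, 1), "eta_q")
})

test_that("risk error and update track squared TD errors", {
  expect_equal(risk_error(-2, 1), 3)
  expect_equal(risk_error(0, 0.5), -0.5)
  expect_error(risk_error(1, -0.1), ">= 0")
  expect_equal(update_risk(1, risk_error(2, 1), 0.1), 1 + 0.1 * 3)
  expect_error(update_risk(-1, 0, 0.1), ">= 0")
  ## an xi inconsistent with the h it is applied to is rejected
  expect_error(update_risk(0.1, -10, 0.5), "negative")
})

test_that("property: risk estimates stay non-negative along any trajectory", {
  set.seed(TEST_SEED)
  for (rep in 1:20) {
    h <- 0
    deltas <- stats::rnorm(200, sd = runif(1, 0.1, 5))
    eta <- runif(1, 0.01, 0.99)
    for (d in deltas) {
      h <- update_risk(h, risk_error(d, h), eta)
      expect_gte(h, 0)
    }
  }
})

test_that("utility is risk-averse in gains and risk-seeking in losses", {
  expect_equal(utility(1, 0.25, 1.5), 0.25)
  expect_equal(utility(-1, 0.25, 1.5), -0.25)
  expect_equal(utility(3, 0.25, 0), 3)      # classical limit
  expect_equal(utility(0, 4, 2), 0)         # sign(0) = 0
  expect_equal(utility(1, 0.25, 1.5, risk_transform = "identity"),
               1 - 1.5 * 0.25)
  ## gain/loss sign-flip: U(-q, h) = -U(q, h)
  set.seed(TEST_SEED)
  q <- stats::rnorm(50); h <- runif(50, 0, 3); a <- runif(50, 0, 2)
  expect_equal(utility(-q, h, a), -utility(q, h, a))
})

test_that("softmax probabilities are normalised, shift-invariant and stable", {
  expect_equal(softmax_probs(c(1, 1, 1), 5), rep(1 / 3, 3))
  expect_equal(softmax_probs(c(3, -2, 7), 0), rep(1 / 3, 3))
  set.seed(TEST_SEED)
  for (rep in 1:20) {
    u <- stats::rnorm(sample(2:6, 1), sd = 10)
    b <- runif(1, 0, 5)
    p <- softmax_probs(u, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(softmax_probs(u + 123.4, b), p)  # shift invariance
  }
  ## no overflow for huge utilities
  expect_equal(softmax_probs(c(1e6, 0), 10), c(1, 0))
})

test_that("sample_action draws from the supplied distribution", {
  expect_error(sample_action(c(0.5, 0.4)), "sum to 1")
  expect_error(sample_action(c(1.5, -0.5)), "sum to 1")
  set.seed(TEST_SEED)
  draws <- replicate(5000, sample_action(c(0.2, 0.5, 0.3)))
  expect_true(all(draws %in% 1:3))
  freq <- tabulate(draws, 3) / 5000
  expect_equal(freq, c(0.2, 0.5, 0.3), tolerance = 0.05)
  ## degenerate distribution is deterministic
  expect_true(all(replicate(20, sample_action(c(0, 1, 0))) == 2L))
})

test_that("oracle: value and risk converge to the mean and variance of reward", {
  ## rewards 3 w.p. 1/3 else 0: mean 1, Var = E[(r - 1)^2] = 2.  A single
  ## final estimate fluctuates with sd ~ sqrt(eta * Var / 2), so the
  ## stationary mean is estimated by time-averaging the second half of a
  ## long run.
  set.seed(TEST_SEED)
  q <- 0; h <- 0
  q_acc <- 0; h_acc <- 0
  for (t in 1:1e5) {
    r <- if (runif(1) < 1 / 3) 3 else 0
    d <- td_error_immediate(r, q)
    h <- update_risk(h, risk_error(d, h), 0.01)
    q <- update_value(q, d, 0.01)
    if (t > 5e4) {
      q_acc <- q_acc + q
      h_acc <- h_acc + h
    }
  }
  expect_equal(q_acc / 5e4, 1, tolerance = 0.05)
  expect_equal(h_acc / 5e4, 2, tolerance = 0.15)
})

test_that("oracle: discounted updates converge to the analytic chain values", {
  ## deterministic chain s1 -> s2 -> terminal, reward 4 on the final
  ## transition, gamma = 0.7: Q(s2) = 4, Q(s1) = 0.7 * 4 = 2.8
  q1 <- 0; q2 <- 0
  for (t in 1:2000) {
    q1 <- update_value(q1, td_error_discounted(0, q2, q1, 0.7), 0.1)
    q2 <- update_value(q2, td_error_discounted(4, 0, q2, 0.7), 0.1)
  }
  expect_equal(q2, 4, tolerance = 1e-6)
  expect_equal(q1, 2.8, tolerance = 1e-6)
})
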