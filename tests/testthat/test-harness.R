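write_cfg <- function(...) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("load_config validates structure and fills defaults", {
  cfg <- load_config(write_cfg("experiment: bee"))
  expect_s3_class(cfg, "rsrl_config")
  expect_equal(cfg$seed, 1L)
  expect_equal(cfg$n_agents, 100L)
  cfg2 <- load_config(write_cfg(
    "experiment: rtd", "seed: 7", "n_agents: 12",
    "params:", "  alpha: 0.5", "task:", "  n_per_state: 20"))
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$params$alpha, 0.5)
  expect_equal(cfg2$task$n_per_state, 20)
  expect_error(load_config(write_cfg("experiment: zzz")), "experiment")
  expect_error(load_config(write_cfg("experiment: bee", "frobnicate: 1")),
               "unknown config key")
  expect_error(load_config(write_cfg("experiment: bee", "params:",
                                     "  alphaa: 1")),
               "unknown params key")
  expect_error(load_config("/no/such/file.yaml"), "not found")
})

test_that("run_experiment dispatches with merged parameters", {
  bee <- run_experiment(load_config(write_cfg(
    "experiment: bee", "n_agents: 10", "seed: 3")))
  expect_s3_class(bee, "bee_sim")
  expect_equal(bee$n_agents, 10)
  expect_equal(bee$seed, 3L)
  expect_equal(bee$params$eta_q, 0.001)  # bee default kept

  rtd <- run_experiment(load_config(write_cfg(
    "experiment: rtd", "n_agents: 4",
    "params:", "  alpha: 1.658",
    "task:", "  n_per_state: 10")))
  expect_s3_class(rtd, "rtd_sim")
  expect_equal(rtd$alpha, 1.658)
  expect_equal(rtd$n_per_state, 10)

  del <- run_experiment(load_config(write_cfg(
    "experiment: delayed", "n_agents: 20",
    "params:", "  gamma: 0.5", "task:", "  n_passes: 1")))
  expect_s3_class(del, "delayed_sim")
  expect_equal(del$gamma, 0.5)
  expect_equal(del$n_passes, 1)

  rev <- run_experiment(load_config(write_cfg(
    "experiment: reversal", "n_agents: 3",
    "params:", "  alpha: 0.3")))
  expect_s3_class(rev, "reversal_sim")
  expect_equal(rev$alpha, 0.3)

  ## a config run equals the direct call with the same arguments
  direct <- run_bee_experiment(n_agents = 10, seed = 3)
  expect_equal(tidy(bee), tidy(direct))
  expect_error(run_experiment(list(experiment = "bee")), "load_config")
  expect_error(run_experiment(load_config(write_cfg(
    "experiment: bee", "task:", "  bogus_option: 1"))))
})

test_that("summarize_agents computes mean, SE and n per group", {
  out <- summarize_agents(tibble::tibble(g = c("a", "a", "b"),
                                         x = c(1, 3, 5)),
                          value = "x", by = "g")
  expect_equal(out$mean, c(2, 5))
  expect_equal(out$se, c(sd(c(1, 3)) / sqrt(2), 0))  # SE = 0 for n = 1
  expect_equal(out$n, c(2L, 1L))
  ## NA values are dropped
  out2 <- summarize_agents(tibble::tibble(x = c(1, NA, 3)), "x")
  expect_equal(out2$mean, 2)
  expect_equal(out2$n, 2L)
  ## SE shrinks like 1/sqrt(n): replicating the sample 4-fold roughly
  ## halves it (exactly, up to the n-1 sample-variance correction)
  x <- c(2, 4, 6, 9)
  one <- summarize_agents(tibble::tibble(x = x), "x")
  four <- summarize_agents(tibble::tibble(x = rep(x, 4)), "x")
  expect_equal(four$se, sd(rep(x, 4)) / sqrt(16))
  expect_equal(four$se / one$se, sqrt(12 / 15) / 2)
  expect_error(summarize_agents(tibble::tibble(x = 1), "y"), "not found")
  expect_error(summarize_agents(tibble::tibble(x = 1), "x", by = "g"),
               "grouping")
})

test_that("summarize_experiment covers every simulation class", {
  for (sim in list(
    run_bee_experiment(n_agents = 10, seed = TEST_SEED),
    run_rtd_experiment(n_agents = 4, n_per_state = 10, seed = TEST_SEED),
    run_delayed_experiment(alpha = 1, gamma = 0.7, n_agents = 20,
                           n_passes = 1, seed = TEST_SEED),
    run_reversal_experiment(n_agents = 3, seed = TEST_SEED))) {
    out <- summarize_experiment(sim)
    expect_named(out, c("condition", "statistic", "mean", "se", "n"))
    expect_gt(nrow(out), 0)
    expect_true(all(out$se >= 0))
  }
})

test_that("write_results emits the documented CSV schema", {
  sim <- run_reversal_experiment(n_agents = 5, seed = TEST_SEED)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_results(sim, path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_named(back, c("experiment", "condition", "statistic", "mean",
                       "se", "n", "seed", "alpha", "beta", "gamma",
                       "eta_q", "eta_h"))
  expect_equal(back$experiment, rep("reversal", nrow(back)))
  expect_equal(back$alpha, rep(0.5, nrow(back)))
  expect_equal(back$mean, out$mean)
  expect_error(write_results(list(), path), "not a recognised")
})

test_that("the genetic algorithm recovers a known optimum", {
  fit <- fit_parameters(function(p) (p[["x"]] - 0.7)^2,
                        lower = c(x = 0), upper = c(x = 1),
                        control = ga_control(generations = 30),
                        seed = TEST_SEED)
  expect_equal(unname(fit$par), 0.7, tolerance = 0.01)
  expect_lt(fit$value, 1e-4)
  expect_equal(nrow(fit$history), 30)
  expect_true(all(diff(vapply(seq_len(29), function(g)
    min(fit$history$best[seq_len(g)]), numeric(1))) <= 0))

  ## two dimensions with different scales
  fit2 <- fit_parameters(
    function(p) (p[["a"]] - 2)^2 + (p[["b"]] + 5)^2,
    lower = c(a = 0, b = -10), upper = c(a = 4, b = 0),
    control = ga_control(generations = 40), seed = TEST_SEED)
  expect_equal(unname(fit2$par), c(2, -5), tolerance = 0.05)

  expect_error(fit_parameters("no", c(x = 0), c(x = 1)), "function")
  expect_error(fit_parameters(identity, c(x = 1), c(x = 0)), "lower")
  expect_error(fit_parameters(function(p) NA_real_,
                              c(x = 0), c(x = 1),
                              ga_control(generations = 1)), "finite")
  expect_error(ga_control(pop_size = 1), "pop_size")
  expect_error(ga_control(elitism = 50), "elitism")
})
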