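test_that("log-likelihood equals the brute-force Bernoulli product", {
  y <- c(1L, 0L, 1L, 1L, 0L)
  pars <- agent_params(.35, .8, .25)
  p <- rw_trajectory(pars, 5)
  brute <- log(prod(ifelse(y == 1, p, 1 - p)))
  expect_equal(loglik_subject(y, pars), brute, tolerance = 1e-12)
})

test_that("log-likelihood limits behave", {
  # p(t) == 0.5 throughout
  expect_equal(loglik_subject(rep(1L, 20), agent_params(0, .5, .5)),
               20 * log(0.5))
  # saturated: certain avoidance predicted and observed
  ll <- loglik_subject(rep(1L, 30),
                       agent_params(.5, 1 - 1e-9, 1 - 1e-9))
  expect_gt(ll, -1e-6)
  expect_error(loglik_subject(c(0L, 2L), agent_params(.3, .8, .1)),
               "binary")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(2)
  good <- matrix(rnorm(5000 * 4), 5000, 4)
  r <- split_rhat(good)
  expect_gt(r, 0.999)
  expect_lt(r, 1.01)

  bad <- cbind(rnorm(1000), rnorm(1000) + 10)
  expect_gt(split_rhat(bad), 1.5)

  expect_error(split_rhat(matrix(1, 100, 4)), "constant")
})

test_that("prior-only sampling reproduces the prior moments", {
  tab <- toy_table(list(s1 = rep(1L, 10)))
  spec <- hier_model_spec(pooled = FALSE, prior_only = TRUE)
  post <- sample_posterior(tab, spec, chains = 2, iterations = 800,
                           warmup = 300, seed = 3, sweeps = 2)
  draws <- as.vector(post$draws[, , "beta[s1]"])
  set.seed(4)
  oracle <- plogis(rnorm(2e5, 0, 1.5))  # prior pushforward
  expect_equal(mean(draws), mean(oracle), tolerance = 0.05)
  expect_equal(sd(draws), sd(oracle), tolerance = 0.1)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("posterior sampling is deterministic given the seed", {
  tab <- small_cohort(n = 3, sessions = 1, seed = 6)
  p1 <- sample_posterior(tab, chains = 2, iterations = 150, warmup = 50,
                         seed = 8, sweeps = 2)
  p2 <- sample_posterior(tab, chains = 2, iterations = 150, warmup = 50,
                         seed = 8, sweeps = 2)
  expect_identical(p1$draws, p2$draws)
  p3 <- sample_posterior(tab, chains = 2, iterations = 150, warmup = 50,
                         seed = 9, sweeps = 2)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("posterior summaries carry diagnostics for every parameter", {
  tab <- small_cohort(n = 3, sessions = 1, seed = 26)
  post <- sample_posterior(tab, chains = 2, iterations = 300, warmup = 100,
                           seed = 2, sweeps = 2)
  s <- tidy(post)
  expect_true(all(c("rhat", "ess", "q2.5", "q97.5") %in% names(s)))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_true(all(is.finite(s$rhat)))
  g <- glance(post)
  expect_identical(g$n_parameters, nrow(s))
})

test_that("credible intervals for beta contract with more trials", {
  width_for <- function(sessions, seed) {
    groups <- list(g = list(n = 1, params = agent_params(.3, .75, .15)))
    tab <- simulate_cohort(cohort_spec(
      groups, std_schedule(sessions, seed), seed = seed))
    spec <- hier_model_spec(pooled = FALSE)
    post <- sample_posterior(tab, spec, chains = 2, iterations = 1500,
                             warmup = 500, seed = 5, sweeps = 4)
    s <- tidy(post)
    b <- s[s$parameter == "beta[g_01]", ]
    b$q97.5 - b$q2.5
  }
  expect_lt(width_for(20, 44), width_for(5, 44) * 0.9)
})

test_that("group comparison detects the parameter that differs", {
  sched <- std_schedule(5, seed = 51)
  groups <- list(
    hi = list(n = 6, params = agent_params(.3, .85, .2), jitter = 0.03),
    lo = list(n = 6, params = agent_params(.3, .55, .2), jitter = 0.03))
  spec <- cohort_spec(groups, sched, seed = 52)
  tab <- simulate_cohort(spec)
  # identity link so the likelihood is well-specified
  truth <- attr(tab, "truth")
  blocks <- purrr::map(seq_len(nrow(truth)), function(i) {
    rec <- simulate_agent(
      agent_params(truth$alpha[i], truth$beta[i], truth$v1[i]),
      sched, seed = 100 + i, link = "identity")
    dplyr::mutate(rec, subject_id = truth$subject_id[i],
                  group = truth$group[i], .before = 1)
  })
  tab <- dplyr::bind_rows(blocks)
  post <- sample_posterior(tab, chains = 2, iterations = 800, warmup = 400,
                           seed = 53, sweeps = 6)
  cmp <- compare_groups(post)
  beta_row <- cmp[cmp$parameter == "beta", ]
  expect_gt(beta_row$mean_diff, 0.1)
  expect_gt(beta_row$q2.5, 0)           # CI excludes zero
  alpha_row <- cmp[cmp$parameter == "alpha", ]
  expect_true(alpha_row$q2.5 < 0 & alpha_row$q97.5 > 0)
})

test_that("single-group models refuse group comparison", {
  tab <- small_cohort(n = 3, sessions = 1, seed = 61)
  post <- sample_posterior(tab, chains = 2, iterations = 150, warmup = 50,
                           seed = 1, sweeps = 2)
  expect_error(compare_groups(post), "single group")
})
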