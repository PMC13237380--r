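test_that("trajectory follows the recursion by hand", {
  expect_equal(rw_trajectory(agent_params(.5, .8, .2), 3),
               c(0.2, 0.5, 0.65))
  expect_equal(rw_trajectory(agent_params(0, .8, .3), 5), rep(0.3, 5))
  expect_equal(rw_trajectory(agent_params(.4, .6, .6), 4), rep(0.6, 4))
  expect_equal(rw_trajectory(agent_params(1, .9, .1), 3)[2:3], c(.9, .9))
})

test_that("closed form matches the iteration", {
  p <- agent_params(.5, .8, .2)
  expect_equal(rw_closed_form(p, 3), 0.8 - 0.6 * 0.25)  # 0.65
  expect_equal(rw_closed_form(p, 1), 0.2)
  set.seed(99)
  for (i in 1:200) {
    pars <- agent_params(runif(1), runif(1), runif(1))
    n <- sample(2:500, 1)
    expect_lt(max(abs(rw_trajectory(pars, n) -
                        rw_closed_form(pars, seq_len(n)))), 1e-12)
  }
})

test_that("the trajectory approaches beta monotonically", {
  set.seed(7)
  for (i in 1:50) {
    pars <- agent_params(runif(1), runif(1), runif(1))
    gap <- abs(rw_trajectory(pars, 100) - pars$beta)
    expect_true(all(diff(gap) <= 1e-15))
  }
})

test_that("noiseless curves are recovered essentially exactly", {
  set.seed(11)
  for (i in 1:5) {
    pars <- c(alpha = runif(1, .05, .95), beta = runif(1, .05, .95),
              v1 = runif(1, .05, .95))
    fit <- fit_group(rw_trajectory(pars, 150))
    expect_lt(max(abs(fit$params - pars)), 1e-3)
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("refitting the fitted curve reproduces the parameters", {
  tab <- small_cohort(n = 6, sessions = 5, seed = 31)
  fit <- fit_group(empirical_group_curve(tab, "ctl"))
  refit <- fit_group(rw_trajectory(fit$params, length(fit$curve)))
  expect_lt(max(abs(refit$params - fit$params)), 1e-6)
})

test_that("a flat curve pins beta and v1 and flags alpha", {
  fit <- fit_group(rep(0.7, 50))
  expect_equal(unname(fit$params["beta"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(fit$params["v1"]), 0.7, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  expect_false(fit$alpha_identifiable)
})

test_that("SSE of a noisy curve tracks the injected noise variance", {
  pars <- agent_params(.3, .8, .1)
  n <- 150
  traj <- rw_trajectory(pars, n)
  set.seed(5)
  sses <- replicate(200, {
    noisy <- pmin(pmax(traj + rnorm(n, 0, 0.05), 0), 1)
    fit_group(noisy)$sse
  })
  expect_equal(mean(sses), 0.05^2 * n, tolerance = 0.2)
})

test_that("bootstrap draws are seeded and collapse for identical subjects", {
  y <- rw_trajectory(agent_params(.3, .8, .1), 30) > 0.5
  tab <- toy_table(list(s1 = y, s2 = y, s3 = y))
  b <- bootstrap_se(tab, n_boot = 30, seed = 4)
  expect_true(all(b$se == 0))

  tab2 <- small_cohort(n = 5, seed = 17)
  b1 <- bootstrap_se(tab2, n_boot = 50, seed = 9)
  b2 <- bootstrap_se(tab2, n_boot = 50, seed = 9)
  expect_identical(b1$draws, b2$draws)
  b3 <- bootstrap_se(tab2, n_boot = 50, seed = 10)
  expect_false(identical(b1$draws, b3$draws))
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(subjects)", {
  sched <- std_schedule(5, seed = 41)
  mk <- function(n, seed) {
    simulate_cohort(cohort_spec(
      list(g = list(n = n, params = agent_params(.3, .7, .15))),
      sched, seed = seed))
  }
  se_small <- bootstrap_se(mk(6, 1), n_boot = 150, seed = 2)$se["beta"]
  se_large <- bootstrap_se(mk(24, 1), n_boot = 150, seed = 2)$se["beta"]
  expect_lt(se_large, se_small)
  expect_lt(se_large / se_small, 0.85)
})

test_that("permutation p is 1 when the groups are identical copies", {
  tab <- small_cohort(n = 3, seed = 23)
  res <- permutation_test(tab, tab, n_perm = 50, seed = 1)
  expect_true(all(res$observed == 0))
  expect_true(all(res$p_values == 1))
})

test_that("permutation test is seeded and needs two subjects per group", {
  a <- small_cohort(n = 3, seed = 3, group = "a")
  b <- small_cohort(n = 3, seed = 4, group = "b")
  r1 <- permutation_test(a, b, n_perm = 100, seed = 6)
  r2 <- permutation_test(a, b, n_perm = 100, seed = 6)
  expect_identical(r1$draws, r2$draws)
  expect_true(all(r1$p_values > 0 & r1$p_values <= 1))
  expect_error(permutation_test(a[a$subject_id == "a_01", ], b,
                                n_perm = 10, seed = 1), ">= 2")
})

test_that("simulated model means converge to the softmax curve", {
  pars <- agent_params(.3, .8, .1, tau = .8)
  m <- simulate_model_mean(pars, 100, n_sims = 4000, seed = 3)
  q <- softmax_avoid_prob(rw_trajectory(pars, 100), .8)
  se <- sqrt(q * (1 - q) / 4000)
  expect_true(all(abs(m$p_avoid - q) <= 4 * se))

  flat <- simulate_model_mean(agent_params(.3, .8, .1, tau = 0), 50,
                              n_sims = 2000, seed = 4)
  expect_true(all(abs(flat$p_avoid - 0.5) < 0.05))
})

test_that("with the link disabled the fit converges to the raw parameters", {
  pars <- agent_params(.3, .8, .1)
  tab <- simulate_cohort(cohort_spec(
    list(g = list(n = 80, params = pars)), std_schedule(5, 71),
    seed = 72, link = "identity"))
  fit <- fit_group(empirical_group_curve(tab, "g"))
  expect_lt(abs(fit$params[["beta"]] - 0.8), 0.05)
  expect_lt(abs(fit$params[["v1"]] - 0.1), 0.1)
  expect_lt(abs(fit$params[["alpha"]] - 0.3), 0.15)
})

test_that("extreme parameter pairs keep their ordering in simulation", {
  hi <- simulate_model_mean(agent_params(.6, .95, .1), 120,
                            n_sims = 500, seed = 8)
  lo <- simulate_model_mean(agent_params(.05, .35, .1), 120,
                            n_sims = 500, seed = 9)
  late <- 100:120
  expect_gt(mean(hi$p_avoid[late]), mean(lo$p_avoid[late]) + 0.1)
})

test_that("fit and resampling objects expose tidy/glance/autoplot", {
  tab <- small_cohort(n = 4, seed = 19)
  fit <- fit_group(empirical_group_curve(tab, "ctl"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("alpha", "beta", "v1"))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
  b <- bootstrap_se(tab, n_boot = 20, seed = 1)
  expect_named(tidy(b), c("term", "estimate", "std.error"))
})
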