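test_that("avoidance rate is the percentage of avoidance trials", {
  tab <- toy_table(list(s1 = rep(0, 30)))
  expect_equal(avoidance_rate(tab)$avoidance_pct, 0)
  tab <- toy_table(list(s1 = rep(1, 30)))
  expect_equal(avoidance_rate(tab)$avoidance_pct, 100)
  tab <- toy_table(list(s1 = c(rep(1, 18), rep(0, 12))))
  expect_equal(avoidance_rate(tab)$avoidance_pct, 60)
})

test_that("avoidance rate is invariant to trial order within a cell", {
  y <- c(rep(1, 7), rep(0, 23))
  tab <- toy_table(list(s1 = y))
  shuffled <- toy_table(list(s1 = sample(y)))
  expect_equal(avoidance_rate(tab)$avoidance_pct,
               avoidance_rate(shuffled)$avoidance_pct)
})

test_that("per-session grouping splits rates by session", {
  tab <- dplyr::bind_rows(
    dplyr::mutate(toy_table(list(s1 = rep(1, 10))), session = 1L),
    dplyr::mutate(toy_table(list(s1 = rep(0, 10))), session = 2L,
                  trial = trial + 10L))
  rates <- avoidance_rate(tab, "per_session")
  expect_equal(sort(rates$avoidance_pct), c(0, 100))
})

test_that("group curve equals per-subject mean and checks alignment", {
  tab <- toy_table(list(s1 = c(1, 0, 1, 0), s2 = c(0, 1, 0, 1)))
  cur <- empirical_group_curve(tab)
  expect_equal(cur$p_avoid, rep(0.5, 4))  # complementary subjects
  expect_equal(cur$n, rep(2L, 4))

  one <- toy_table(list(s1 = c(1, 1, 0)))
  expect_equal(empirical_group_curve(one)$p_avoid, c(1, 1, 0))

  ragged <- dplyr::bind_rows(toy_table(list(s1 = c(1, 0, 1))),
                             toy_table(list(s2 = c(1, 0))))
  expect_error(empirical_group_curve(ragged), "s2")
})

test_that("group curve averages commute with subject averaging", {
  tab <- small_cohort(n = 6, seed = 13)
  cur <- empirical_group_curve(tab, "ctl")
  per_subj <- vapply(unique(tab$subject_id), function(s) {
    tab$outcome[tab$subject_id == s][order(tab$trial[tab$subject_id == s])]
  }, integer(max(tab$trial)))
  expect_equal(cur$p_avoid, rowMeans(per_subj))
})

test_that("cohort curves track the softmax-mapped trajectory", {
  pars <- agent_params(.3, .8, .1, tau = .8)
  groups <- list(g = list(n = 60, params = pars))
  tab <- simulate_cohort(cohort_spec(groups, std_schedule(1, 21), seed = 22))
  cur <- empirical_group_curve(tab, "g")
  q <- softmax_avoid_prob(rw_trajectory(pars, max(cur$trial)), .8)
  se <- sqrt(q * (1 - q) / 60)
  expect_true(mean(abs(cur$p_avoid - q) <= 3 * se) > 0.95)
})

test_that("progressive-ratio breakpoint follows the advancement rule", {
  # two successes at each stage, then six failures at 35 cm
  s <- tibble::tibble(distance_cm = c(25, 25, 30, 30, rep(35, 6)),
                      success = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(pr_breakpoint(s), 30)

  none <- tibble::tibble(distance_cm = rep(25, 6), success = rep(FALSE, 6))
  expect_true(is.na(pr_breakpoint(none)))

  alt <- tibble::tibble(distance_cm = rep(25, 8),
                        success = rep(c(TRUE, FALSE), 4))
  expect_equal(pr_breakpoint(alt), 25)  # never two consecutive successes
})

test_that("breakpoint is monotone in added successes at larger distances", {
  base <- tibble::tibble(distance_cm = c(25, 25, 30, 30),
                         success = c(TRUE, TRUE, TRUE, TRUE))
  extended <- dplyr::bind_rows(base,
                               tibble::tibble(distance_cm = 35,
                                              success = TRUE))
  expect_gte(pr_breakpoint(extended), pr_breakpoint(base))
})

test_that("malformed progressions are rejected", {
  expect_error(pr_breakpoint(tibble::tibble(distance_cm = c(30, 30),
                                            success = c(TRUE, TRUE))),
               "malformed")
  # advancement without two consecutive successes
  expect_error(pr_breakpoint(tibble::tibble(
    distance_cm = c(25, 30), success = c(TRUE, TRUE))), "malformed")
  # distance jump of two stages
  expect_error(pr_breakpoint(tibble::tibble(
    distance_cm = c(25, 25, 35), success = c(TRUE, TRUE, TRUE))),
    "malformed")
})
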