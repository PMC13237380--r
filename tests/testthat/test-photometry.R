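make_session <- function(..., seed = 4) {
  spec <- transient_spec(...)
  generate_photometry(list(safety = seq(30, 570, by = 40)), spec,
                      duration = 600, seed = seed)
}

test_that("isosbestic regression recovers exact affine relations", {
  t <- seq(0, 10, by = 0.05)
  f405 <- 1 + 0.1 * sin(t)
  sess <- structure(list(
    signals = tibble::tibble(time_s = t, f473 = 2 * f405 + 1, f405 = f405),
    events = tibble::tibble(event = character(), time_s = numeric()),
    rate_hz = 20), class = "photometry_session")
  cf <- fit_isosbestic(sess)
  expect_equal(unname(cf), c(2, 1), tolerance = 1e-10)

  # adding a constant to both channels changes the intercept only
  sess2 <- sess
  sess2$signals$f405 <- sess2$signals$f405 + 5
  sess2$signals$f473 <- sess2$signals$f473 + 5
  cf2 <- fit_isosbestic(sess2)
  expect_equal(cf2[["slope"]], cf[["slope"]], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(cf2[["intercept"]], cf[["intercept"]])))

  sess$signals$f405 <- rep(1, length(t))
  expect_error(fit_isosbestic(sess), "constant")
})

test_that("generator ground-truth coefficients are recovered", {
  sess <- make_session(
    events = list(safety = list(amplitude = 0, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0.002)
  cf <- fit_isosbestic(sess)
  expect_equal(cf[["slope"]], sess$truth$slope, tolerance = 0.02)
  expect_equal(cf[["intercept"]], sess$truth$intercept, tolerance = 0.05)
})

test_that("dF/F is zero for artifact-only sessions and scale-invariant", {
  sess <- make_session(
    events = list(safety = list(amplitude = 0, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0)
  dff <- compute_dff(sess)
  tol <- 10 * .Machine$double.eps * diff(range(sess$signals$f473))
  expect_lt(max(abs(dff$dff)), max(tol, 1e-12))

  scaled <- sess
  scaled$signals$f473 <- 3 * scaled$signals$f473
  scaled$signals$f405 <- 3 * scaled$signals$f405
  expect_equal(compute_dff(scaled)$dff, dff$dff, tolerance = 1e-9)
})

test_that("an injected transient amplitude survives the round trip", {
  sess <- make_session(
    events = list(safety = list(amplitude = 0.05, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0)
  dff <- compute_dff(sess)
  expect_equal(max(dff$dff), 0.05, tolerance = 0.05 * 0.05 / 0.05)
  expect_equal(max(dff$dff), 0.05, tolerance = 0.0025 / 0.05)
})

test_that("alignment windows have the stated sample arithmetic", {
  sess <- make_session(
    events = list(safety = list(amplitude = .05, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0)
  dff <- compute_dff(sess)
  tens <- align_to_events(dff, sess$events, "safety", pre = 1, post = 1)
  expect_equal(ncol(tens$mat), 40L)  # round(20 * 2)
  expect_equal(nrow(tens$mat), 14L)
  expect_equal(tens$time[1], -1)
  expect_lt(max(tens$time), 1)

  # events snap to the nearest grid sample
  t2 <- align_to_events(dff, 30.02, pre = 1, post = 1)
  t3 <- align_to_events(dff, 30.00, pre = 1, post = 1)
  expect_identical(t2$mat, t3$mat)

  # incomplete windows are excluded and reported
  t4 <- align_to_events(dff, c(0.5, 100), pre = 5, post = 5)
  expect_equal(nrow(t4$mat), 1L)
  expect_equal(t4$excluded$event_time_s, 0.5)
  expect_error(align_to_events(dff, sess$events, "nonexistent"),
               "nonexistent")
})

test_that("a delta transient lands at sample index pre x rate", {
  t <- seq(0, 100, by = 0.05)
  dff <- tibble::tibble(time_s = t, dff = 0)
  events <- c(20, 40, 60)
  dff$dff[round(events / 0.05) + 1L] <- 1
  attr(dff, "rate_hz") <- 20
  class(dff) <- c("dff_trace", class(dff))
  tens <- align_to_events(dff, events, pre = 2, post = 2)
  for (r in 1:3) {
    expect_equal(which(tens$mat[r, ] == 1) - 1L, 2L * 20L)
  }
})

test_that("baseline z-scoring standardises each trial", {
  sess <- make_session(
    events = list(safety = list(amplitude = .05, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0.003)
  tens <- align_to_events(compute_dff(sess), sess$events, "safety")
  tz <- zscore_baseline(tens)
  base <- tz$time >= -5 & tz$time < 0
  for (r in seq_len(nrow(tz$mat))) {
    expect_lt(abs(mean(tz$mat[r, base])), 1e-10)
    expect_equal(sd(tz$mat[r, base]), 1, tolerance = 1e-10)
  }
  # affine transforms of the trace cancel out
  tens2 <- tens
  tens2$mat <- 3 * tens2$mat + 7
  tz2 <- zscore_baseline(tens2)
  expect_equal(tz2$mat, tz$mat, tolerance = 1e-9)
})

test_that("zero-baseline-SD trials are excluded, not silently dropped", {
  mat <- rbind(c(rep(0, 100), rep(1, 100)),
               rnorm(200))
  tens <- manual_tensor(mat, zscored = FALSE)
  tz <- zscore_baseline(tens)
  expect_equal(nrow(tz$mat), 1L)
  expect_equal(nrow(tz$excluded), 1L)
  expect_match(tz$excluded$reason, "zero baseline SD")
})

test_that("trapezoid AUC matches analytic areas and is additive", {
  rate <- 20
  time <- seq(-5, 5 - 1 / rate, by = 1 / rate)
  zero <- manual_tensor(matrix(0, 1, length(time)))
  a0 <- auc_pre_post(zero)
  expect_equal(a0$auc_pre, 0)
  expect_equal(a0$auc_post, 0)

  # triangular bump, height 2, base 1 s, fully inside the post window
  tri <- pmax(0, 2 * (1 - abs(time - 2) / 0.5))
  tens <- manual_tensor(matrix(tri, 1))
  a <- auc_pre_post(tens)
  expect_equal(a$auc_post, 1.0, tolerance = 0.01)

  # additivity over windows abutting at a shared interior sample
  whole <- auc_pre_post(tens, post_window = c(0, 5))$auc_post
  parts <- auc_pre_post(tens, post_window = c(0, 2.5))$auc_post +
    auc_pre_post(tens, post_window = c(2.45, 5))$auc_post
  expect_equal(whole, parts, tolerance = 1e-10)
})

test_that("subject means average subjects, not pooled trials", {
  mat <- rbind(rep(1, 200),
               matrix(rep(0, 200 * 9), 9, 200, byrow = TRUE))
  trials <- tibble::tibble(trial = 1:10, event_time_s = 1:10,
                           subject_id = c("a", rep("b", 9)))
  tens <- manual_tensor(mat, trials = trials)
  m <- subject_mean_signal(tens)
  expect_equal(unique(m$mean), 0.5)      # two-stage mean
  expect_false(isTRUE(all.equal(unique(m$mean), mean(mat))))  # pooled 0.1

  solo <- manual_tensor(mat[1:3, ],
                        trials = tibble::tibble(trial = 1:3,
                                                event_time_s = 1:3,
                                                subject_id = "a"))
  expect_equal(subject_mean_signal(solo)$mean, colMeans(mat[1:3, ]))

  shuffled <- tens
  ord <- c(5, 1, 7, 2, 9, 3, 10, 4, 8, 6)
  shuffled$mat <- shuffled$mat[ord, ]
  shuffled$trials <- shuffled$trials[ord, ]
  expect_equal(subject_mean_signal(shuffled)$mean, m$mean)
})

test_that("latency ordering is a stable ascending sort", {
  mat <- matrix(seq_len(50), 5, 10)
  mk <- function(lat) {
    manual_tensor(mat, trials = tibble::tibble(
      trial = 1:5, event_time_s = 1:5, latency_s = lat))
  }
  sorted <- order_by_latency(mk(c(1, 2, 3, 4, 5)))
  expect_equal(sorted$mat, mat)
  reversed <- order_by_latency(mk(c(5, 4, 3, 2, 1)))
  expect_equal(reversed$mat, mat[5:1, ])
  set.seed(3)
  lat <- runif(5)
  rand <- order_by_latency(mk(lat))
  expect_equal(rand$mat, mat[order(lat), ])  # comparison-sort oracle
  expect_error(order_by_latency(mk(c(1, NA, 3, 4, 5))), "latency")
})

test_that("dual-sensor peak offsets recover injected lags", {
  ev <- list(safety = seq(30, 570, by = 40))
  mk <- function(lat, seed) {
    spec <- transient_spec(events = list(
      safety = list(amplitude = .05, latency = lat, rise = .1, decay = .5)),
      noise_sd = 0.001)
    s <- generate_photometry(ev, spec, 600, seed = seed)
    zscore_baseline(align_to_events(compute_dff(s), s$events, "safety"))
  }
  ta <- mk(0, 7)
  same <- peak_offset(ta, ta)
  expect_true(all(same$offset_s[!same$flagged] == 0))
  for (lag in c(0.1, 0.3, 0.5)) {
    tb <- mk(lag, 8)
    po <- peak_offset(ta, tb)
    expect_lte(abs(mean(po$offset_s[!po$flagged]) - lag), 0.05 + 1e-9)
  }
})

test_that("boundary maxima are flagged as no-peak", {
  dec <- manual_tensor(matrix(seq(5, 1, length.out = 200), 1))
  po <- peak_offset(dec, dec)
  expect_true(all(po$flagged))
  expect_true(all(is.na(po$offset_s)))
})

test_that("photometry files round-trip", {
  sess <- make_session(
    events = list(safety = list(amplitude = .05, latency = 0,
                                rise = .1, decay = .5)),
    noise_sd = 0.002)
  sp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_photometry(sess, sp, ep)
  back <- read_photometry(sp, ep)
  expect_equal(back$signals$f473, sess$signals$f473, tolerance = 1e-9)
  expect_equal(back$rate_hz, 20, tolerance = 1e-6)
  expect_s3_class(autoplot(zscore_baseline(align_to_events(
    compute_dff(back), back$events, "safety"))), "ggplot")
})
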