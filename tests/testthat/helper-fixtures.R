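# Shared fixtures, built in code at test time.

std_schedule <- function(sessions = 5, seed = 7) {
  make_schedule("standard_2aa", sessions = sessions, seed = seed)
}

small_cohort <- function(n = 4, params = agent_params(0.3, 0.8, 0.1),
                         sessions = 1, seed = 1, group = "ctl") {
  groups <- setNames(list(list(n = n, params = params)), group)
  simulate_cohort(cohort_spec(groups, std_schedule(sessions, seed + 100),
                              seed = seed))
}

# Hand-built behavior table with fully controlled outcomes.
toy_table <- function(outcomes_by_subject, group = "g") {
  purrr::imap_dfr(outcomes_by_subject, function(y, sid) {
    tibble::tibble(subject_id = sid, group = group,
                   session = 1L, trial = seq_along(y),
                   outcome = as.integer(y),
                   latency_s = ifelse(y == 1, 3, 15),
                   ws_onset_s = 35 * seq_along(y),
                   shuttle_s = NA_real_, safety_s = NA_real_)
  })
}

# Double-exponential EPSC: amplitude is the (signed) peak deviation from
# baseline; kernel normalised to unit peak.
synth_epsc <- function(amps, stims, rise = 1, decay = 8, dt = 0.05,
                       t_end = 200, baseline = -10) {
  t <- seq(0, t_end, by = dt)
  y <- rep(baseline, length(t))
  peak_t <- rise * log(1 + decay / rise)
  peak <- (1 - exp(-peak_t / rise)) * exp(-peak_t / decay)
  for (i in seq_along(amps)) {
    dtv <- t - stims[i]
    k <- ifelse(dtv >= 0, (1 - exp(-pmax(dtv, 0) / rise)) *
                  exp(-pmax(dtv, 0) / decay), 0) / peak
    y <- y + amps[i] * k
  }
  tibble::tibble(time_ms = t, current_pA = y)
}

# Minimal aligned tensor for window arithmetic tests.
manual_tensor <- function(mat, rate = 20, pre = 5, post = 5,
                          trials = NULL, zscored = TRUE) {
  n_pre <- round(rate * pre)
  structure(list(
    mat = mat,
    time = (seq_len(ncol(mat)) - 1L - n_pre) / rate,
    trials = trials %||% tibble::tibble(trial = seq_len(nrow(mat)),
                                        event_time_s = seq_len(nrow(mat))),
    pre = pre, post = post, rate_hz = rate, event = "manual",
    excluded = tibble::tibble(), zscored = zscored
  ), class = "aligned_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
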