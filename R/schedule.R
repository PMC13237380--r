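# Task-schedule generation for the avoidance protocols.

protocol_defaults <- list(
  standard_2aa = list(
    trials = 30L, ws_max = 15, us_max = 7, iti = c(30, 40),
    shock = TRUE, sessions = 5L),
  probabilistic = list(
    trials = NA_integer_, ws_max = 15, us_max = 7, iti = c(30, 40),
    shock = TRUE, sessions = 1L),
  extinction_rp = list(
    trials = 15L, ws_max = 15, us_max = 0, iti = c(35, 45),
    shock = FALSE, sessions = 1L),
  extinction = list(
    trials = 30L, ws_max = 15, us_max = 0, iti = c(30, 40),
    shock = FALSE, sessions = 1L),
  head_fixed = list(
    trials = 50L, ws_max = 10, us_max = 5, iti = c(30, 30),
    shock = TRUE, sessions = 3L),
  progressive_ratio = list(
    trials = 60L, ws_max = 20, us_max = 5, iti = c(30, 30),
    shock = TRUE, sessions = 1L)
)

#' Generate a task schedule for an avoidance protocol
#'
#' Builds the trial-by-trial schedule (inter-trial intervals, warning-signal
#' and shock ceilings, surprise-omission flags) for one of the supported
#' protocols:
#'
#' * `standard_2aa` — 30 warning signals (WS, up to 15 s) per session,
#'   footshock (up to 7 s) on failure, ITI uniform on 30–40 s.
#' * `probabilistic` — a 20-trial baseline phase followed by a probabilistic
#'   phase containing exactly five surprise safety-omission trials separated
#'   by 5–10 intervening trials (about 62 trials per session in total).
#' * `extinction_rp` — response prevention: 15 WS, 35–45 s ITI, no shock.
#' * `extinction` — 30 WS, 30–40 s ITI, no shock.
#' * `head_fixed` — 50 trials per session, WS up to 10 s, air-puff US up to
#'   5 s, fixed 30 s ITI.
#' * `progressive_ratio` — head-fixed schedule with WS ceiling raised to
#'   20 s; the running-distance requirement starts at 25 cm and advances in
#'   5 cm steps after two consecutive successes (realised during
#'   simulation/scoring, so the per-trial distance is not preassigned here).
#'
#' @param protocol One of the protocol names above.
#' @param sessions Number of sessions; defaults to the protocol's standard
#'   count (5 for `standard_2aa`, 3 for `head_fixed`, otherwise 1).
#' @param seed Integer seed; schedules are deterministic given the seed.
#'
#' @return A tibble of class `safeval_schedule` with one row per trial:
#'   `session`, `trial` (global, 1-based), `trial_in_session`, `iti_s`,
#'   `ws_max_s`, `us_max_s`, `shock_on`, `surprise`. Protocol metadata is
#'   attached as attributes (`protocol`, `iti_bounds`, `pr_rule`).
#' @examples
#' sched <- make_schedule("standard_2aa", sessions = 5, seed = 7)
#' nrow(sched)  # 150
#' @export
make_schedule <- function(protocol, sessions = NULL, seed = 1L) {
  if (!is.character(protocol) || length(protocol) != 1L ||
      !protocol %in% names(protocol_defaults)) {
    abort(sprintf("Unknown protocol %s; must be one of: %s.",
                  deparse(protocol),
                  paste(names(protocol_defaults), collapse = ", ")))
  }
  def <- protocol_defaults[[protocol]]
  sessions <- as.integer(sessions %||% def$sessions)
  if (is.na(sessions) || sessions < 1L) abort("`sessions` must be >= 1.")

  seeded(seed, function() {
    per_session <- lapply(seq_len(sessions), function(s) {
      if (protocol == "probabilistic") {
        # 20-trial reliable baseline, then 5 surprise omissions each
        # preceded by 5-10 intervening trials, plus a short tail.
        gaps <- sample(5:10, 5L, replace = TRUE)
        tail_n <- sample(1:3, 1L)
        # k-th surprise position: baseline + intervening gaps + earlier surprises
        surprise_at <- 20L + cumsum(gaps) + seq_len(5L)
        n <- surprise_at[5L] + tail_n
        surprise <- rep(FALSE, n)
        surprise[surprise_at] <- TRUE
      } else {
        n <- def$trials
        surprise <- rep(FALSE, n)
      }
      tibble::tibble(
        session = s,
        trial_in_session = seq_len(n),
        iti_s = runif(n, def$iti[1], def$iti[2]),
        ws_max_s = def$ws_max,
        us_max_s = def$us_max,
        shock_on = def$shock,
        surprise = surprise
      )
    })
    out <- dplyr::bind_rows(per_session)
    out <- dplyr::mutate(out, trial = dplyr::row_number(),
                         .before = "trial_in_session")
    attr(out, "protocol") <- protocol
    attr(out, "iti_bounds") <- def$iti
    attr(out, "seed") <- as.integer(seed)
    if (protocol == "progressive_ratio") {
      attr(out, "pr_rule") <- list(start_cm = 25, step_cm = 5,
                                   advance_after = 2L, fail_limit = 6L)
    }
    class(out) <- c("safeval_schedule", class(out))
    out
  })
}

#' Check a schedule (or simulated behavior table) against protocol rules
#'
#' Returns violations as data, not errors: each row names the rule broken
#' and the trial(s) involved. Checked rules: ITI within the protocol's
#' bounds; per-session trial counts for fixed-length protocols; for the
#' probabilistic protocol, exactly five surprise trials per session with
#' 5–10 intervening trials between consecutive surprises and none in the
#' 20-trial baseline.
#'
#' @param x A `safeval_schedule` (or a behavior table carrying the same
#'   columns and attributes).
#' @return A tibble with columns `rule`, `session`, `trial`, `detail`;
#'   zero rows when the schedule is compliant.
#' @export
validate_schedule <- function(x) {
  protocol <- attr(x, "protocol")
  bounds <- attr(x, "iti_bounds")
  if (is.null(protocol)) abort("`x` has no protocol metadata.")
  v <- list()
  add <- function(rule, session, trial, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      rule = rule, session = session, trial = trial, detail = detail)
  }
  bad_iti <- which(x$iti_s < bounds[1] | x$iti_s > bounds[2])
  for (i in bad_iti) {
    add("iti_bounds", x$session[i], x$trial[i],
        sprintf("ITI %.2f s outside [%g, %g]", x$iti_s[i],
                bounds[1], bounds[2]))
  }
  def <- protocol_defaults[[protocol]]
  if (!is.na(def$trials)) {
    counts <- table(x$session)
    for (s in names(counts)) {
      if (counts[[s]] != def$trials) {
        add("trial_count", as.integer(s), NA_integer_,
            sprintf("%d trials, expected %d", counts[[s]], def$trials))
      }
    }
  }
  if (protocol == "probabilistic") {
    for (s in unique(x$session)) {
      xi <- x[x$session == s, ]
      at <- xi$trial_in_session[xi$surprise]
      if (length(at) != 5L) {
        add("surprise_count", s, NA_integer_,
            sprintf("%d surprise trials, expected 5", length(at)))
      }
      if (any(at <= 20L)) {
        add("surprise_in_baseline", s, at[at <= 20L][1],
            "surprise trial inside the 20-trial baseline")
      }
      gaps <- diff(c(20L, at)) - 1L
      bad <- which(gaps < 5L | gaps > 10L)
      for (b in bad) {
        add("surprise_gap", s, at[b],
            sprintf("gap of %d intervening trials outside [5, 10]", gaps[b]))
      }
    }
  } else if (any(x$surprise)) {
    add("surprise_flag", x$session[which(x$surprise)[1]],
        x$trial[which(x$surprise)[1]],
        "surprise flags only allowed in the probabilistic protocol")
  }
  if (length(v) == 0L) {
    tibble::tibble(rule = character(), session = integer(),
                   trial = integer(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
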