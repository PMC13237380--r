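# Synthetic avoidance learners: single agents and labelled cohorts.

#' Simulate one avoidance learner on a task schedule
#'
#' The latent avoidance probability follows the Rescorla-Wagner recursion
#' deterministically (there is no outcome feedback in the update; see
#' [rw_trajectory()]). On each trial the binary outcome is drawn as
#' `Bernoulli(plogis(tau * (2 * p(t) - 1)))`. Avoidance trials get a
#' shuttle latency drawn from an exponential truncated to
#' `(0, ws_max_s)`; escape trials take the full WS duration and the
#' shuttle/safety timestamps are missing (the animal only crosses after
#' shock onset).
#'
#' @param params An [agent_params()] object (or coercible list).
#' @param schedule A [make_schedule()] tibble.
#' @param seed Integer seed; the whole record is reproducible given it.
#' @param link `"softmax"` (default) draws outcomes through the softmax
#'   mapping; `"identity"` draws them directly as `Bernoulli(p(t))`
#'   (the tau-link-disabled variant, used e.g. for well-specified
#'   parameter-recovery simulation).
#' @param outcome_feedback If `TRUE`, the latent state is updated only
#'   after avoidance trials (sensitivity-analysis variant); default `FALSE`,
#'   the outcome-free update.
#' @param latency_rate Rate (1/s) of the truncated-exponential avoid
#'   latency; default gives mean latency around a third of the WS ceiling.
#'
#' @return A tibble with one row per trial: `session`, `trial`,
#'   `outcome` (1 = avoid, 0 = escape), `latency_s`, `ws_onset_s`,
#'   `shuttle_s`, `safety_s` (the two timestamps are `NA` on escape
#'   trials), plus the latent `p_a` used to generate the outcome.
#' @export
simulate_agent <- function(params, schedule, seed = 1L,
                           link = c("softmax", "identity"),
                           outcome_feedback = FALSE,
                           latency_rate = NULL) {
  params <- as_agent_params(params)
  link <- match.arg(link)
  out_prob <- function(p) {
    if (link == "softmax") softmax_avoid_prob(p, params$tau) else p
  }
  if (!is.data.frame(schedule) || nrow(schedule) == 0L) {
    abort("`schedule` must be a non-empty schedule tibble.")
  }
  n <- nrow(schedule)
  seeded(seed, function() {
    if (outcome_feedback) {
      p_a <- numeric(n)
      outcome <- integer(n)
      cur <- params$v1
      for (t in seq_len(n)) {
        p_a[t] <- cur
        outcome[t] <- rbinom(1L, 1L, out_prob(cur))
        if (outcome[t] == 1L) cur <- cur + params$alpha * (params$beta - cur)
      }
    } else {
      p_a <- rw_trajectory(params, n)
      outcome <- rbinom(n, 1L, out_prob(p_a))
    }
    ws_max <- schedule$ws_max_s
    rate <- latency_rate %||% (3 / ws_max)
    u <- runif(n)
    lat_avoid <- -log(1 - u * (1 - exp(-rate * ws_max))) / rate
    latency <- ifelse(outcome == 1L, lat_avoid, ws_max)
    # escape trials: shock until crossing, short random escape delay
    shock_dur <- runif(n, 0.2, pmax(schedule$us_max_s, 0.2))
    out <- tibble::tibble(
      session = schedule$session,
      trial = schedule$trial,
      outcome = as.integer(outcome),
      latency_s = latency,
      p_a = p_a
    )
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$session),
      ws_onset_s = {
        dur <- ifelse(.data$outcome == 1L, .data$latency_s,
                      ws_max[.data$trial] + shock_dur[.data$trial])
        cumsum(schedule$iti_s[.data$trial]) +
          dplyr::lag(cumsum(dur), default = 0)
      },
      .after = "latency_s")
    out <- dplyr::ungroup(out)
    out$shuttle_s <- ifelse(out$outcome == 1L,
                            out$ws_onset_s + out$latency_s, NA_real_)
    out$safety_s <- out$shuttle_s
    dplyr::relocate(out, "p_a", .after = "safety_s")
  })
}

#' Specify a simulated cohort
#'
#' @param groups Named list; each element describes one group as a list
#'   with `n` (subjects, >= 1), `params` (an [agent_params()]) and
#'   optionally `jitter`, a single half-width or named vector of
#'   half-widths: each subject's parameters are drawn uniformly within
#'   `params +/- jitter`, clamped to the unit interval (`tau` clamped at 0).
#' @param schedule A [make_schedule()] tibble shared by all subjects.
#' @param seed Master seed; per-subject seeds are derived deterministically
#'   from it so cohorts are bit-reproducible.
#' @param link Outcome link passed to [simulate_agent()]: `"softmax"`
#'   (default) or `"identity"`.
#' @return A `cohort_spec` object.
#' @examples
#' spec <- cohort_spec(
#'   groups = list(control = list(n = 8, params = agent_params(.3, .8, .1))),
#'   schedule = make_schedule("standard_2aa", seed = 1), seed = 42)
#' @export
cohort_spec <- function(groups, schedule, seed = 1L,
                        link = c("softmax", "identity")) {
  link <- match.arg(link)
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)) ||
      any(names(groups) == "")) {
    abort("`groups` must be a non-empty named list.")
  }
  groups <- lapply(groups, function(g) {
    g$n <- as.integer(g$n %||% 1L)
    if (g$n < 1L) abort("each group needs >= 1 subject")
    g$params <- as_agent_params(g$params)
    g$jitter <- g$jitter %||% 0
    g
  })
  structure(list(groups = groups, schedule = schedule,
                 seed = as.integer(seed), link = link),
            class = "cohort_spec")
}

jitter_params <- function(params, jitter) {
  if (all(jitter == 0)) return(params)
  j <- function(nm, lo = 0, hi = 1) {
    hw <- if (!is.null(names(jitter))) jitter[[nm]] %||% 0 else jitter[[1L]]
    min(max(params[[nm]] + runif(1, -hw, hw), lo), hi)
  }
  agent_params(j("alpha"), j("beta"), j("v1"),
               max(params$tau + (if (!is.null(names(jitter)))
                 jitter[["tau"]] %||% 0 else 0) * runif(1, -1, 1), 0))
}

#' Simulate a labelled cohort of avoidance learners
#'
#' Runs [simulate_agent()] for every subject of every group in the spec,
#' with per-subject seeds derived from the master seed, and stacks the
#' records into one behavior table.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `safeval_behavior`: columns `subject_id`,
#'   `group`, `session`, `trial`, `outcome`, `latency_s`, `ws_onset_s`,
#'   `shuttle_s`, `safety_s`, `p_a`. True per-subject parameters are kept
#'   in the `"truth"` attribute (one row per subject).
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  idx <- 0L
  truth <- list()
  blocks <- list()
  for (g in names(spec$groups)) {
    grp <- spec$groups[[g]]
    for (i in seq_len(grp$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, i)
      sseed <- derive_seed(spec$seed, idx)
      pars <- seeded(derive_seed(spec$seed, 100000L + idx),
                     function() jitter_params(grp$params, grp$jitter))
      rec <- simulate_agent(pars, spec$schedule, seed = sseed,
                            link = spec$link %||% "softmax")
      rec <- dplyr::mutate(rec, subject_id = sid, group = g,
                           .before = "session")
      blocks[[idx]] <- rec
      truth[[idx]] <- tibble::tibble(
        subject_id = sid, group = g, alpha = pars$alpha, beta = pars$beta,
        v1 = pars$v1, tau = pars$tau, seed = sseed)
    }
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "protocol") <- attr(spec$schedule, "protocol")
  attr(out, "iti_bounds") <- attr(spec$schedule, "iti_bounds")
  class(out) <- c("safeval_behavior", class(out))
  out
}

#' Read or write a behavior table
#'
#' The on-disk schema is comma-separated with columns `subject_id`,
#' `group`, `session`, `trial`, `outcome`, `latency_s`, `ws_onset_s`,
#' `shuttle_s`, `safety_s`; shuttle/safety are empty fields on escape
#' trials.
#'
#' @param x A behavior table.
#' @param path File path.
#' @return `read_behavior()` returns the tibble; `write_behavior()` its
#'   input, invisibly.
#' @export
write_behavior <- function(x, path) {
  cols <- c("subject_id", "group", "session", "trial", "outcome",
            "latency_s", "ws_onset_s", "shuttle_s", "safety_s")
  utils::write.table(as.data.frame(x)[, cols], path, sep = ",",
                     na = "", row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("safeval_behavior", class(out))
  out
}
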