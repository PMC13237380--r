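# Behavioral metrics: avoidance rate, group learning curves, PR breakpoint.

#' Avoidance rate per subject or per session
#'
#' The avoidance rate is the percentage of avoidance trials over total
#' trials within each grouping cell.
#'
#' @param table A behavior table (see [simulate_cohort()] /
#'   [read_behavior()]).
#' @param grouping `"per_subject"` (one rate per subject) or
#'   `"per_session"` (one rate per subject x session).
#' @return A tibble with the grouping columns, `n_trials`, `n_avoid`, and
#'   `avoidance_pct` on the 0-100 scale.
#' @examples
#' tab <- simulate_cohort(cohort_spec(
#'   groups = list(ctl = list(n = 2, params = agent_params(.3, .8, .1))),
#'   schedule = make_schedule("standard_2aa", sessions = 1, seed = 1),
#'   seed = 1))
#' avoidance_rate(tab)
#' @export
avoidance_rate <- function(table, grouping = c("per_subject", "per_session")) {
  grouping <- match.arg(grouping)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("`table` must be a non-empty behavior table.")
  }
  keys <- switch(grouping,
                 per_subject = c("group", "subject_id"),
                 per_session = c("group", "subject_id", "session"))
  keys <- intersect(keys, names(table))
  out <- dplyr::summarise(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(keys))),
    n_trials = dplyr::n(),
    n_avoid = sum(.data$outcome),
    avoidance_pct = 100 * mean(.data$outcome),
    .groups = "drop")
  out
}

#' Per-trial mean avoidance curve of a group
#'
#' The group learning curve is the across-subject mean of the 0/1 outcome
#' at each trial, with sessions concatenated into a single trial axis in
#' session order. All subjects in the group must have identical trial
#' indices; ragged groups are an error that names the offenders.
#'
#' @param table A behavior table.
#' @param group Optional group label to select; default uses all rows.
#' @return A tibble: `trial`, `p_avoid` (mean outcome), `n` (subjects).
#' @export
empirical_group_curve <- function(table, group = NULL) {
  if (!is.null(group)) {
    table <- table[table$group == group, ]
    if (nrow(table) == 0L) abort(sprintf("no rows for group %s", group))
  }
  counts <- table(table$subject_id)
  if (length(unique(counts)) > 1L) {
    bad <- names(counts)[counts != stats::median(counts)]
    abort(sprintf("ragged trial counts; offending subjects: %s",
                  paste(bad, collapse = ", ")))
  }
  table <- dplyr::arrange(table, .data$subject_id, .data$session, .data$trial)
  dplyr::summarise(
    dplyr::group_by(table, .data$trial),
    p_avoid = mean(.data$outcome), n = dplyr::n(), .groups = "drop")
}

#' Progressive-ratio breakpoint
#'
#' In the progressive-ratio test the running-distance requirement starts
#' at 25 cm and advances in 5 cm increments only after two consecutive
#' successful avoidance trials; the breakpoint is the longest distance at
#' which avoidance was still achieved. The session-termination rule (six
#' consecutive failures) is validated but not enforced.
#'
#' @param session A tibble/data frame with ordered columns `distance_cm`
#'   and `success` (logical or 0/1).
#' @param start_cm,step_cm Progression rule constants (25 and 5 cm).
#' @return The breakpoint distance in cm, or `NA` if no trial succeeded.
#' @examples
#' pr_breakpoint(tibble::tibble(
#'   distance_cm = c(25, 25, 30, 30, rep(35, 6)),
#'   success = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))))  # 30
#' @export
pr_breakpoint <- function(session, start_cm = 25, step_cm = 5) {
  d <- session$distance_cm
  s <- as.logical(session$success)
  if (length(d) == 0L) abort("`session` is empty")
  # validate the progression rule
  if (d[1] != start_cm) {
    abort(sprintf("malformed progression: first distance %g, expected %g",
                  d[1], start_cm))
  }
  streak <- 0L
  for (i in seq_along(d)) {
    if (i > 1L) {
      step <- d[i] - d[i - 1L]
      if (!step %in% c(0, step_cm)) {
        abort(sprintf(
          "malformed progression: trial %d jumps from %g to %g cm", i,
          d[i - 1L], d[i]))
      }
      if (step == step_cm && streak < 2L) {
        abort(sprintf(
          "malformed progression: advancement at trial %d without two consecutive successes",
          i))
      }
      if (step == step_cm) streak <- 0L
    }
    streak <- if (s[i]) streak + 1L else 0L
  }
  # termination rule: validated, not enforced
  fails <- rle(!s)
  if (any(fails$values & fails$lengths >= 6L)) {
    over <- which(fails$values & fails$lengths >= 6L)[1]
    if (over < length(fails$lengths)) {
      warn("session continues past six consecutive failures")
    }
  }
  if (!any(s)) return(NA_real_)
  max(d[s])
}
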