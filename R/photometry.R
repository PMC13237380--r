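# Fiber-photometry processing: isosbestic detrending, dF/F, peri-event
# alignment, baseline z-scoring, trapezoid AUC, averaging, peak offsets.
#
# Conventions used throughout: half-open windows [t - pre, t + post),
# nearest-sample event snapping, 1-based trial indices, 0-based sample
# indices within a window.

#' Least-squares fit of the signal channel on the isosbestic channel
#'
#' Ordinary least squares of F473 on F405 over the entire session,
#' producing the fitted control trace
#' `F_fitted405 = slope * F405 + intercept` used for detrending.
#'
#' @param session A `photometry_session`.
#' @param channel Signal channel column (default `"f473"`; use `"f560"`
#'   for red-sensor sessions, which are processed identically against the
#'   405 reference).
#' @return Named vector `c(slope, intercept)`.
#' @export
fit_isosbestic <- function(session, channel = "f473") {
  sig <- session$signals
  if (nrow(sig) < 2L) abort("need >= 2 samples")
  x <- sig$f405
  if (sd(x) == 0) abort("degenerate regression: F405 is constant")
  yv <- sig[[channel]]
  b <- cov(x, yv) / var(x)
  a <- mean(yv) - b * mean(x)
  c(slope = b, intercept = a)
}

#' Compute dF/F against the fitted isosbestic control
#'
#' `dF/F = (F473 - F_fitted405) / F_fitted405` pointwise, with the
#' regression coefficients recorded on the result. Errors if the fitted
#' control crosses zero (reporting the sample indices), since the ratio
#' is then meaningless.
#'
#' @param session A `photometry_session`.
#' @param channel Signal channel column.
#' @return A tibble of class `dff_trace`: `time_s`, `dff`; attributes
#'   `coefficients` and `rate_hz`.
#' @export
compute_dff <- function(session, channel = "f473") {
  cf <- fit_isosbestic(session, channel)
  fitted <- cf["slope"] * session$signals$f405 + cf["intercept"]
  scale <- stats::median(abs(session$signals[[channel]]))
  bad <- which(abs(fitted) < 1e-6 * max(scale, .Machine$double.eps))
  if (length(bad)) {
    abort(sprintf(
      "fitted 405 trace crosses zero at %d sample(s) (first indices: %s)",
      length(bad), paste(head(bad, 5L), collapse = ", ")))
  }
  out <- tibble::tibble(
    time_s = session$signals$time_s,
    dff = (session$signals[[channel]] - fitted) / fitted)
  attr(out, "coefficients") <- cf
  attr(out, "rate_hz") <- session$rate_hz
  class(out) <- c("dff_trace", class(out))
  out
}

#' Align a dF/F trace to events
#'
#' Extracts a trials x samples matrix of windows `[t - pre, t + post)`
#' around each event time, snapping each event to the nearest sample on
#' the grid. Window length is `round(rate * (pre + post))` samples for
#' every trial; events whose window is not fully covered by the session
#' are excluded and reported in the `excluded` attribute (never silently
#' dropped).
#'
#' @param trace A `dff_trace` (or any tibble with `time_s` and a value
#'   column plus a `rate_hz` attribute).
#' @param events Either a numeric vector of event times or the session's
#'   events tibble (`event`, `time_s`).
#' @param event Event name to select when `events` is a tibble.
#' @param pre,post Window extent before/after the event, s.
#' @param meta Optional tibble of per-trial metadata (e.g. `subject_id`,
#'   `latency_s`), one row per event in order.
#' @return An `aligned_tensor`: list with `mat` (trials x samples),
#'   `time` (sample offsets, s), `trials` (metadata tibble), `pre`,
#'   `post`, `rate_hz`, `event`, `excluded`.
#' @export
align_to_events <- function(trace, events, event = NULL, pre = 5, post = 5,
                            meta = NULL) {
  rate <- attr(trace, "rate_hz")
  if (is.null(rate)) abort("`trace` carries no `rate_hz` attribute")
  if (is.data.frame(events)) {
    if (is.null(event)) abort("give `event` to select from the events table")
    if (!event %in% events$event) {
      abort(sprintf("event %s not present in the events table", deparse(event)))
    }
    times <- sort(events$time_s[events$event == event])
  } else {
    times <- as.numeric(events)
  }
  if (length(times) == 0L) abort("no events to align to")
  n_pre <- round(rate * pre)
  n_win <- round(rate * (pre + post))
  t0 <- trace$time_s[1]
  centre <- as.integer(round((times - t0) * rate)) + 1L
  first <- centre - n_pre
  last <- first + n_win - 1L
  ok <- first >= 1L & last <= nrow(trace)
  if (!any(ok)) abort("no alignable events: all windows incomplete")
  mat <- t(vapply(which(ok), function(i) {
    trace$dff[first[i]:last[i]]
  }, numeric(n_win)))
  trials <- tibble::tibble(trial = seq_len(sum(ok)),
                           event_time_s = times[ok])
  if (!is.null(meta)) {
    trials <- dplyr::bind_cols(trials, meta[ok, , drop = FALSE])
  }
  excluded <- tibble::tibble(event_time_s = times[!ok],
                             reason = "window not fully covered by session")
  structure(list(
    mat = mat, time = (seq_len(n_win) - 1L - n_pre) / rate,
    trials = trials, pre = pre, post = post, rate_hz = rate,
    event = event %||% NA_character_, excluded = excluded,
    zscored = FALSE
  ), class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  cat(sprintf(
    "<aligned_tensor> %d trials x %d samples (%s; [-%g, %g) s at %g Hz)%s\n",
    nrow(x$mat), ncol(x$mat), x$event, x$pre, x$post, x$rate_hz,
    if (x$zscored) " [z-scored]" else ""))
  invisible(x)
}

#' Z-score an aligned tensor against its per-trial baseline
#'
#' Each trial is standardised by the mean and SD of its own baseline
#' segment (default the 5 s immediately before the event,
#' `[-5, 0)`). Trials with zero baseline SD are excluded and recorded in
#' `excluded`.
#'
#' @param tensor An `aligned_tensor`.
#' @param baseline Two-element window `[from, to)` in seconds relative to
#'   the event.
#' @return The tensor with `mat` z-scored, per-trial `baseline_mean` /
#'   `baseline_sd` added to `trials`, and `zscored = TRUE`.
#' @export
zscore_baseline <- function(tensor, baseline = c(-5, 0)) {
  idx <- tensor$time >= baseline[1] & tensor$time < baseline[2]
  if (!any(idx)) abort("baseline window contains no samples")
  bm <- rowMeans(tensor$mat[, idx, drop = FALSE])
  bs <- apply(tensor$mat[, idx, drop = FALSE], 1, sd)
  bad <- which(bs == 0)
  if (length(bad)) {
    tensor$excluded <- dplyr::bind_rows(
      tensor$excluded,
      tibble::tibble(event_time_s = tensor$trials$event_time_s[bad],
                     reason = "zero baseline SD"))
    tensor$mat <- tensor$mat[-bad, , drop = FALSE]
    tensor$trials <- tensor$trials[-bad, , drop = FALSE]
    bm <- bm[-bad]; bs <- bs[-bad]
    if (nrow(tensor$mat) == 0L) abort("all trials had zero baseline SD")
  }
  tensor$mat <- (tensor$mat - bm) / bs
  tensor$trials$baseline_mean <- bm
  tensor$trials$baseline_sd <- bs
  tensor$zscored <- TRUE
  tensor
}

#' Trapezoid area under the curve over pre- and post-event windows
#'
#' Composite trapezoid rule on each trial's (typically z-scored) signal
#' over the baseline (pre) and event (post) windows; units are z.s when
#' applied to z-scored tensors.
#'
#' @param tensor An `aligned_tensor`.
#' @param pre_window,post_window Two-element windows `[from, to)` in
#'   seconds relative to the event.
#' @return A tibble: `trial`, `auc_pre`, `auc_post` (plus any trial
#'   metadata columns).
#' @export
auc_pre_post <- function(tensor, pre_window = c(-5, 0),
                         post_window = c(0, 5)) {
  win_auc <- function(w) {
    idx <- which(tensor$time >= w[1] & tensor$time < w[2])
    if (length(idx) < 2L) abort("window contains fewer than 2 samples")
    apply(tensor$mat[, idx, drop = FALSE], 1,
          function(yv) trapz(tensor$time[idx], yv))
  }
  dplyr::bind_cols(
    tensor$trials,
    tibble::tibble(auc_pre = win_auc(pre_window),
                   auc_post = win_auc(post_window)))
}

#' Across-subject mean signal
#'
#' Averages each subject's trials first, then averages the subject means
#' (unweighted), so subjects with many trials do not dominate. The SEM is
#' across subjects.
#'
#' @param tensor An `aligned_tensor` whose `trials` metadata contains a
#'   `subject_id` column.
#' @return A tibble: `time_s`, `mean`, `sem`, `n_subjects`.
#' @export
subject_mean_signal <- function(tensor) {
  if (!"subject_id" %in% names(tensor$trials)) {
    abort("`tensor$trials` needs a `subject_id` column")
  }
  subs <- unique(tensor$trials$subject_id)
  per_sub <- vapply(subs, function(s) {
    colMeans(tensor$mat[tensor$trials$subject_id == s, , drop = FALSE])
  }, numeric(ncol(tensor$mat)))
  tibble::tibble(
    time_s = tensor$time,
    mean = rowMeans(per_sub),
    sem = apply(per_sub, 1, sd) / sqrt(length(subs)),
    n_subjects = length(subs))
}

#' Order tensor rows by avoidance latency
#'
#' Stable ascending sort of trials by their latency (for latency-sorted
#' heatmaps); ties keep the original (subject, trial) order.
#'
#' @param tensor An `aligned_tensor` with a `latency_s` column in
#'   `trials`.
#' @return The row-permuted tensor.
#' @export
order_by_latency <- function(tensor) {
  if (!"latency_s" %in% names(tensor$trials) ||
      anyNA(tensor$trials$latency_s)) {
    abort("every trial needs a non-missing `latency_s`")
  }
  ord <- order(tensor$trials$latency_s)  # stable in R
  tensor$mat <- tensor$mat[ord, , drop = FALSE]
  tensor$trials <- tensor$trials[ord, , drop = FALSE]
  tensor$trials$trial <- seq_len(nrow(tensor$trials))
  tensor
}

#' Per-trial peak-time offset between two sensors
#'
#' For matched trials of two aligned tensors (e.g. an acetylcholine and a
#' dopamine sensor), finds the time of the global maximum of each trace
#' within the post-event search window and reports
#' `offset = t_peak(B) - t_peak(A)` (positive means B peaks later).
#' Maxima landing on the window boundary are rejected as "no peak" and
#' flagged rather than reported.
#'
#' @param tensor_a,tensor_b Aligned tensors with identical trial counts
#'   and time grids.
#' @param window Search window `[from, to)` in seconds post-event.
#' @return A tibble: `trial`, `t_peak_a`, `t_peak_b`, `offset_s`,
#'   `flagged` (TRUE when either trace had no interior peak; offsets are
#'   `NA` there).
#' @export
peak_offset <- function(tensor_a, tensor_b, window = c(0, 5)) {
  if (nrow(tensor_a$mat) != nrow(tensor_b$mat)) {
    abort("tensors must have matched trials")
  }
  if (!isTRUE(all.equal(tensor_a$time, tensor_b$time))) {
    abort("tensors must share the time grid")
  }
  idx <- which(tensor_a$time >= window[1] & tensor_a$time < window[2])
  peak_t <- function(yv) {
    j <- which.max(yv)
    if (j == 1L || j == length(yv)) return(NA_real_)  # boundary: no peak
    tensor_a$time[idx[j]]
  }
  ta <- apply(tensor_a$mat[, idx, drop = FALSE], 1, peak_t)
  tb <- apply(tensor_b$mat[, idx, drop = FALSE], 1, peak_t)
  tibble::tibble(
    trial = seq_along(ta), t_peak_a = ta, t_peak_b = tb,
    offset_s = tb - ta, flagged = is.na(ta) | is.na(tb))
}

#' @export
autoplot.aligned_tensor <- function(object, ...) {
  df <- tidyr::expand_grid(trial = seq_len(nrow(object$mat)),
                           time_s = object$time)
  df$value <- as.vector(t(object$mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$trial,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$zscored) "z" else "dF/F") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_vline(xintercept = 0, colour = "white",
                        linetype = 2) +
    ggplot2::labs(x = "Time from event (s)", y = "Trial")
}

#' Plot the across-subject mean signal with its SEM ribbon
#'
#' @param tensor An `aligned_tensor` with subject metadata.
#' @return A ggplot object.
#' @export
plot_mean_signal <- function(tensor) {
  df <- subject_mean_signal(tensor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from event (s)",
                  y = if (tensor$zscored) "dF/F (z)" else "dF/F")
}
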