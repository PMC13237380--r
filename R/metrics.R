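# Scalar metrics: Sidak adjustment and ex vivo EPSC measurements.

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1. Monotone in both `p` and `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.01, m = 3)  # 0.029701
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < 1) abort("`m` must be >= 1")
  pmin(1 - (1 - p)^m, 1)
}

# Peak amplitude of a response epoch, relative to a pre-stimulus baseline
# mean, as the extremum (largest |deviation|) within the epoch.
epoch_peak <- function(time_ms, current_pA, from, to, baseline) {
  idx <- time_ms >= from & time_ms < to
  if (!any(idx)) abort("empty response epoch")
  dev <- current_pA[idx] - baseline
  dev[which.max(abs(dev))]
}

#' Paired-pulse ratio of a double-EPSC trace
#'
#' The ratio of the peak amplitude of the second EPSC to that of the
#' first, with each peak measured as the extremum from the pre-stimulus
#' baseline within its response epoch (stimulus to next stimulus /
#' equal-length epoch after the second).
#'
#' @param trace Tibble/data frame with `time_ms`, `current_pA`.
#' @param stim1,stim2 Stimulus times, ms (typically 50 ms apart).
#' @param baseline_ms Length of the pre-`stim1` baseline window.
#' @return The ratio `|peak2| / |peak1|`.
#' @export
paired_pulse_ratio <- function(trace, stim1, stim2, baseline_ms = 10) {
  if (stim2 <= stim1) abort("`stim2` must follow `stim1`")
  base_idx <- trace$time_ms >= (stim1 - baseline_ms) & trace$time_ms < stim1
  if (!any(base_idx)) abort("no samples in the baseline window")
  baseline <- mean(trace$current_pA[base_idx])
  isi <- stim2 - stim1
  p1 <- epoch_peak(trace$time_ms, trace$current_pA, stim1, stim2, baseline)
  p2 <- epoch_peak(trace$time_ms, trace$current_pA, stim2, stim2 + isi,
                   baseline)
  if (p1 == 0) abort("zero first-peak amplitude")
  abs(p2) / abs(p1)
}

#' Rectification index
#'
#' `|amplitude at +40 mV| / |amplitude at -70 mV|`; signs of the inputs
#' are irrelevant.
#'
#' @param amp_pos40,amp_neg70 EPSC amplitudes at the two holding
#'   potentials.
#' @return The index.
#' @export
rectification_index <- function(amp_pos40, amp_neg70) {
  if (any(amp_neg70 == 0)) abort("zero denominator amplitude")
  abs(amp_pos40) / abs(amp_neg70)
}

#' NASPM inhibition as baseline-normalised amplitude
#'
#' Mean drug-epoch EPSC amplitude divided by mean baseline amplitude
#' (baseline: the 5 min before application; drug epoch: four stimulations
#' starting 9 min after application, in the original protocol).
#'
#' @param baseline,drug Numeric vectors of EPSC amplitudes.
#' @return `mean(drug) / mean(baseline)`.
#' @export
naspm_inhibition <- function(baseline, drug) {
  if (length(baseline) < 1L || length(drug) < 1L) {
    abort("need >= 1 amplitude in each epoch")
  }
  mb <- mean(baseline)
  if (mb == 0) abort("zero baseline mean")
  mean(drug) / mb
}

interp_crossing <- function(t, yv, level, rising = TRUE) {
  # first crossing of `level`, linear interpolation between samples
  n <- length(yv)
  for (i in seq_len(n - 1L)) {
    lo <- yv[i]; hi <- yv[i + 1L]
    hit <- if (rising) lo < level && hi >= level else lo > level && hi <= level
    if (hit) {
      return(t[i] + (level - lo) / (hi - lo) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' 20-80% rise and decay times of an EPSC
#'
#' Rise = time from 20% to 80% of peak on the rising phase; decay = time
#' from 80% back down to 20% on the falling phase; crossings are linearly
#' interpolated between samples. The peak is measured relative to a
#' pre-stimulus baseline mean (10 ms window by default). Works on either
#' polarity (the trace is rectified around baseline internally).
#'
#' @param trace Tibble/data frame with `time_ms`, `current_pA`.
#' @param stim Stimulus time, ms (baseline taken before it; response
#'   after).
#' @param baseline_ms Pre-stimulus baseline window length, ms.
#' @return A tibble: `rise_ms`, `decay_ms`, `peak_pA` (signed, relative
#'   to baseline), `t_peak_ms`.
#' @export
rise_decay_times <- function(trace, stim = 0, baseline_ms = 10) {
  base_idx <- trace$time_ms >= (stim - baseline_ms) & trace$time_ms < stim
  baseline <- if (any(base_idx)) mean(trace$current_pA[base_idx]) else 0
  resp <- trace$time_ms >= stim
  t <- trace$time_ms[resp]
  yv <- trace$current_pA[resp] - baseline
  j <- which.max(abs(yv))
  peak <- yv[j]
  if (peak == 0) abort("no identifiable peak above baseline")
  w <- yv * sign(peak)  # rectify so the peak is positive
  pk <- abs(peak)
  t20r <- interp_crossing(t[1:j], w[1:j], 0.2 * pk, rising = TRUE)
  t80r <- interp_crossing(t[1:j], w[1:j], 0.8 * pk, rising = TRUE)
  t80f <- interp_crossing(t[j:length(t)], w[j:length(w)], 0.8 * pk,
                          rising = FALSE)
  t20f <- interp_crossing(t[j:length(t)], w[j:length(w)], 0.2 * pk,
                          rising = FALSE)
  if (anyNA(c(t20r, t80r, t80f, t20f))) {
    abort("could not locate all 20%/80% crossings")
  }
  tibble::tibble(rise_ms = t80r - t20r, decay_ms = t20f - t80f,
                 peak_pA = peak, t_peak_ms = t[j])
}

#' Current value at a fixed delay after the stimulus
#'
#' Point measure used for NMDA-receptor quantification: the (baseline-
#' subtracted, linearly interpolated) current 50 ms after the stimulus at
#' +40 mV in the original protocol.
#'
#' @param trace Tibble/data frame with `time_ms`, `current_pA`.
#' @param stim Stimulus time, ms.
#' @param offset_ms Delay after the stimulus, ms (default 50).
#' @param baseline_ms Pre-stimulus baseline window length, ms.
#' @return Interpolated current (pA) relative to baseline.
#' @export
epsc_amplitude_at <- function(trace, stim = 0, offset_ms = 50,
                              baseline_ms = 10) {
  base_idx <- trace$time_ms >= (stim - baseline_ms) & trace$time_ms < stim
  baseline <- if (any(base_idx)) mean(trace$current_pA[base_idx]) else 0
  target <- stim + offset_ms
  if (target < min(trace$time_ms) || target > max(trace$time_ms)) {
    abort("target time outside the trace")
  }
  stats::approx(trace$time_ms, trace$current_pA, xout = target)$y - baseline
}
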