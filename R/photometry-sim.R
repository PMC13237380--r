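# Synthetic two-channel fiber-photometry sessions with known ground truth.

#' Specify synthetic photometry transients and noise
#'
#' Describes the generative ingredients of a synthetic session: per-event
#' fluorescence transients (double-exponential kernels in dF/F units),
#' slow exponential bleaching shared by both channels, brief shared motion
#' artifacts, and white measurement noise.
#'
#' @param events Named list; each element is a list with `amplitude`
#'   (peak dF/F of the transient), `latency` (onset delay after the event,
#'   s), `rise` and `decay` (time constants, s, > 0).
#' @param bleach_tau Bleaching time constant, s.
#' @param bleach_depth Fractional fluorescence lost at infinite time,
#'   in `[0, 1)`.
#' @param artifact_amplitude SD of shared motion-artifact bump amplitudes
#'   (raw fluorescence units).
#' @param artifact_rate Rate of artifact bumps, events/s.
#' @param noise_sd SD of per-channel white noise (raw units).
#' @param rate_hz Sampling rate; must comfortably resolve the fastest
#'   transient.
#' @return A `transient_spec` object.
#' @export
transient_spec <- function(events = list(
                             safety = list(amplitude = 0.05, latency = 0,
                                           rise = 0.1, decay = 0.5)),
                           bleach_tau = 600, bleach_depth = 0.2,
                           artifact_amplitude = 0.02, artifact_rate = 0.1,
                           noise_sd = 0.003, rate_hz = 20) {
  for (nm in names(events)) {
    ev <- events[[nm]]
    if (!is.finite(ev$amplitude)) abort("transient amplitudes must be finite")
    if (ev$rise <= 0 || ev$decay <= 0) abort("time constants must be > 0")
  }
  if (bleach_tau <= 0) abort("`bleach_tau` must be > 0")
  if (bleach_depth < 0 || bleach_depth >= 1) {
    abort("`bleach_depth` must be in [0, 1)")
  }
  fastest <- min(vapply(events, function(e) e$rise, numeric(1)))
  if (rate_hz <= 2 / (2 * pi * fastest)) {
    abort("`rate_hz` too low to resolve the fastest transient")
  }
  structure(list(events = events, bleach_tau = bleach_tau,
                 bleach_depth = bleach_depth,
                 artifact_amplitude = artifact_amplitude,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 rate_hz = rate_hz),
            class = "transient_spec")
}

transient_kernel <- function(t, rise, decay) {
  k <- (1 - exp(-pmax(t, 0) / rise)) * exp(-pmax(t, 0) / decay)
  k[t < 0] <- 0
  # normalise to unit peak (argmax at rise * log(1 + decay/rise))
  tp <- rise * log(1 + decay / rise)
  peak <- (1 - exp(-tp / rise)) * exp(-tp / decay)
  k / peak
}

#' Generate a synthetic two-channel photometry session
#'
#' The 405 nm (isosbestic) channel carries baseline x bleach, shared
#' motion artifacts and white noise. The 473 nm channel is an affine image
#' of the systematic 405 part (`slope`, `intercept`, recorded as ground
#' truth) plus event-locked transients scaled so that their downstream
#' dF/F peak equals the specified amplitude, plus independent noise.
#'
#' @param events Named list mapping event name to a numeric vector of
#'   event times (s), all within `[0, duration]`.
#' @param spec A [transient_spec()].
#' @param duration Session length, s (> 0).
#' @param seed Integer seed.
#' @param slope,intercept Affine map from the systematic 405 component to
#'   the 473 baseline.
#' @return A `photometry_session`: list with `signals` (tibble `time_s`,
#'   `f473`, `f405`), `events` (tibble `event`, `time_s`), `rate_hz`, and
#'   `truth` (slope, intercept, the spec, and the injected noise floor).
#' @export
generate_photometry <- function(events, spec, duration, seed = 1L,
                                slope = 1.8, intercept = 0.3) {
  if (!inherits(spec, "transient_spec")) abort("`spec` must be a transient_spec")
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0")
  ev_times <- unlist(events, use.names = FALSE)
  if (length(ev_times) && (min(ev_times) < 0 || max(ev_times) > duration)) {
    abort("all event times must lie within [0, duration]")
  }
  seeded(seed, function() {
    t <- seq(0, duration, by = 1 / spec$rate_hz)
    n <- length(t)
    systematic <- 1 * ((1 - spec$bleach_depth) +
                         spec$bleach_depth * exp(-t / spec$bleach_tau))
    n_art <- rpois(1L, spec$artifact_rate * duration)
    if (n_art > 0 && spec$artifact_amplitude > 0) {
      at <- runif(n_art, 0, duration)
      aa <- rnorm(n_art, 0, spec$artifact_amplitude)
      for (j in seq_len(n_art)) {
        systematic <- systematic + aa[j] * exp(-pmax(t - at[j], 0) / 0.3) *
          (t >= at[j])
      }
    }
    base473 <- slope * systematic + intercept
    transients <- numeric(n)
    for (nm in names(spec$events)) {
      ev <- spec$events[[nm]]
      for (t0 in events[[nm]] %||% numeric(0)) {
        transients <- transients +
          ev$amplitude * transient_kernel(t - t0 - ev$latency,
                                          ev$rise, ev$decay)
      }
    }
    f405 <- systematic + rnorm(n, 0, spec$noise_sd)
    f473 <- base473 * (1 + transients) + rnorm(n, 0, spec$noise_sd)
    ev_tbl <- tibble::tibble(
      event = rep(names(events), lengths(events)),
      time_s = unlist(events, use.names = FALSE) %||% numeric(0))
    structure(list(
      signals = tibble::tibble(time_s = t, f473 = f473, f405 = f405),
      events = ev_tbl,
      rate_hz = spec$rate_hz,
      truth = list(slope = slope, intercept = intercept, spec = spec,
                   noise_sd = spec$noise_sd, seed = as.integer(seed))
    ), class = "photometry_session")
  })
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %d samples at %g Hz, %d events (%s)\n",
              nrow(x$signals), x$rate_hz, nrow(x$events),
              paste(unique(x$events$event), collapse = ", ")))
  invisible(x)
}

#' Read or write a photometry session as two delimited files
#'
#' `signals_path` holds `time_s,f473,f405[,f560]`; `events_path` holds
#' `event,time_s`.
#'
#' @param x A `photometry_session`.
#' @param signals_path,events_path File paths.
#' @return `read_photometry()` returns the session; `write_photometry()`
#'   its input, invisibly.
#' @export
write_photometry <- function(x, signals_path, events_path) {
  utils::write.table(as.data.frame(x$signals), signals_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(x$events), events_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname write_photometry
#' @export
read_photometry <- function(signals_path, events_path) {
  sig <- tibble::as_tibble(utils::read.csv(signals_path))
  ev <- tibble::as_tibble(utils::read.csv(events_path))
  dt <- diff(sig$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    abort("signals must be on a strictly increasing uniform time grid")
  }
  structure(list(signals = sig, events = ev,
                 rate_hz = 1 / stats::median(dt), truth = NULL),
            class = "photometry_session")
}
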