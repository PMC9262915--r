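#' Configuration for the synthetic sIPSC trace generator
#'
#' Spontaneous inhibitory postsynaptic currents recorded under voltage clamp
#' at 0 mV are outward (positive) currents with a fast rise and slower
#' exponential decay. Events arrive as a Poisson process; amplitudes are
#' log-normal; the trace carries Gaussian instrument noise and a slow
#' membrane drift.
#'
#' @param duration_s recording length (s).
#' @param rate_hz sampling rate (Hz), default 20000.
#' @param event_rate_hz Poisson event rate (Hz).
#' @param rise_ms,decay_ms biexponential time constants (ms); rise < decay.
#' @param amp_mean_pa,amp_cv log-normal amplitude mean (pA) and coefficient
#'   of variation.
#' @param noise_sd_pa Gaussian noise SD (pA).
#' @param drift_amp_pa,drift_freq_hz slow sinusoidal baseline drift.
#' @param polarity +1 for outward currents (clamp at 0 mV), -1 for inward.
#' @return list of class \code{"ipsc_sim_config"}.
#' @export
ipsc_sim_config <- function(duration_s = 120, rate_hz = 20000,
                            event_rate_hz = 5, rise_ms = 0.5, decay_ms = 10,
                            amp_mean_pa = 50, amp_cv = 0.3, noise_sd_pa = 5,
                            drift_amp_pa = 10, drift_freq_hz = 0.05,
                            polarity = 1) {
  if (rise_ms >= decay_ms) stop("rise_ms must be < decay_ms")
  if (event_rate_hz < 0) stop("event_rate_hz must be >= 0")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 event_rate_hz = event_rate_hz, rise_ms = rise_ms,
                 decay_ms = decay_ms, amp_mean_pa = amp_mean_pa,
                 amp_cv = amp_cv, noise_sd_pa = noise_sd_pa,
                 drift_amp_pa = drift_amp_pa, drift_freq_hz = drift_freq_hz,
                 polarity = polarity),
            class = "ipsc_sim_config")
}

# Biexponential synaptic kernel normalized to unit peak.
ipsc_kernel <- function(rate_hz, rise_ms, decay_ms, length_ms = NULL) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  if (is.null(length_ms)) length_ms <- decay_ms * 8
  t <- seq(0, length_ms / 1000, by = 1 / rate_hz)
  h <- exp(-t / td) - exp(-t / tr)
  h / max(h)
}

#' Simulate a voltage-clamp trace with ground-truth sIPSCs
#'
#' @param cfg an \code{\link{ipsc_sim_config}}.
#' @param seed integer seed; output is a pure function of (cfg, seed).
#' @return list with \code{signal} (\code{\link{uniform_signal}}, pA) and
#'   \code{truth} (\code{\link{event_table}}: onset, time of true peak, and
#'   programmed peak amplitude in pA).
#' @export
simulate_ipsc_trace <- function(cfg = ipsc_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "ipsc_sim_config"))
  set.seed(seed)
  n <- round(cfg$duration_s * cfg$rate_hz)
  t <- (0:(n - 1)) / cfg$rate_hz
  x <- cfg$drift_amp_pa * sin(2 * pi * cfg$drift_freq_hz * t)
  n_ev <- stats::rpois(1, cfg$event_rate_hz * cfg$duration_s)
  kern <- ipsc_kernel(cfg$rate_hz, cfg$rise_ms, cfg$decay_ms)
  tr <- cfg$rise_ms / 1000; td <- cfg$decay_ms / 1000
  t_peak_rel <- tr * td / (td - tr) * log(td / tr)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, cfg$duration_s - 10 * td))
    sdlog <- sqrt(log(1 + cfg$amp_cv^2))
    amps <- stats::rlnorm(n_ev, log(cfg$amp_mean_pa) - sdlog^2 / 2, sdlog)
    for (k in seq_len(n_ev)) {
      i0 <- round(onsets[k] * cfg$rate_hz) + 1
      idx <- i0:min(i0 + length(kern) - 1, n)
      x[idx] <- x[idx] + cfg$polarity * amps[k] * kern[seq_along(idx)]
    }
    truth <- event_table(onset_s = onsets, peak_s = onsets + t_peak_rel,
                         offset_s = onsets + 5 * td, amplitude = amps)
  } else {
    truth <- event_table()
  }
  if (cfg$noise_sd_pa > 0) x <- x + stats::rnorm(n, sd = cfg$noise_sd_pa)
  list(signal = uniform_signal(x, cfg$rate_hz, 0, "pA"), truth = truth)
}

#' Parameters for threshold-triggered sIPSC detection
#'
#' The detector works on a differentiated copy of the trace: an event
#' triggers where the (optionally boxcar-smoothed) derivative stays above
#' \code{derivative_threshold} for at least \code{trigger_duration_ms}.
#' Threshold and trigger duration are the per-cell criteria an
#' electrophysiologist adjusts to separate synaptic rise slopes from noise
#' and slow membrane fluctuations; both are reported in the output
#' attributes for provenance.
#'
#' @param derivative_threshold trigger threshold on the derivative (pA/ms).
#' @param trigger_duration_ms minimum continuous supra-threshold run (ms).
#' @param smoothing_ms boxcar width applied to the derivative and to the
#'   trace copy used for peak/baseline measurement (0 = none).
#' @param peak_window_ms window after onset searched for the event peak.
#' @param baseline_window_ms pre-onset window whose median is the baseline.
#' @param refractory_ms re-triggers this close to an onset are ignored.
#' @param polarity +1 outward / -1 inward.
#' @return list of class \code{"ipsc_detect_params"}.
#' @export
ipsc_detect_params <- function(derivative_threshold = 12,
                               trigger_duration_ms = 0.4, smoothing_ms = 1,
                               peak_window_ms = 10, baseline_window_ms = 5,
                               refractory_ms = 2, polarity = 1) {
  if (derivative_threshold <= 0) stop("derivative_threshold must be > 0")
  if (any(c(trigger_duration_ms, smoothing_ms, peak_window_ms,
            baseline_window_ms, refractory_ms) < 0)) {
    stop("durations must be >= 0")
  }
  structure(list(derivative_threshold = derivative_threshold,
                 trigger_duration_ms = trigger_duration_ms,
                 smoothing_ms = smoothing_ms,
                 peak_window_ms = peak_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 refractory_ms = refractory_ms, polarity = polarity),
            class = "ipsc_detect_params")
}

boxcar <- function(x, width) {
  if (width <= 1) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  na <- is.na(y)
  y[na] <- x[na]
  y
}

#' Detect spontaneous IPSCs from a voltage-clamp trace
#'
#' @param signal a \code{\link{uniform_signal}} in pA, rate at least 1 kHz.
#' @param params an \code{\link{ipsc_detect_params}}.
#' @return an \code{\link{event_table}} (onset, peak, offset, amplitude in
#'   pA relative to the pre-onset baseline median), with the detection
#'   parameters attached as attribute \code{"params"}.
#' @export
detect_ipsc_events <- function(signal, params = ipsc_detect_params()) {
  stopifnot(inherits(signal, "uniform_signal"))
  rate <- signal$rate_hz
  if (rate < 1000) stop("sampling rate must be >= 1 kHz")
  trig_n <- max(1L, round(params$trigger_duration_ms / 1000 * rate))
  if (params$trigger_duration_ms > 0 &&
      params$trigger_duration_ms / 1000 * rate < 2) {
    stop("trigger_duration_ms spans < 2 samples at this rate")
  }
  x <- params$polarity * signal$values
  deriv <- c(diff(x), 0) * rate / 1000          # pA/ms
  sm_n <- round(params$smoothing_ms / 1000 * rate)
  deriv <- boxcar(deriv, sm_n)
  xm <- boxcar(x, sm_n)                         # measurement copy
  above <- deriv > params$derivative_threshold
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  cand <- which(r$values & r$lengths >= trig_n)
  onsets_i <- run_start[cand]
  if (!length(onsets_i)) {
    return(structure(event_table(), params = params))
  }
  refr_n <- params$refractory_ms / 1000 * rate
  keep <- c(TRUE, diff(onsets_i) >= refr_n)
  while (!all(keep)) {
    onsets_i <- onsets_i[keep]
    keep <- c(TRUE, diff(onsets_i) >= refr_n)
  }
  n <- length(x)
  pw <- max(1L, round(params$peak_window_ms / 1000 * rate))
  bw <- max(1L, round(params$baseline_window_ms / 1000 * rate))
  onset_s <- peak_s <- amp <- numeric(length(onsets_i))
  for (k in seq_along(onsets_i)) {
    i0 <- onsets_i[k]
    win <- i0:min(i0 + pw, n)
    pk <- win[which.max(xm[win])]
    bwin <- max(1, i0 - bw):max(1, i0 - 1)
    base <- stats::median(xm[bwin])
    onset_s[k] <- signal$t0_s + (i0 - 1) / rate
    peak_s[k] <- signal$t0_s + (pk - 1) / rate
    amp[k] <- xm[pk] - base
  }
  out <- event_table(onset_s = onset_s, peak_s = peak_s,
                     offset_s = peak_s, amplitude = amp)
  attr(out, "params") <- params
  out
}

#' Per-cell sIPSC summary
#'
#' @param events an \code{\link{event_table}} from
#'   \code{\link{detect_ipsc_events}}.
#' @param recording_duration_s recording length (s), > 0.
#' @return list with \code{frequency_hz}, \code{mean_amplitude_pa}
#'   (\code{NA} and \code{amplitude_defined = FALSE} when no events), and
#'   \code{n_events}.
#' @export
summarize_ipsc <- function(events, recording_duration_s) {
  if (recording_duration_s <= 0) stop("recording duration must be > 0")
  n <- nrow(events)
  list(frequency_hz = n / recording_duration_s,
       mean_amplitude_pa = if (n) mean(events$amplitude) else NA_real_,
       amplitude_defined = n > 0,
       n_events = n)
}
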