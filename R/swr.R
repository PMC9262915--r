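#' Parameters for sharp-wave ripple detection
#'
#' The detector band-passes the pyramidal-layer LFP in the ripple band,
#' rectifies and Gaussian-smooths it into an envelope, standardizes the
#' envelope against immobility baseline statistics, and thresholds.
#'
#' @param band_lo_hz,band_hi_hz ripple band edges (Hz); defaults 70 and 250.
#' @param envelope_gauss_sd_ms SD of the Gaussian smoothing kernel applied to
#'   the rectified band-passed signal (ms). Default 4 ms, about half a ripple
#'   cycle at 150 Hz.
#' @param threshold_sd detection threshold in baseline-SD units (default 3).
#' @param boundary_sd event onset/offset boundary in SD units (default 1);
#'   must be below \code{threshold_sd}.
#' @param min_dur_ms minimum duration of the supra-threshold core of a
#'   candidate (ms).
#' @param max_dur_ms maximum duration of the boundary-extended event (ms).
#' @param merge_gap_ms events separated by less than this are merged (ms).
#' @return list of class \code{"ripple_params"}.
#' @export
ripple_params <- function(band_lo_hz = 70, band_hi_hz = 250,
                          envelope_gauss_sd_ms = 4, threshold_sd = 3,
                          boundary_sd = 1, min_dur_ms = 20, max_dur_ms = 250,
                          merge_gap_ms = 15) {
  if (band_lo_hz <= 0 || band_hi_hz <= band_lo_hz) stop("need 0 < lo < hi")
  if (!(threshold_sd > boundary_sd && boundary_sd > 0)) {
    stop("need threshold_sd > boundary_sd > 0")
  }
  if (min_dur_ms >= max_dur_ms) stop("need min_dur_ms < max_dur_ms")
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 envelope_gauss_sd_ms = envelope_gauss_sd_ms,
                 threshold_sd = threshold_sd, boundary_sd = boundary_sd,
                 min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
                 merge_gap_ms = merge_gap_ms),
            class = "ripple_params")
}

#' Ripple-band envelope of an LFP signal
#'
#' Zero-phase bandpass in \code{[band_lo_hz, band_hi_hz]} followed by
#' rectification (absolute value) and Gaussian smoothing with SD
#' \code{envelope_gauss_sd_ms}. The filter's cosine-tapered transitions reach
#' full stopband rejection at 0.8x the lower and 1.2x the upper band edge.
#'
#' @param signal a \code{\link{uniform_signal}} (pyramidal-layer LFP);
#'   \code{rate_hz} must be at least twice the upper band edge.
#' @param params a \code{\link{ripple_params}}.
#' @return a dimensionless \code{\link{uniform_signal}} at the input rate.
#' @export
ripple_envelope <- function(signal, params = ripple_params()) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (signal$rate_hz < 2 * params$band_hi_hz) {
    stop(sprintf("rate %g Hz below Nyquist requirement %g Hz",
                 signal$rate_hz, 2 * params$band_hi_hz))
  }
  filt <- fft_bandpass(signal$values, signal$rate_hz,
                       params$band_lo_hz, params$band_hi_hz)
  env <- gauss_smooth(abs(filt), signal$rate_hz,
                      params$envelope_gauss_sd_ms / 1000)
  uniform_signal(env, signal$rate_hz, signal$t0_s, "dimensionless")
}

#' Baseline envelope statistics during immobility
#'
#' Mean and SD of the ripple envelope restricted to non-movement periods;
#' these define the SD unit in which ripple power is expressed.
#'
#' @param envelope envelope \code{\link{uniform_signal}} from
#'   \code{\link{ripple_envelope}}.
#' @param immobility \code{\link{interval_set}} of non-movement periods;
#'   at least \code{min_immobility_s} of total duration is required.
#' @param min_immobility_s minimum immobility needed for a stable estimate.
#' @return list of class \code{"baseline_stats"} with \code{mu}, \code{sd},
#'   \code{source_intervals}, \code{n_samples}.
#' @export
baseline_stats <- function(envelope, immobility, min_immobility_s = 10) {
  immobility <- as_interval_set(immobility)
  if (iv_duration(immobility) < min_immobility_s) {
    stop(sprintf("immobility duration %.2f s below required minimum %g s",
                 iv_duration(immobility), min_immobility_s))
  }
  vals <- restrict(envelope, immobility)
  structure(list(mu = mean(vals), sd = stats::sd(vals),
                 source_intervals = immobility, n_samples = length(vals)),
            class = "baseline_stats")
}

#' Detect sharp-wave ripples from a standardized envelope
#'
#' Candidate events are maximal runs of the z-scored envelope above
#' \code{threshold_sd}; candidates separated by less than
#' \code{merge_gap_ms} are merged. The duration criteria are applied to the
#' merged supra-threshold core: cores shorter than \code{min_dur_ms} or
#' longer than \code{max_dur_ms} are discarded (brief noise excursions cross
#' a 3-SD threshold routinely, but only a genuine ripple holds it for tens
#' of milliseconds). Each surviving event is extended outward to the nearest
#' crossing of \code{boundary_sd}, which defines its reported onset/offset.
#' Per-event power is in baseline-SD units: \code{mean_power_sd} is the mean
#' z over \code{[onset, offset)} and \code{max_power_sd} the peak z over the
#' core.
#'
#' @param envelope envelope \code{\link{uniform_signal}}.
#' @param stats a \code{\link{baseline_stats}} from the same envelope
#'   definition.
#' @param params a \code{\link{ripple_params}}.
#' @return an \code{\link{event_table}} with columns \code{onset_s},
#'   \code{peak_s}, \code{offset_s}, \code{amplitude} (= max z),
#'   \code{mean_power_sd}, \code{max_power_sd}, \code{duration_ms}.
#' @export
detect_swr <- function(envelope, stats, params = ripple_params()) {
  stopifnot(inherits(envelope, "uniform_signal"),
            inherits(stats, "baseline_stats"))
  z <- (envelope$values - stats$mu) / stats$sd
  rate <- envelope$rate_hz
  n <- length(z)
  above_thr <- z > params$threshold_sd
  if (!any(above_thr)) return(swr_empty_table())
  above_bnd <- z > params$boundary_sd
  r <- rle(above_thr)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  cs <- run_start[r$values]; ce <- run_end[r$values]
  # merge cores separated by short gaps, then apply the duration criteria
  # to the (merged) supra-threshold core
  gap_samp <- params$merge_gap_ms / 1000 * rate
  m_on <- cs[1]; m_off <- ce[1]
  for (k in seq_along(cs)[-1]) {
    if (cs[k] - m_off[length(m_off)] < gap_samp) {
      m_off[length(m_off)] <- ce[k]
    } else {
      m_on <- c(m_on, cs[k]); m_off <- c(m_off, ce[k])
    }
  }
  core_ms <- (m_off - m_on + 1) / rate * 1000
  ok <- core_ms >= params$min_dur_ms & core_ms <= params$max_dur_ms
  m_on <- m_on[ok]; m_off <- m_off[ok]
  if (!length(m_on)) return(swr_empty_table())
  # extend each event outward to the boundary_sd crossings; nearby events
  # may share a boundary run, which only widens their reported extent
  rb <- rle(above_bnd)
  rb_end <- cumsum(rb$lengths)
  rb_start <- rb_end - rb$lengths + 1
  bs <- rb_start[rb$values]; be <- rb_end[rb$values]
  on_i <- bs[findInterval(m_on, bs)]
  off_i <- be[findInterval(m_off, bs)]
  t_of <- function(i) envelope$t0_s + (i - 1) / rate
  peak_i <- mean_z <- max_z <- numeric(length(m_on))
  for (k in seq_along(m_on)) {
    idx <- on_i[k]:off_i[k]
    core <- m_on[k]:m_off[k]
    peak_i[k] <- core[which.max(z[core])]
    mean_z[k] <- mean(z[idx])
    max_z[k] <- max(z[core])
  }
  event_table(onset_s = t_of(on_i), peak_s = t_of(peak_i),
              offset_s = t_of(off_i + 1), amplitude = max_z,
              mean_power_sd = mean_z, max_power_sd = max_z,
              duration_ms = (off_i - on_i + 1) / rate * 1000)
}

swr_empty_table <- function() {
  event_table(numeric(0), numeric(0), numeric(0), numeric(0),
              mean_power_sd = numeric(0), max_power_sd = numeric(0),
              duration_ms = numeric(0))
}

#' Sharp-wave ripple occurrence rate during immobility
#'
#' Counts events whose envelope peak lies inside immobility and divides by
#' total immobility time (ripples are immobility events; set
#' \code{denominator = "total"} to divide by the whole recording instead).
#'
#' @param events an \code{\link{event_table}} from \code{\link{detect_swr}}.
#' @param immobility \code{\link{interval_set}} with positive duration.
#' @param denominator \code{"immobility"} (default) or \code{"total"}.
#' @param total_duration_s recording length; required for
#'   \code{denominator = "total"}.
#' @return events per second.
#' @export
swr_rate <- function(events, immobility, denominator = c("immobility",
                     "total"), total_duration_s = NULL) {
  denominator <- match.arg(denominator)
  immobility <- as_interval_set(immobility)
  dur <- iv_duration(immobility)
  if (dur <= 0) stop("immobility duration must be > 0")
  n <- if (nrow(events)) sum(in_intervals(events$peak_s, immobility)) else 0L
  if (denominator == "total") {
    if (is.null(total_duration_s)) stop("total_duration_s required")
    return(n / total_duration_s)
  }
  n / dur
}

#' Detect ripples across sessions with a common threshold
#'
#' Baseline statistics are computed on the concatenation of all sessions'
#' immobility-restricted envelopes, and \code{\link{detect_swr}} is run per
#' session with those shared statistics — removing any between-session
#' detection-threshold difference.
#'
#' @param sessions list of sessions, each a list with elements
#'   \code{envelope} (\code{\link{uniform_signal}}) and \code{immobility}
#'   (\code{\link{interval_set}}); all envelopes must share one rate.
#' @param params a \code{\link{ripple_params}}.
#' @return list with \code{events} (per-session list of event tables) and
#'   \code{stats} (the shared \code{baseline_stats}).
#' @export
detect_swr_common_threshold <- function(sessions, params = ripple_params()) {
  if (!length(sessions)) stop("need at least one session")
  rates <- vapply(sessions, function(s) s$envelope$rate_hz, numeric(1))
  if (length(unique(rates)) != 1) {
    stop("sessions have heterogeneous sampling rates")
  }
  pooled <- unlist(lapply(sessions, function(s) {
    restrict(s$envelope, as_interval_set(s$immobility))
  }), use.names = FALSE)
  if (length(pooled) < 2) stop("too few immobility samples to pool")
  shared <- structure(list(mu = mean(pooled), sd = stats::sd(pooled),
                           source_intervals = NULL,
                           n_samples = length(pooled)),
                      class = "baseline_stats")
  events <- lapply(sessions, function(s) {
    detect_swr(s$envelope, shared, params)
  })
  list(events = events, stats = shared)
}
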