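#' Configuration for the synthetic LFP generator
#'
#' Describes a head-fixed CA1 recording session: 1/f background noise
#' throughout, theta and gamma oscillations during mobility, and sharp-wave
#' ripples arriving as a Poisson process during immobility. Ripple amplitude
#' is specified in analysis-envelope SD units (see
#' \code{\link{simulate_lfp}}) so detector behavior at the 3-SD threshold can
#' be programmed directly.
#'
#' @param duration_s session length (s).
#' @param rate_hz sampling rate (Hz); acquisition-grade default 20000.
#' @param ripple_rate_hz Poisson arrival rate of ripples during immobility.
#' @param ripple_freq_hz ripple carrier frequency (Hz).
#' @param ripple_dur_ms SD of the Gaussian ripple amplitude envelope (ms).
#' @param ripple_amp_sd target analysis-envelope peak in baseline-SD units.
#' @param ripple_refractory_s minimum spacing between ripple peaks; Poisson
#'   times are thinned to enforce it so ground-truth events never overlap.
#' @param theta_freq_hz,theta_amp_mv theta oscillation (mobility only).
#' @param theta_4hz_frac amplitude of the co-varying 4 Hz slow component,
#'   as a fraction of \code{theta_amp_mv}; scaling theta scales both, so the
#'   8 Hz / 4 Hz power ratio is a waveform property independent of
#'   oscillation amplitude.
#' @param gamma_band_hz,gamma_amp_mv band-limited gamma noise (mobility only).
#' @param noise_sd_mv SD of the 1/f background.
#' @param noise_exponent spectral exponent of the background (power ~ 1/f^e).
#' @param mobility_schedule \code{\link{interval_set}} of mobility bouts, or
#'   \code{NULL} for alternating 30 s mobility / 30 s immobility blocks
#'   (50 percent immobility).
#' @param analysis_params \code{\link{ripple_params}} defining the envelope
#'   against which ripple amplitude is calibrated.
#' @return list of class \code{"lfp_sim_config"}.
#' @export
lfp_sim_config <- function(duration_s = 600, rate_hz = 20000,
                           ripple_rate_hz = 0.3, ripple_freq_hz = 150,
                           ripple_dur_ms = 20, ripple_amp_sd = 6,
                           ripple_refractory_s = 0.2,
                           theta_freq_hz = 8, theta_amp_mv = 0.1,
                           theta_4hz_frac = 0.35,
                           gamma_band_hz = c(30, 90), gamma_amp_mv = 0.03,
                           noise_sd_mv = 0.05, noise_exponent = 2,
                           mobility_schedule = NULL,
                           analysis_params = ripple_params()) {
  if (duration_s <= 0 || rate_hz <= 0) stop("duration and rate must be > 0")
  if (ripple_rate_hz < 0) stop("ripple_rate_hz must be >= 0")
  if (is.null(mobility_schedule)) {
    starts <- seq(0, duration_s - 1e-9, by = 60)
    mobility_schedule <- interval_set(starts, pmin(starts + 30, duration_s))
  }
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 ripple_rate_hz = ripple_rate_hz,
                 ripple_freq_hz = ripple_freq_hz,
                 ripple_dur_ms = ripple_dur_ms,
                 ripple_amp_sd = ripple_amp_sd,
                 ripple_refractory_s = ripple_refractory_s,
                 theta_freq_hz = theta_freq_hz, theta_amp_mv = theta_amp_mv,
                 theta_4hz_frac = theta_4hz_frac,
                 gamma_band_hz = gamma_band_hz, gamma_amp_mv = gamma_amp_mv,
                 noise_sd_mv = noise_sd_mv, noise_exponent = noise_exponent,
                 mobility_schedule = as_interval_set(mobility_schedule),
                 analysis_params = analysis_params),
            class = "lfp_sim_config")
}

# Unit-amplitude ripple kernel: cosine carrier under a Gaussian envelope.
ripple_kernel <- function(rate_hz, freq_hz, env_sd_s) {
  half <- ceiling(4 * env_sd_s * rate_hz)
  t <- (-half:half) / rate_hz
  cos(2 * pi * freq_hz * t) * exp(-t^2 / (2 * env_sd_s^2))
}

#' Simulate a CA1 LFP session with ground-truth ripples
#'
#' The background (1/f noise plus mobility-gated theta and gamma) is built
#' first; its ripple-band envelope over immobility supplies the baseline mean
#' and SD. Each ripple is a Gaussian-enveloped cosine at
#' \code{ripple_freq_hz} whose raw amplitude is calibrated per event against
#' the analysis envelope definition: a root solve on the local window makes
#' the envelope of background-plus-ripple peak at exactly
#' \code{mu + ripple_amp_sd * sd}, so the programmed SD amplitude is what
#' the detector will measure. Ripple times are Poisson within immobility,
#' thinned to the refractory spacing, and kept clear of interval edges so
#' every event lies wholly inside immobility.
#'
#' @param cfg an \code{\link{lfp_sim_config}}.
#' @param seed integer seed; output is a pure function of (cfg, seed).
#' @return list with \code{signal} (\code{\link{uniform_signal}}, mV),
#'   \code{truth} (\code{\link{event_table}} of programmed ripples,
#'   amplitude in envelope-SD units), \code{mobility} and \code{immobility}
#'   (\code{\link{interval_set}}s), and \code{baseline} (the background
#'   envelope mu/sd used for calibration).
#' @export
simulate_lfp <- function(cfg = lfp_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "lfp_sim_config"))
  set.seed(seed)
  n <- round(cfg$duration_s * cfg$rate_hz)
  t <- (0:(n - 1)) / cfg$rate_hz
  mobility <- cfg$mobility_schedule
  immobility <- iv_complement(mobility, 0, cfg$duration_s)
  if (iv_duration(immobility) <= 0 && cfg$ripple_rate_hz > 0) {
    stop("ripple_rate_hz > 0 requires some immobility in the schedule")
  }
  bg <- cfg$noise_sd_mv * colored_noise(n, cfg$rate_hz, cfg$noise_exponent)
  if (cfg$theta_amp_mv > 0 || cfg$gamma_amp_mv > 0) {
    mob_ind <- in_intervals(t, mobility)
    osc <- cfg$theta_amp_mv * (sin(2 * pi * cfg$theta_freq_hz * t) +
                               cfg$theta_4hz_frac * sin(2 * pi * 4 * t))
    gam <- fft_bandpass(stats::rnorm(n), cfg$rate_hz,
                        cfg$gamma_band_hz[1], cfg$gamma_band_hz[2])
    osc <- osc + cfg$gamma_amp_mv * gam / stats::sd(gam)
    bg <- bg + osc * mob_ind
  }
  # calibration baseline: envelope of the ripple-free background
  env_sd_s <- cfg$ripple_dur_ms / 1000
  bg_sig <- uniform_signal(bg, cfg$rate_hz, 0, "mV")
  env_bg <- ripple_envelope(bg_sig, cfg$analysis_params)
  base <- baseline_stats(env_bg, immobility,
                         min_immobility_s = min(10, iv_duration(immobility)))
  kern <- ripple_kernel(cfg$rate_hz, cfg$ripple_freq_hz, env_sd_s)

  # Poisson ripple times inside immobility, clear of edges, refractory-thinned
  margin <- 3 * env_sd_s
  peaks <- numeric(0)
  if (cfg$ripple_rate_hz > 0) {
    for (i in seq_len(nrow(immobility))) {
      a <- immobility$start_s[i] + margin
      b <- immobility$end_s[i] - margin
      if (b <= a) next
      k <- stats::rpois(1, cfg$ripple_rate_hz * (b - a))
      if (k > 0) peaks <- c(peaks, stats::runif(k, a, b))
    }
    peaks <- sort(peaks)
    if (length(peaks) > 1) {
      keep <- c(TRUE, diff(peaks) >= cfg$ripple_refractory_s)
      while (!all(keep)) {          # re-thin against the kept predecessor
        peaks <- peaks[keep]
        keep <- c(TRUE, diff(peaks) >= cfg$ripple_refractory_s)
      }
    }
  }
  # Per-event amplitude calibration against the analysis envelope: for each
  # event, solve for the raw amplitude that makes the local envelope of
  # (background + a * kernel) peak exactly at mu + ripple_amp_sd * sd.
  x <- bg
  half <- (length(kern) - 1) / 2
  amps_mv <- numeric(length(peaks))
  target <- base$mu + cfg$ripple_amp_sd * base$sd
  hw <- round(0.5 * cfg$rate_hz)            # 0.5 s local window
  for (k in seq_along(peaks)) {
    c_i <- round(peaks[k] * cfg$rate_hz) + 1
    w0 <- max(1, c_i - hw); w1 <- min(n, c_i + hw)
    bgw <- bg[w0:w1]
    kin <- (c_i - half):(c_i + half)
    okk <- kin >= w0 & kin <= w1
    core <- (c_i - w0 + 1) + (-half:half)[okk]
    peak_env <- function(a) {
      xw <- bgw
      xw[core] <- xw[core] + a * kern[okk]
      ew <- ripple_envelope(uniform_signal(xw, cfg$rate_hz, 0, "mV"),
                            cfg$analysis_params)$values
      max(ew[core])
    }
    a0 <- target / 0.6                      # rectified-cosine initial scale
    amps_mv[k] <- if (peak_env(0) >= target) {
      0  # local excursion already reaches the target envelope; nothing added
    } else {
      stats::uniroot(function(a) peak_env(a) - target, lower = 0,
                     upper = 4 * a0, extendInt = "upX",
                     tol = target * 1e-4)$root
    }
    idx <- kin[okk]
    x[idx] <- x[idx] + amps_mv[k] * kern[okk]
  }
  truth <- event_table(onset_s = peaks - 2 * env_sd_s, peak_s = peaks,
                       offset_s = peaks + 2 * env_sd_s,
                       amplitude = rep(cfg$ripple_amp_sd, length(peaks)),
                       amp_mv = amps_mv)
  list(signal = uniform_signal(x, cfg$rate_hz, 0, "mV"), truth = truth,
       mobility = mobility, immobility = immobility,
       baseline = list(mu = base$mu, sd = base$sd))
}
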