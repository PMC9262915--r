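#' Configuration for the synthetic fiber-photometry generator
#'
#' Emulates a one-fiber GCaMP recording during open-field exploration: a
#' speed profile with discrete mobility bouts drives neural activity through
#' a linear acceleration coupling and a calcium-indicator kernel; the
#' calcium-dependent (465 nm) and isosbestic (405 nm) channels share one
#' bleaching trend and one motion-artifact component, so the isosbestic
#' regression can remove both.
#'
#' @param duration_s session length (s).
#' @param rate_hz photometry sampling rate (Hz), default 1000.
#' @param frame_rate_hz tracking rate (Hz), default 15.
#' @param coupling_gain fractional dF per m/s^2 of acceleration.
#' @param gcamp_rise_s,gcamp_decay_s indicator kernel time constants (s).
#' @param bleach_tau_s photobleaching time constant (s).
#' @param artifact_amp SD of the shared fractional motion artifact
#'   (motion perturbs light collection multiplicatively, so both channels
#'   carry the same fractional artifact).
#' @param noise_sd per-channel Gaussian noise SD (a.u.).
#' @param f465_base,f405_base unbleached baseline fluorescence (a.u.).
#' @param bout_rate_hz mobility bout initiation rate during immobility.
#' @param bout_dur_s mean bout duration (s).
#' @param peak_speed_mps typical peak bout speed (m/s).
#' @param arena_m arena size (m).
#' @return list of class \code{"photometry_sim_config"}.
#' @export
photometry_sim_config <- function(duration_s = 600, rate_hz = 1000,
                                  frame_rate_hz = 15, coupling_gain = 0.05,
                                  gcamp_rise_s = 0.2, gcamp_decay_s = 0.7,
                                  bleach_tau_s = 2000, artifact_amp = 0.02,
                                  noise_sd = 0.3, f465_base = 100,
                                  f405_base = 60, bout_rate_hz = 0.1,
                                  bout_dur_s = 3, peak_speed_mps = 0.2,
                                  arena_m = c(0.35, 0.24)) {
  if (gcamp_rise_s >= gcamp_decay_s) stop("rise must be < decay")
  if (duration_s <= 0 || rate_hz <= 0) stop("duration and rate must be > 0")
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 frame_rate_hz = frame_rate_hz,
                 coupling_gain = coupling_gain,
                 gcamp_rise_s = gcamp_rise_s, gcamp_decay_s = gcamp_decay_s,
                 bleach_tau_s = bleach_tau_s, artifact_amp = artifact_amp,
                 noise_sd = noise_sd, f465_base = f465_base,
                 f405_base = f405_base, bout_rate_hz = bout_rate_hz,
                 bout_dur_s = bout_dur_s, peak_speed_mps = peak_speed_mps,
                 arena_m = arena_m),
            class = "photometry_sim_config")
}

#' Simulate a fiber-photometry session with ground truth
#'
#' Mobility bouts are scheduled as a renewal process (exponential immobility
#' gaps at \code{bout_rate_hz}, bout durations around \code{bout_dur_s});
#' each bout carries a raised-cosine speed bump. Neural activity is
#' \code{coupling_gain * acceleration} convolved with the unit-area
#' biexponential GCaMP kernel and clipped at zero; the 465 channel is
#' \code{f465_base * bleach * (1 + activity) * (1 + artifact)} plus channel
#' noise, the 405 channel \code{f405_base * bleach * (1 + artifact)} plus
#' its own noise — the two channels share the bleach trend and the
#' fractional motion artifact exactly.
#'
#' @param cfg a \code{\link{photometry_sim_config}}.
#' @param seed integer seed; output is a pure function of (cfg, seed).
#' @return list with \code{f465}, \code{f405}
#'   (\code{\link{uniform_signal}}s, a.u.), \code{track} (a
#'   \code{\link{track}} consistent with the speed profile),
#'   \code{activity} (programmed fractional dF at \code{rate_hz}),
#'   \code{bouts} (programmed mobility \code{\link{interval_set}}).
#' @export
simulate_photometry <- function(cfg = photometry_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "photometry_sim_config"))
  set.seed(seed)
  n <- round(cfg$duration_s * cfg$rate_hz)
  t <- (0:(n - 1)) / cfg$rate_hz
  # bout schedule
  starts <- ends <- numeric(0)
  cur <- stats::rexp(1, cfg$bout_rate_hz)
  while (cur < cfg$duration_s - cfg$bout_dur_s) {
    len <- max(1.2, stats::rgamma(1, shape = 4,
                                  rate = 4 / cfg$bout_dur_s))
    if (cur + len > cfg$duration_s) break
    starts <- c(starts, cur); ends <- c(ends, cur + len)
    cur <- cur + len + stats::rexp(1, cfg$bout_rate_hz)
  }
  bouts <- interval_set(starts, ends)
  speed <- numeric(n)
  ramp_s <- 0.3                      # trapezoidal speed profile per bout
  for (k in seq_along(starts)) {
    idx <- which(t >= starts[k] & t < ends[k])
    pk <- cfg$peak_speed_mps * stats::runif(1, 0.7, 1.3)
    up <- pmin(1, (t[idx] - starts[k]) / ramp_s)
    down <- pmin(1, (ends[k] - t[idx]) / ramp_s)
    speed[idx] <- pk * pmin(up, down)
  }
  accel <- c(0, diff(speed)) * cfg$rate_hz
  kern <- ipsc_kernel(cfg$rate_hz, cfg$gcamp_rise_s * 1000,
                      cfg$gcamp_decay_s * 1000)
  kern <- kern / sum(kern)           # unit-area indicator kernel
  activity <- pmax(0, fft_convolve(cfg$coupling_gain * accel, kern))
  bleach <- exp(-t / cfg$bleach_tau_s)
  artifact <- if (cfg$artifact_amp > 0) {
    raw <- gauss_smooth(stats::rnorm(n), cfg$rate_hz, 0.2)
    cfg$artifact_amp * raw / stats::sd(raw)
  } else numeric(n)
  noise465 <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else 0
  noise405 <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else 0
  f465 <- cfg$f465_base * bleach * (1 + activity) * (1 + artifact) + noise465
  f405 <- cfg$f405_base * bleach * (1 + artifact) + noise405
  # track consistent with the speed profile
  nf <- round(cfg$duration_s * cfg$frame_rate_hz)
  tf <- (0:(nf - 1)) / cfg$frame_rate_hz
  vf <- stats::approx(t, speed, xout = tf, rule = 2)$y
  x <- y <- numeric(nf)
  x[1] <- cfg$arena_m[1] / 2; y[1] <- cfg$arena_m[2] / 2
  heading <- stats::runif(1, 0, 2 * pi)
  for (i in 2:nf) {
    heading <- heading + stats::rnorm(1, sd = 0.3)
    xi <- x[i - 1] + vf[i] * cos(heading) / cfg$frame_rate_hz
    yi <- y[i - 1] + vf[i] * sin(heading) / cfg$frame_rate_hz
    if (xi < 0 || xi > cfg$arena_m[1]) { heading <- pi - heading
                                         xi <- min(max(xi, 0), cfg$arena_m[1]) }
    if (yi < 0 || yi > cfg$arena_m[2]) { heading <- -heading
                                         yi <- min(max(yi, 0), cfg$arena_m[2]) }
    x[i] <- xi; y[i] <- yi
  }
  list(f465 = uniform_signal(f465, cfg$rate_hz, 0, "a.u."),
       f405 = uniform_signal(f405, cfg$rate_hz, 0, "a.u."),
       track = track(tf, x, y, cfg$frame_rate_hz),
       activity = uniform_signal(activity, cfg$rate_hz, 0, "dimensionless"),
       bouts = bouts)
}

# linear convolution (same length as x) via FFT
fft_convolve <- function(x, kern) {
  n <- length(x)
  npad <- stats::nextn(n + length(kern), c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, npad - n)))
  K <- stats::fft(c(kern, rep(0, npad - length(kern))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / npad
}

#' Isosbestic-corrected dF/F
#'
#' Fits the 405 nm isosbestic channel onto the 465 nm channel by
#' least-squares affine regression over the whole session and reports the
#' residual as a fraction of the fit:
#' \code{dF/F = 100 * (F465 - fit(F405)) / fit(F405)}. Bleaching and motion
#' artifacts common to both channels cancel; the session mean of dF/F is
#' near zero by construction of the fit.
#'
#' @param f465,f405 \code{\link{uniform_signal}}s with equal rate and length.
#' @param output_percent return percent (default) or fraction.
#' @return a \code{\link{uniform_signal}} of dF/F.
#' @export
isosbestic_dff <- function(f465, f405, output_percent = TRUE) {
  stopifnot(inherits(f465, "uniform_signal"),
            inherits(f405, "uniform_signal"))
  if (f465$rate_hz != f405$rate_hz ||
      length(f465$values) != length(f405$values)) {
    stop("channels must share rate and length")
  }
  if (stats::sd(f405$values) <= 0) {
    stop("isosbestic channel has zero variance; affine fit is degenerate")
  }
  fit <- stats::lm.fit(cbind(1, f405$values), f465$values)
  pred <- cbind(1, f405$values) %*% fit$coefficients
  dff <- (f465$values - pred) / pred
  if (output_percent) dff <- 100 * dff
  uniform_signal(as.numeric(dff), f465$rate_hz, f465$t0_s, "dimensionless")
}

#' Parameters for mobility segmentation
#'
#' @param speed_threshold_mps speed above which a frame is mobile.
#' @param min_bout_s runs shorter than this are dropped.
#' @param merge_gap_s immobile gaps shorter than this inside mobility are
#'   bridged.
#' @return list of class \code{"mobility_params"}.
#' @export
mobility_params <- function(speed_threshold_mps = 0.02, min_bout_s = 1,
                            merge_gap_s = 0.5) {
  if (speed_threshold_mps <= 0) stop("speed threshold must be > 0")
  structure(list(speed_threshold_mps = speed_threshold_mps,
                 min_bout_s = min_bout_s, merge_gap_s = merge_gap_s),
            class = "mobility_params")
}

#' Segment a track into mobility and immobility
#'
#' Frames with speed above threshold are mobile; runs shorter than
#' \code{min_bout_s} are dropped, then gaps shorter than \code{merge_gap_s}
#' are merged. Mobility and immobility partition the track span.
#'
#' @param trk a \code{\link{track}} (kinematics are computed if absent).
#' @param params a \code{\link{mobility_params}}.
#' @return list with \code{mobility} and \code{immobility}
#'   \code{\link{interval_set}}s.
#' @export
segment_mobility <- function(trk, params = mobility_params()) {
  stopifnot(inherits(trk, "track"))
  if (nrow(trk) == 0) stop("empty track")
  if (is.null(trk$speed_mps)) trk <- kinematics(trk)
  rate <- attr(trk, "frame_rate_hz")
  span_end <- trk$t_s[1] + nrow(trk) / rate
  if (span_end - trk$t_s[1] < params$min_bout_s) {
    stop("track shorter than min_bout_s")
  }
  mob <- runs_to_intervals(trk$speed_mps > params$speed_threshold_mps,
                           rate, trk$t_s[1])
  mob <- iv_drop_short(mob, params$min_bout_s)
  mob <- iv_merge_gaps(mob, params$merge_gap_s)
  list(mobility = mob,
       immobility = iv_complement(mob, trk$t_s[1], span_end))
}

#' Transition-triggered average of a signal
#'
#' The signal is z-scored over the session, snippets are cut around each
#' transition time and averaged pointwise. Transitions whose window does not
#' fit inside the span are dropped and counted.
#'
#' @param signal a \code{\link{uniform_signal}}.
#' @param transitions numeric vector of transition times (s).
#' @param window_s length-2 vector \code{c(pre, post)} in seconds (both
#'   positive; the snippet runs from \code{-pre} to \code{+post}).
#' @return list with \code{t_s} (snippet timebase), \code{mean},
#'   \code{sem}, \code{n}, \code{n_dropped}, \code{zero_variance} flag.
#' @export
transition_triggered_average <- function(signal, transitions,
                                         window_s = c(2, 2)) {
  stopifnot(inherits(signal, "uniform_signal"))
  rate <- signal$rate_hz
  sdv <- stats::sd(signal$values)
  zero_var <- !is.finite(sdv) || sdv == 0
  z <- if (zero_var) numeric(length(signal$values))
       else zscore(signal$values)
  pre_n <- round(window_s[1] * rate); post_n <- round(window_s[2] * rate)
  n <- length(z)
  idx0 <- round((transitions - signal$t0_s) * rate) + 1
  ok <- idx0 - pre_n >= 1 & idx0 + post_n <= n
  if (!any(ok)) stop("no transition has a full window inside the span")
  snip <- vapply(idx0[ok], function(i) z[(i - pre_n):(i + post_n)],
                 numeric(pre_n + post_n + 1))
  m <- rowMeans(snip)
  nn <- sum(ok)
  sem <- if (nn > 1) apply(snip, 1, stats::sd) / sqrt(nn) else rep(NA_real_,
                                                                   nrow(snip))
  list(t_s = (-pre_n:post_n) / rate, mean = m, sem = sem, n = nn,
       n_dropped = sum(!ok), zero_variance = zero_var)
}

#' Align dF/F to the tracking timebase
#'
#' Downsamples by windowed mean: each frame receives the mean of the dF/F
#' samples in the half-open frame slot \code{[t, t + 1/frame_rate)}.
#'
#' @param dff a \code{\link{uniform_signal}}.
#' @param trk a \code{\link{track}}.
#' @return numeric vector, one value per frame (NA for frames with no
#'   overlapping samples).
#' @export
dff_per_frame <- function(dff, trk) {
  rate_f <- attr(trk, "frame_rate_hz")
  ts <- signal_times(dff)
  frame <- floor((ts - trk$t_s[1]) * rate_f) + 1
  keep <- frame >= 1 & frame <= nrow(trk)
  out <- rep(NA_real_, nrow(trk))
  agg <- tapply(dff$values[keep], frame[keep], mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Acceleration-response curve of z-scored dF/F
#'
#' Pairs instantaneous acceleration with frame-aligned z-scored dF/F and
#' bins the pairs into equal-count bins, separately for acceleration and
#' deceleration.
#'
#' @param dff a \code{\link{uniform_signal}} overlapping the track in time.
#' @param trk a \code{\link{track}}.
#' @param n_bins equal-count bins per sign (default 10).
#' @return data frame: \code{accel_mps2} (bin mean), \code{mean_z},
#'   \code{sem}, \code{n}, \code{side}.
#' @export
acceleration_response_curve <- function(dff, trk, n_bins = 10) {
  if (is.null(trk$accel_mps2)) trk <- kinematics(trk)
  y <- dff_per_frame(dff, trk)
  ok <- !is.na(y)
  x <- trk$accel_mps2[ok]; y <- y[ok]
  if (length(x) < 10 * n_bins) {
    stop(sprintf("need at least %d (accel, dF/F) pairs, got %d",
                 10 * n_bins, length(x)))
  }
  y <- zscore(y)
  one_side <- function(sel, side) {
    xs <- x[sel]; ys <- y[sel]
    if (!length(xs)) return(NULL)
    q <- stats::quantile(xs, probs = seq(0, 1, length.out = n_bins + 1))
    b <- cut(xs, breaks = unique(q), include.lowest = TRUE)
    data.frame(accel_mps2 = as.numeric(tapply(xs, b, mean)),
               mean_z = as.numeric(tapply(ys, b, mean)),
               sem = as.numeric(tapply(ys, b, stats::sd) /
                                  sqrt(tapply(ys, b, length))),
               n = as.integer(tapply(ys, b, length)),
               side = side)
  }
  out <- rbind(one_side(x < 0, "deceleration"),
               one_side(x >= 0, "acceleration"))
  rownames(out) <- NULL
  out
}

#' Acceleration modulation index from a quadratic fit
#'
#' Least-squares quadratic of z-scored dF/F against instantaneous
#' acceleration; the index is the fitted difference between the response at
#' a reference acceleration (the 95th percentile of |acceleration|) and at
#' its negative: \code{index = yhat(+a_ref) - yhat(-a_ref) = 2 a1 a_ref}. It
#' summarizes the asymmetry between the acceleration and deceleration limbs
#' of the response curve; the raw coefficients are returned alongside.
#'
#' @param accel instantaneous acceleration values (m/s^2), both signs
#'   represented.
#' @param zdff matching z-scored dF/F values.
#' @return list of class \code{"modulation_result"}: \code{coeffs}
#'   (a2, a1, a0), \code{a_ref}, \code{index}, \code{n_points}.
#' @export
modulation_index <- function(accel, zdff) {
  ok <- is.finite(accel) & is.finite(zdff)
  accel <- accel[ok]; zdff <- zdff[ok]
  if (length(accel) < 10) stop("need at least 10 (accel, dF/F) pairs")
  if (min(accel) >= 0 || max(accel) <= 0) {
    stop("acceleration must span both signs")
  }
  fit <- stats::lm.fit(cbind(accel^2, accel, 1), zdff)
  co <- fit$coefficients           # a2, a1, a0
  a_ref <- stats::quantile(abs(accel), 0.95, names = FALSE)
  structure(list(coeffs = c(a2 = unname(co[1]), a1 = unname(co[2]),
                            a0 = unname(co[3])),
                 a_ref = a_ref, index = 2 * unname(co[2]) * a_ref,
                 n_points = length(accel)),
            class = "modulation_result")
}
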