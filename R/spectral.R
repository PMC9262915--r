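#' Welch power spectral density with a Hamming window
#'
#' Averages Hamming-windowed one-sided periodograms over 50 percent
#' overlapping segments of length \code{1 / resolution_hz} seconds, giving a
#' frequency grid at exactly \code{resolution_hz} spacing. Normalization is
#' Parseval-consistent: the integral of the density over frequency
#' approximates the signal variance (power, in signal-units squared per Hz).
#'
#' @param values numeric samples (or a \code{\link{uniform_signal}}, in which
#'   case \code{rate_hz} is taken from it).
#' @param rate_hz sampling rate (Hz).
#' @param resolution_hz frequency resolution (Hz); default 0.5 fixes the
#'   window length at 2 s.
#' @param demean subtract the segment mean before windowing (default FALSE).
#' @return list of class \code{"spectral_summary"}: \code{freqs_hz},
#'   \code{power}, \code{resolution_hz}, \code{n_windows}, \code{window}
#'   (name and length).
#' @export
power_spectrum <- function(values, rate_hz = NULL, resolution_hz = 0.5,
                           demean = FALSE) {
  if (inherits(values, "uniform_signal")) {
    rate_hz <- values$rate_hz
    values <- values$values
  }
  if (is.null(rate_hz)) stop("rate_hz required for plain numeric input")
  nwin <- round(rate_hz / resolution_hz)
  if (length(values) < nwin) {
    stop(sprintf("need at least one full window (%d samples), got %d",
                 nwin, length(values)))
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hamming
  step <- floor(nwin / 2)
  starts <- seq(1, length(values) - nwin + 1, by = step)
  nf <- floor(nwin / 2) + 1
  acc <- numeric(nf)
  scale <- 1 / (rate_hz * sum(w^2))
  for (s in starts) {
    seg <- values[s:(s + nwin - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[1:nf]
    acc <- acc + (Mod(X)^2) * scale
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nwin even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  structure(list(freqs_hz = (0:(nf - 1)) * resolution_hz, power = p,
                 resolution_hz = resolution_hz, n_windows = length(starts),
                 window = list(name = "hamming", length_s = nwin / rate_hz)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d bins @ %g Hz, %d window(s) [%s %gs]\n",
              length(x$freqs_hz), x$resolution_hz, x$n_windows,
              x$window$name, x$window$length_s))
  invisible(x)
}

#' Remove line noise from a spectrum by log-linear interpolation
#'
#' Bins within \code{halfwidth_hz} of each harmonic of the mains frequency
#' are replaced by linear interpolation of log-power between the nearest
#' untouched flanking bins, respecting the 1/f background. All other bins
#' are returned unchanged.
#'
#' @param spec a \code{\link{power_spectrum}} result.
#' @param line_hz mains frequency (default 50).
#' @param n_harmonics harmonics to clean (default 3: 50, 100, 150 Hz).
#' @param halfwidth_hz half-width of each notch (Hz).
#' @return the corrected \code{spectral_summary}.
#' @export
interpolate_line_noise <- function(spec, line_hz = 50, n_harmonics = 3,
                                   halfwidth_hz = 2) {
  stopifnot(inherits(spec, "spectral_summary"))
  if (halfwidth_hz >= line_hz / 2) stop("halfwidth must be < line_hz / 2")
  f <- spec$freqs_hz
  p <- spec$power
  for (k in seq_len(n_harmonics)) {
    fk <- k * line_hz
    if (fk - halfwidth_hz > max(f)) break
    bad <- which(abs(f - fk) <= halfwidth_hz + 1e-9)
    if (!length(bad)) next
    lo <- min(bad) - 1; hi <- max(bad) + 1
    if (lo < 1 || hi > length(f)) {
      stop("notch band touches the spectrum edge; no flanking bins")
    }
    eps <- .Machine$double.xmin
    lp <- stats::approx(x = f[c(lo, hi)], y = log(p[c(lo, hi)] + eps),
                        xout = f[bad])$y
    p[bad] <- exp(lp)
  }
  spec$power <- p
  spec
}

#' Integrated band power
#'
#' Sum of density times bin width over bins with \code{lo_hz <= f < hi_hz}
#' (half-open, so adjacent bands add exactly).
#'
#' @param spec a \code{\link{power_spectrum}} result.
#' @param lo_hz,hi_hz band edges (Hz), within the spectrum range.
#' @return band power in signal-units squared.
#' @export
band_power <- function(spec, lo_hz, hi_hz) {
  stopifnot(inherits(spec, "spectral_summary"))
  if (lo_hz >= hi_hz) stop("need lo_hz < hi_hz")
  f <- spec$freqs_hz
  if (lo_hz < min(f) - 1e-9 || hi_hz > max(f) + spec$resolution_hz + 1e-9) {
    stop("band outside spectrum range")
  }
  sel <- f >= lo_hz - 1e-9 & f < hi_hz - 1e-9
  sum(spec$power[sel]) * spec$resolution_hz
}

#' Theta 8 Hz / 4 Hz power ratio
#'
#' Density at the 8.0 Hz bin divided by density at the 4.0 Hz bin; a
#' peak-sharpness index of the theta rhythm. With \code{band_halfwidth_hz}
#' set, mean density over f +/- halfwidth is used for each of the two bands
#' instead of the single bin.
#'
#' @param spec a \code{\link{power_spectrum}} result with bins at 4 and 8 Hz.
#' @param band_halfwidth_hz optional half-width (Hz) for band mode.
#' @return the ratio; \code{NaN} (flagged undefined) if the 4 Hz density is
#'   zero.
#' @export
theta_ratio_8_4 <- function(spec, band_halfwidth_hz = 0) {
  stopifnot(inherits(spec, "spectral_summary"))
  dens_at <- function(f0) {
    sel <- abs(spec$freqs_hz - f0) <= band_halfwidth_hz + 1e-9
    if (!any(sel)) stop(sprintf("no spectrum bin at %g Hz", f0))
    mean(spec$power[sel])
  }
  p8 <- dens_at(8); p4 <- dens_at(4)
  if (p4 == 0) return(NaN)
  p8 / p4
}

#' Parameters for theta-segment selection
#'
#' @param window_s,step_s sliding-window length and step (s).
#' @param theta_band_hz theta band (Hz), default 4-10.
#' @param reference_band_hz reference band (Hz), default 1-4; disjoint from
#'   theta.
#' @param ratio_threshold theta/reference power ratio above which a window
#'   counts as theta.
#' @param min_segment_s minimum kept segment length (s).
#' @return list of class \code{"theta_segment_params"}.
#' @export
theta_segment_params <- function(window_s = 2, step_s = 1,
                                 theta_band_hz = c(4, 10),
                                 reference_band_hz = c(1, 4),
                                 ratio_threshold = 2, min_segment_s = 3) {
  if (ratio_threshold <= 0) stop("ratio_threshold must be > 0")
  if (max(reference_band_hz) > min(theta_band_hz) + 1e-9 &&
      min(reference_band_hz) < max(theta_band_hz)) {
    if (!(reference_band_hz[2] <= theta_band_hz[1] ||
          theta_band_hz[2] <= reference_band_hz[1])) {
      stop("theta and reference bands must be disjoint")
    }
  }
  structure(list(window_s = window_s, step_s = step_s,
                 theta_band_hz = theta_band_hz,
                 reference_band_hz = reference_band_hz,
                 ratio_threshold = ratio_threshold,
                 min_segment_s = min_segment_s),
            class = "theta_segment_params")
}

#' Identify segments of continuous theta by spectral criteria
#'
#' Slides a window along the signal, computes the theta / reference
#' band-power ratio per window, unions consecutive supra-threshold windows
#' into segments, and keeps segments at least \code{min_segment_s} long.
#'
#' @param signal a \code{\link{uniform_signal}} at least one window long.
#' @param params a \code{\link{theta_segment_params}}.
#' @return an \code{\link{interval_set}} of theta segments.
#' @export
find_theta_segments <- function(signal, params = theta_segment_params()) {
  stopifnot(inherits(signal, "uniform_signal"))
  nwin <- round(params$window_s * signal$rate_hz)
  nstep <- round(params$step_s * signal$rate_hz)
  n <- length(signal$values)
  if (n < nwin) stop("signal span shorter than one window")
  starts <- seq(1, n - nwin + 1, by = nstep)
  res_hz <- 1 / params$window_s
  hit <- logical(length(starts))
  for (k in seq_along(starts)) {
    seg <- signal$values[starts[k]:(starts[k] + nwin - 1)]
    sp <- power_spectrum(seg, signal$rate_hz, resolution_hz = res_hz,
                         demean = TRUE)
    th <- band_power(sp, params$theta_band_hz[1], params$theta_band_hz[2])
    rf <- band_power(sp, params$reference_band_hz[1],
                     params$reference_band_hz[2])
    hit[k] <- rf > 0 && th / rf > params$ratio_threshold
  }
  if (!any(hit)) return(interval_set())
  t_start <- signal$t0_s + (starts - 1) / signal$rate_hz
  t_end <- pmin(t_start + params$window_s,
                signal$t0_s + n / signal$rate_hz)
  merged <- union_overlapping(t_start[hit], t_end[hit])
  iv_drop_short(interval_set(merged$start_s, merged$end_s),
                params$min_segment_s)
}

# union possibly-overlapping intervals (given as sorted parallel vectors)
# into a disjoint list
union_overlapping <- function(start_s, end_s) {
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  starts <- start_s[1]; ends <- end_s[1]
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] <= ends[length(ends)]) {
      ends[length(ends)] <- max(ends[length(ends)], end_s[i])
    } else {
      starts <- c(starts, start_s[i]); ends <- c(ends, end_s[i])
    }
  }
  list(start_s = starts, end_s = ends)
}
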