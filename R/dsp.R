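# Frequency-domain signal utilities shared by the ripple, spectral and
# synthetic modules. All are zero-phase by construction.

# Frequencies (Hz) of the DFT bins of an n-point transform at rate fs,
# in fft() order (0, df, ..., fs/2, ..., -df).
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Zero-phase bandpass via multiplication in the frequency domain with a
# cosine-tapered (Tukey-edge) transfer function: unit gain in [lo, hi],
# zero outside [lo*(1-trans), hi*(1+trans)], raised-cosine transitions.
# Infinite stopband attenuation at and beyond the outer edges. The line
# through the endpoints is removed and a short cosine edge taper applied
# before zero-padding: an edge discontinuity (large when the signal has
# strong low-frequency content) would otherwise leak 1/t sinc ringing deep
# into the record.
fft_bandpass <- function(values, rate_hz, lo_hz, hi_hz, trans = 0.2) {
  n <- length(values)
  if (hi_hz >= rate_hz / 2) stop("band upper edge must be below Nyquist")
  line <- values[1] + (values[n] - values[1]) * (0:(n - 1)) / max(n - 1, 1)
  detr <- values - line
  ntap <- min(ceiling(0.25 * rate_hz), floor(n / 4))
  if (ntap > 1) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(ntap) - 1) / ntap))
    detr[seq_len(ntap)] <- detr[seq_len(ntap)] * ramp
    detr[n + 1 - seq_len(ntap)] <- detr[n + 1 - seq_len(ntap)] * ramp
  }
  npad <- stats::nextn(n + 2 * ceiling(rate_hz / lo_hz), c(2, 3, 5))
  x <- c(detr, rep(0, npad - n))
  f <- abs(fft_freqs(npad, rate_hz))
  lo0 <- lo_hz * (1 - trans); hi1 <- hi_hz * (1 + trans)
  H <- numeric(npad)
  H[f >= lo_hz & f <= hi_hz] <- 1
  ramp_lo <- f > lo0 & f < lo_hz
  H[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - lo0) / (lo_hz - lo0)))
  ramp_hi <- f > hi_hz & f < hi1
  H[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi_hz) / (hi1 - hi_hz)))
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / npad
  y[seq_len(n)]
}

# Zero-phase Gaussian smoothing (SD sd_s seconds) by multiplication with the
# Gaussian transfer function exp(-(2*pi*f*sd)^2 / 2); exact up to padding.
gauss_smooth <- function(values, rate_hz, sd_s) {
  if (sd_s <= 0) return(values)
  n <- length(values)
  npad <- stats::nextn(n + ceiling(8 * sd_s * rate_hz), c(2, 3, 5))
  # pad by edge replication to avoid wrap-around transients
  x <- c(values, rep(values[n], npad - n))
  f <- fft_freqs(npad, rate_hz)
  H <- exp(-0.5 * (2 * pi * f * sd_s)^2)
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / npad
  y[seq_len(n)]
}

# Gaussian noise spectrally shaped to power ~ 1/f^exponent, zero mean and
# expected unit variance. The normalization is deterministic (the analytic
# sd of the shaped process, not the sample sd): a 1/f^2 process carries most
# of its variance in a handful of low-frequency components whose realized
# power varies wildly between seeds, and dividing by the sample sd would
# propagate that variability into the (stable) in-band scale.
colored_noise <- function(n, rate_hz, exponent = 1) {
  npad <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(npad)
  f <- abs(fft_freqs(npad, rate_hz))
  shape <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / npad
  y <- y[seq_len(n)]
  (y - mean(y)) / sqrt(mean(shape^2))
}
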