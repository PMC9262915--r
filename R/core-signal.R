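#' Uniformly sampled signal
#'
#' Container for one uniformly sampled real-valued channel (an LFP trace in
#' mV, a voltage-clamp current in pA, a fluorescence channel in a.u., or a
#' derived dimensionless quantity such as an envelope or a z-score).
#' The time of sample \code{i} (0-based) is \code{t0_s + i / rate_hz}.
#'
#' @param values numeric vector of samples; all values must be finite.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, in seconds.
#' @param units unit label: one of \code{"mV"}, \code{"pA"}, \code{"a.u."},
#'   \code{"dimensionless"}.
#' @return An object of class \code{"uniform_signal"}: a list with elements
#'   \code{values}, \code{rate_hz}, \code{t0_s}, \code{units}.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 8 * (0:999) / 1000), 1000, units = "mV")
#' signal_duration(s)
#' @export
uniform_signal <- function(values, rate_hz, t0_s = 0, units = "dimensionless") {
  values <- as.numeric(values)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (length(values) && !all(is.finite(values))) {
    stop("all signal values must be finite")
  }
  units <- match.arg(units, c("dimensionless", "mV", "pA", "a.u."))
  structure(
    list(values = values, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s), units = units),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz, t0 = %g s, units = %s\n",
              length(x$values), x$rate_hz, x$t0_s, x$units))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample timestamps of a uniform signal
#'
#' @param signal a \code{\link{uniform_signal}}.
#' @return numeric vector of times (s), one per sample.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  signal$t0_s + (seq_along(signal$values) - 1) / signal$rate_hz
}

#' Duration of a uniform signal
#'
#' The covered span is the half-open interval
#' \code{[t0_s, t0_s + n / rate_hz)}: each sample owns the 1/rate slot that
#' starts at its own timestamp.
#'
#' @param signal a \code{\link{uniform_signal}}.
#' @return span length in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  length(signal$values) / signal$rate_hz
}

#' Restrict a signal to a set of time intervals
#'
#' Returns the concatenated samples whose timestamps fall inside \code{ivs},
#' in time order. Membership uses the half-open rule
#' \code{start <= t < end} evaluated on exact sample timestamps, so adjacent
#' intervals never double-count a sample.
#'
#' @param signal a \code{\link{uniform_signal}}.
#' @param ivs an \code{\link{interval_set}}; every interval must lie within
#'   the signal span.
#' @return numeric vector of samples (possibly empty).
#' @export
restrict <- function(signal, ivs) {
  stopifnot(inherits(signal, "uniform_signal"))
  ivs <- as_interval_set(ivs)
  if (nrow(ivs) == 0) return(numeric(0))
  n <- length(signal$values)
  span_end <- signal$t0_s + n / signal$rate_hz
  eps <- 1e-9 / signal$rate_hz
  out <- vector("list", nrow(ivs))
  for (k in seq_len(nrow(ivs))) {
    a <- ivs$start_s[k]; b <- ivs$end_s[k]
    if (a < signal$t0_s - eps || b > span_end + eps) {
      stop(sprintf("interval [%g, %g) lies outside the signal span [%g, %g)",
                   a, b, signal$t0_s, span_end))
    }
    # first index with t >= a, last with t < b (0-based indices)
    i0 <- ceiling((a - signal$t0_s) * signal$rate_hz - 1e-9)
    i1 <- ceiling((b - signal$t0_s) * signal$rate_hz - 1e-9) - 1
    i0 <- max(i0, 0); i1 <- min(i1, n - 1)
    out[[k]] <- if (i1 >= i0) signal$values[(i0 + 1):(i1 + 1)] else numeric(0)
  }
  unlist(out, use.names = FALSE)
}

#' Standardize values against a given mean and SD
#'
#' @param values numeric vector.
#' @param mu reference mean.
#' @param sd reference standard deviation (> 0).
#' @return \code{(values - mu) / sd}.
#' @export
zscore <- function(values, mu = mean(values), sd = stats::sd(values)) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  (values - mu) / sd
}

#' Resample a signal onto a new uniform grid by linear interpolation
#'
#' The new grid spans the same time range (first to last sample) and keeps
#' both endpoints.
#'
#' @param signal a \code{\link{uniform_signal}} with at least 2 samples.
#' @param new_rate_hz target rate in Hz (> 0).
#' @return a \code{\link{uniform_signal}} at \code{new_rate_hz}.
#' @export
resample_linear <- function(signal, new_rate_hz) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (length(signal$values) < 2) stop("signal must have at least 2 samples")
  if (!is.finite(new_rate_hz) || new_rate_hz <= 0) {
    stop("new_rate_hz must be > 0")
  }
  t_old <- signal_times(signal)
  t_end <- t_old[length(t_old)]
  n_new <- floor((t_end - signal$t0_s) * new_rate_hz) + 1
  t_new <- signal$t0_s + (seq_len(n_new) - 1) / new_rate_hz
  t_new[t_new > t_end] <- t_end
  vals <- stats::approx(t_old, signal$values, xout = t_new)$y
  uniform_signal(vals, new_rate_hz, t0_s = signal$t0_s, units = signal$units)
}

#' Write / read a uniform signal as plain CSV
#'
#' One \code{value} column; rate, origin and units are stored in a
#' \code{#}-prefixed header line so the file round-trips losslessly.
#'
#' @param signal a \code{\link{uniform_signal}}.
#' @param path file path.
#' @return \code{write_signal_csv} returns \code{path} invisibly;
#'   \code{read_signal_csv} returns a \code{\link{uniform_signal}}.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "uniform_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.17g t0_s=%.17g units=%s",
                     signal$rate_hz, signal$t0_s, signal$units), con)
  writeLines("value", con)
  writeLines(sprintf("%.17g", signal$values), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "rate_hz=([-0-9.eE+]+) t0_s=([-0-9.eE+]+) units=(\\S+)", hdr))[[1]]
  if (length(m) != 4) stop("missing signal header line in ", path)
  vals <- utils::read.csv(path, comment.char = "#")$value
  uniform_signal(vals, as.numeric(m[2]), as.numeric(m[3]), m[4])
}
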