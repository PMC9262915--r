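#' Ordered disjoint half-open time intervals
#'
#' An interval set represents a behavioral or analytic state as a list of
#' half-open intervals \code{[start_s, end_s)}, sorted ascending and pairwise
#' disjoint (mobility bouts, immobility, theta segments, ...). The half-open
#' convention means adjacent intervals tile time without double-counting
#' samples.
#'
#' @param start_s,end_s numeric vectors of interval starts and ends (s);
#'   \code{start_s < end_s} elementwise.
#' @return A data frame of class \code{"interval_set"} with columns
#'   \code{start_s}, \code{end_s}.
#' @examples
#' ivs <- interval_set(c(0, 5), c(2, 8))
#' iv_duration(ivs)
#' @export
interval_set <- function(start_s = numeric(0), end_s = numeric(0)) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s)) stop("start_s and end_s lengths differ")
  if (length(start_s)) {
    if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
      stop("interval endpoints must be finite")
    }
    if (any(end_s <= start_s)) stop("every interval needs start < end")
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(start_s[-1] < end_s[-length(end_s)])) {
      stop("intervals must be pairwise disjoint")
    }
  }
  structure(data.frame(start_s = start_s, end_s = end_s),
            class = c("interval_set", "data.frame"))
}

#' @rdname interval_set
#' @param x object to coerce (interval_set, 2-column data frame or matrix).
#' @export
as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.data.frame(x)) {
    cols <- if (all(c("start_s", "end_s") %in% names(x))) {
      x[c("start_s", "end_s")]
    } else x[, 1:2]
    return(interval_set(cols[[1]], cols[[2]]))
  }
  stop("cannot coerce to interval_set")
}

#' Total duration of an interval set
#'
#' @param ivs an \code{\link{interval_set}}.
#' @return sum of interval lengths in seconds.
#' @export
iv_duration <- function(ivs) {
  ivs <- as_interval_set(ivs)
  sum(ivs$end_s - ivs$start_s)
}

#' Complement of an interval set within a span
#'
#' @param ivs an \code{\link{interval_set}} contained in
#'   \code{[span_start_s, span_end_s)}.
#' @param span_start_s,span_end_s span bounds (s).
#' @return the interval_set covering the span minus \code{ivs}.
#' @export
iv_complement <- function(ivs, span_start_s, span_end_s) {
  ivs <- as_interval_set(ivs)
  if (span_end_s <= span_start_s) stop("span must have positive length")
  if (nrow(ivs) &&
      (min(ivs$start_s) < span_start_s || max(ivs$end_s) > span_end_s)) {
    stop("ivs extend outside the span")
  }
  edges_lo <- c(span_start_s, ivs$end_s)
  edges_hi <- c(ivs$start_s, span_end_s)
  keep <- edges_hi > edges_lo
  interval_set(edges_lo[keep], edges_hi[keep])
}

#' Intersection of two interval sets
#'
#' @param a,b interval sets.
#' @return the interval_set of all overlaps.
#' @export
iv_intersect <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(interval_set())
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start_s[i], b$start_s)
    hi <- pmin(a$end_s[i], b$end_s)
    keep <- hi > lo
    starts <- c(starts, lo[keep]); ends <- c(ends, hi[keep])
  }
  interval_set(starts, ends)
}

#' Merge intervals separated by short gaps
#'
#' @param ivs an \code{\link{interval_set}}.
#' @param max_gap_s gaps strictly shorter than this are bridged.
#' @return merged interval_set.
#' @export
iv_merge_gaps <- function(ivs, max_gap_s) {
  ivs <- as_interval_set(ivs)
  if (nrow(ivs) < 2) return(ivs)
  starts <- ivs$start_s[1]; ends <- ivs$end_s[1]
  for (i in 2:nrow(ivs)) {
    if (ivs$start_s[i] - ends[length(ends)] < max_gap_s) {
      ends[length(ends)] <- ivs$end_s[i]
    } else {
      starts <- c(starts, ivs$start_s[i]); ends <- c(ends, ivs$end_s[i])
    }
  }
  interval_set(starts, ends)
}

#' Drop intervals shorter than a minimum duration
#'
#' @param ivs an \code{\link{interval_set}}.
#' @param min_dur_s minimum kept duration (s).
#' @return filtered interval_set.
#' @export
iv_drop_short <- function(ivs, min_dur_s) {
  ivs <- as_interval_set(ivs)
  keep <- (ivs$end_s - ivs$start_s) >= min_dur_s
  interval_set(ivs$start_s[keep], ivs$end_s[keep])
}

#' Membership of time points in an interval set
#'
#' @param t_s numeric vector of times.
#' @param ivs an \code{\link{interval_set}}.
#' @return logical vector: \code{start <= t < end} for some interval.
#' @export
in_intervals <- function(t_s, ivs) {
  ivs <- as_interval_set(ivs)
  out <- rep(FALSE, length(t_s))
  for (i in seq_len(nrow(ivs))) {
    out <- out | (t_s >= ivs$start_s[i] & t_s < ivs$end_s[i])
  }
  out
}

#' Convert a per-sample logical state to an interval set
#'
#' Sample \code{i} (0-based, time \code{t0_s + i/rate_hz}) owns the half-open
#' slot of width \code{1/rate_hz} starting at its timestamp, so a maximal run
#' of TRUE samples from index i to j maps to the interval
#' \code{[t(i), t(j) + 1/rate)}.
#'
#' @param flag logical vector, one element per sample.
#' @param rate_hz sampling rate (Hz).
#' @param t0_s time of the first sample (s).
#' @return an \code{\link{interval_set}}.
#' @export
runs_to_intervals <- function(flag, rate_hz, t0_s = 0) {
  if (!length(flag) || !any(flag)) return(interval_set())
  r <- rle(as.logical(flag))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  on <- which(r$values)
  interval_set(t0_s + (starts_idx[on] - 1) / rate_hz,
               t0_s + ends_idx[on] / rate_hz)
}

#' Write / read an interval set as CSV
#'
#' @param ivs an \code{\link{interval_set}}.
#' @param path file path.
#' @export
write_intervals_csv <- function(ivs, path) {
  utils::write.csv(as.data.frame(as_interval_set(ivs)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  as_interval_set(utils::read.csv(path))
}
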