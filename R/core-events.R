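#' Table of detected or ground-truth events
#'
#' One row per event with onset, peak and offset times and an amplitude in
#' the units of the source signal (or in baseline-SD units for ripple
#' power). Additional per-event measures may be supplied as extra columns.
#'
#' @param onset_s,peak_s,offset_s event times (s); \code{onset <= peak <=
#'   offset} rowwise.
#' @param amplitude per-event amplitude; must be finite.
#' @param ... further equal-length per-event columns (kept by name).
#' @return data frame of class \code{"event_table"}, sorted by onset.
#' @export
event_table <- function(onset_s = numeric(0), peak_s = onset_s,
                        offset_s = peak_s, amplitude = rep(NA_real_,
                        length(onset_s)), ...) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   peak_s = as.numeric(peak_s),
                   offset_s = as.numeric(offset_s),
                   amplitude = as.numeric(amplitude))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  if (nrow(df)) {
    tol <- 1e-9
    if (any(df$peak_s < df$onset_s - tol) ||
        any(df$offset_s < df$peak_s - tol)) {
      stop("events must satisfy onset <= peak <= offset")
    }
    if (!all(is.finite(df$amplitude) | is.na(df$amplitude))) {
      stop("amplitudes must be finite (or NA)")
    }
    df <- df[order(df$onset_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Match detected events to ground truth and score recall/precision
#'
#' Greedy one-to-one matching on a reference time column: each truth event is
#' matched to the nearest unmatched detected event within \code{tol_s}.
#'
#' @param detected,truth \code{\link{event_table}}s.
#' @param tol_s matching tolerance (s).
#' @param on time column used for matching (default \code{"peak_s"}).
#' @return list with \code{recall}, \code{precision}, \code{n_matched},
#'   \code{n_detected}, \code{n_truth}, and the index pairs \code{matches}
#'   (columns \code{truth}, \code{detected}).
#' @export
match_events <- function(detected, truth, tol_s, on = "peak_s") {
  td <- detected[[on]]; tt <- truth[[on]]
  used <- rep(FALSE, length(td))
  mt <- md <- integer(0)
  for (i in order(tt)) {
    d <- abs(td - tt[i])
    d[used] <- Inf
    j <- if (length(d)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      mt <- c(mt, i); md <- c(md, j)
    }
  }
  n_matched <- length(mt)
  list(recall = if (length(tt)) n_matched / length(tt) else NA_real_,
       precision = if (length(td)) n_matched / length(td) else NA_real_,
       n_matched = n_matched, n_detected = length(td), n_truth = length(tt),
       matches = data.frame(truth = mt, detected = md))
}

#' Write / read an event table as CSV
#'
#' @param events an \code{\link{event_table}}.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  do.call(event_table, df)
}
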