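#' Time-stamped 2-D position track
#'
#' @param t_s,x_m,y_m per-frame time (s) and head position (m); times must
#'   be strictly increasing on a uniform grid.
#' @param frame_rate_hz tracking rate (Hz), default 15.
#' @return data frame of class \code{"track"} with columns \code{t_s},
#'   \code{x_m}, \code{y_m} (and, after \code{\link{kinematics}},
#'   \code{speed_mps} and \code{accel_mps2}).
#' @export
track <- function(t_s, x_m, y_m, frame_rate_hz = 15) {
  if (length(t_s) != length(x_m) || length(t_s) != length(y_m)) {
    stop("t_s, x_m, y_m must have equal length")
  }
  if (length(t_s) > 1) {
    dt <- diff(t_s)
    if (any(dt <= 0) || max(abs(dt - 1 / frame_rate_hz)) > 1e-6) {
      stop("t_s must increase uniformly at 1/frame_rate_hz spacing")
    }
  }
  structure(data.frame(t_s = t_s, x_m = x_m, y_m = y_m),
            frame_rate_hz = frame_rate_hz,
            class = c("track", "data.frame"))
}

#' Instantaneous speed and acceleration from a position track
#'
#' Speed is the frame-to-frame displacement times the frame rate, passed
#' through a 3-frame running median to suppress single-frame tracking
#' jitter; acceleration is the centered difference of speed (one-sided at
#' the endpoints).
#'
#' @param trk a \code{\link{track}} with at least 3 frames.
#' @return the track with \code{speed_mps} and \code{accel_mps2} columns.
#' @export
kinematics <- function(trk) {
  stopifnot(inherits(trk, "track"))
  n <- nrow(trk)
  if (n < 3) stop("need at least 3 frames")
  rate <- attr(trk, "frame_rate_hz")
  step <- sqrt(diff(trk$x_m)^2 + diff(trk$y_m)^2)
  v <- c(step[1], step) * rate          # frame i uses displacement into i
  v <- stats::runmed(v, 3)
  a <- numeric(n)
  a[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate / 2
  a[1] <- (v[2] - v[1]) * rate
  a[n] <- (v[n] - v[n - 1]) * rate
  trk$speed_mps <- v
  trk$accel_mps2 <- a
  trk
}

#' Configuration for novel-object-location scoring
#'
#' @param object_xy_m 2-column matrix (or 2-vector list) of object centers
#'   (m); row 1 is the displaced object by convention.
#' @param object_radius_m object footprint radius (m).
#' @param zone_width_m width of the perimetral exploration zone around the
#'   footprint (m); default 0.02 (the 2 cm head-entry zone).
#' @param arena_m arena width and height (m); default the 0.35 x 0.24 m
#'   open field.
#' @return list of class \code{"nol_config"}.
#' @export
nol_config <- function(object_xy_m = rbind(c(0.05, 0.05), c(0.30, 0.19)),
                       object_radius_m = 0.02, zone_width_m = 0.02,
                       arena_m = c(0.35, 0.24)) {
  object_xy_m <- rbind(object_xy_m)
  outer <- object_radius_m + zone_width_m
  if (any(object_xy_m[, 1] < outer - 1e-12) ||
      any(object_xy_m[, 2] < outer - 1e-12) ||
      any(object_xy_m[, 1] > arena_m[1] - outer + 1e-12) ||
      any(object_xy_m[, 2] > arena_m[2] - outer + 1e-12)) {
    stop("object zones must lie inside the arena")
  }
  if (nrow(object_xy_m) > 1) {
    d <- stats::dist(object_xy_m)
    if (min(d) < 2 * outer) stop("object zones overlap")
  }
  structure(list(object_xy_m = object_xy_m,
                 object_radius_m = object_radius_m,
                 zone_width_m = zone_width_m, arena_m = arena_m),
            class = "nol_config")
}

# annulus membership of positions around one object center
in_zone <- function(x, y, cx, cy, r_in, r_out) {
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  d >= r_in & d < r_out
}

#' Per-object exploration time and entry count
#'
#' A frame counts toward an object when the head lies in the half-open
#' annulus \code{[radius, radius + zone_width)} around its center; an entry
#' is the first frame of each maximal in-zone run.
#'
#' @param trk a \code{\link{track}}.
#' @param cfg a \code{\link{nol_config}}.
#' @return data frame with one row per object: \code{object}, \code{time_s},
#'   \code{entries}.
#' @export
exploration_times <- function(trk, cfg) {
  stopifnot(inherits(trk, "track"), inherits(cfg, "nol_config"))
  rate <- attr(trk, "frame_rate_hz")
  r_in <- cfg$object_radius_m
  r_out <- r_in + cfg$zone_width_m
  out <- data.frame(object = seq_len(nrow(cfg$object_xy_m)),
                    time_s = NA_real_, entries = NA_integer_)
  for (o in seq_len(nrow(cfg$object_xy_m))) {
    inz <- in_zone(trk$x_m, trk$y_m, cfg$object_xy_m[o, 1],
                   cfg$object_xy_m[o, 2], r_in, r_out)
    out$time_s[o] <- sum(inz) / rate
    r <- rle(inz)
    out$entries[o] <- sum(r$values)
  }
  out
}

#' Novel-object-location discrimination index
#'
#' The difference in exploration between the displaced and the familiar
#' object divided by total exploration; positive values indicate location
#' memory.
#'
#' @param t_displaced_s,t_familiar_s exploration times (s).
#' @return value in [-1, 1]; \code{NaN} (flagged undefined, to be excluded
#'   from group tables) when total exploration is zero.
#' @export
discrimination_index <- function(t_displaced_s, t_familiar_s) {
  tot <- t_displaced_s + t_familiar_s
  ifelse(tot > 0, (t_displaced_s - t_familiar_s) / tot, NaN)
}

#' Simulate an open-field track with optional object bias
#'
#' A reflected random walk at the tracking frame rate: heading follows a
#' wrapped random walk, speed an autocorrelated positive process, and a
#' \code{bias} toward object 1 adds an attraction step proportional to the
#' bias whenever the animal is within \code{bias_range_m} of that object,
#' producing extra dwell near it. Ground-truth zone times are computed from
#' the generated frames with the same half-open annulus membership rule the
#' scorer uses.
#'
#' @param cfg a \code{\link{nol_config}}.
#' @param duration_s session length (s).
#' @param frame_rate_hz tracking rate (Hz).
#' @param bias attraction strength toward object 1 (0 = unbiased walk).
#' @param bias_range_m range of the attraction (m).
#' @param mean_speed_mps typical walking speed.
#' @param seed integer seed.
#' @return list with \code{track} (a \code{\link{track}}) and \code{truth}
#'   (data frame \code{object}, \code{time_s} of exact per-frame zone
#'   membership).
#' @export
simulate_nol_track <- function(cfg = nol_config(), duration_s = 600,
                               frame_rate_hz = 15, bias = 0,
                               bias_range_m = 0.1, mean_speed_mps = 0.06,
                               seed = 1) {
  stopifnot(inherits(cfg, "nol_config"))
  set.seed(seed)
  n <- round(duration_s * frame_rate_hz)
  dt <- 1 / frame_rate_hz
  x <- y <- numeric(n)
  x[1] <- cfg$arena_m[1] / 2; y[1] <- cfg$arena_m[2] / 2
  heading <- stats::runif(1, 0, 2 * pi)
  speed <- mean_speed_mps
  for (i in 2:n) {
    heading <- heading + stats::rnorm(1, sd = 0.6)
    speed <- max(0, speed + stats::rnorm(1, sd = 0.02) -
                   0.3 * (speed - mean_speed_mps) * dt * frame_rate_hz)
    dx <- speed * cos(heading) * dt
    dy <- speed * sin(heading) * dt
    if (bias != 0) {
      vx <- cfg$object_xy_m[1, 1] - x[i - 1]
      vy <- cfg$object_xy_m[1, 2] - y[i - 1]
      d <- sqrt(vx^2 + vy^2)
      if (d < bias_range_m && d > 1e-9) {
        dx <- dx + bias * mean_speed_mps * dt * vx / d
        dy <- dy + bias * mean_speed_mps * dt * vy / d
      }
    }
    xi <- x[i - 1] + dx; yi <- y[i - 1] + dy
    # reflect at walls
    if (xi < 0) { xi <- -xi; heading <- pi - heading }
    if (xi > cfg$arena_m[1]) { xi <- 2 * cfg$arena_m[1] - xi
                               heading <- pi - heading }
    if (yi < 0) { yi <- -yi; heading <- -heading }
    if (yi > cfg$arena_m[2]) { yi <- 2 * cfg$arena_m[2] - yi
                               heading <- -heading }
    x[i] <- min(max(xi, 0), cfg$arena_m[1])
    y[i] <- min(max(yi, 0), cfg$arena_m[2])
  }
  trk <- track((0:(n - 1)) * dt, x, y, frame_rate_hz)
  r_in <- cfg$object_radius_m
  r_out <- r_in + cfg$zone_width_m
  truth <- data.frame(object = seq_len(nrow(cfg$object_xy_m)),
                      time_s = NA_real_)
  for (o in seq_len(nrow(cfg$object_xy_m))) {
    truth$time_s[o] <- sum(in_zone(x, y, cfg$object_xy_m[o, 1],
                                   cfg$object_xy_m[o, 2], r_in, r_out)) /
      frame_rate_hz
  }
  list(track = trk, truth = truth)
}
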