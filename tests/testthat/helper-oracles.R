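# Shared test oracles and small fixtures, built in code.

# Brute-force membership oracle for restrict(): per-sample interval test.
restrict_oracle <- function(signal, ivs) {
  ts <- signal_times(signal)
  keep <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(ivs))) {
    keep <- keep | (ts >= ivs$start_s[i] & ts < ivs$end_s[i])
  }
  signal$values[keep]
}

# Jaccard overlap between two interval sets.
iv_jaccard <- function(a, b) {
  inter <- iv_duration(iv_intersect(a, b))
  inter / (iv_duration(a) + iv_duration(b) - inter)
}

# Standard scored SWR run: detect on the full envelope, keep events whose
# peak lies in immobility (ripples are immobility events), match to truth.
swr_run <- function(sim, params = ripple_params(), tol_s = 0.025) {
  env <- ripple_envelope(sim$signal, params)
  bs <- baseline_stats(env, sim$immobility)
  ev <- detect_swr(env, bs, params)
  evi <- ev[in_intervals(ev$peak_s, sim$immobility), ]
  sc <- match_events(evi, sim$truth, tol_s)
  list(events = ev, events_immobile = evi, score = sc,
       rate = swr_rate(ev, sim$immobility), stats = bs)
}

# Session modulation index from a simulated photometry session.
session_modulation_index <- function(sim) {
  d <- isosbestic_dff(sim$f465, sim$f405)
  trk <- kinematics(sim$track)
  y <- dff_per_frame(d, trk)
  ok <- !is.na(y)
  modulation_index(trk$accel_mps2[ok], zscore(y[ok]))
}

# Disk mask fixture for ring/ROI geometry tests.
make_disk_mask <- function(npx, cx, cy, r_px) {
  xs <- seq_len(npx) - 0.5
  X <- matrix(xs, npx, npx)
  Y <- matrix(xs, npx, npx, byrow = TRUE)
  (X - cx)^2 + (Y - cy)^2 <= r_px^2
}

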