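# The generators are pure functions of (config, seed) and their ground truth
# must be sufficient to score the matching detector.

test_that("simulate_lfp is deterministic and respects its schedule", {
  cfg <- lfp_sim_config(duration_s = 60, rate_hz = 1250, ripple_rate_hz = 0.2)
  a <- simulate_lfp(cfg, seed = 5)
  b <- simulate_lfp(cfg, seed = 5)
  expect_identical(a$signal$values, b$signal$values)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  # ripples only inside immobility
  if (nrow(a$truth)) {
    expect_true(all(in_intervals(a$truth$peak_s, a$immobility)))
  }
  # no ripples requested -> empty truth
  z <- simulate_lfp(lfp_sim_config(duration_s = 30, rate_hz = 1250,
                                   ripple_rate_hz = 0), seed = 1)
  expect_equal(nrow(z$truth), 0)
  expect_error(
    simulate_lfp(lfp_sim_config(duration_s = 30, rate_hz = 1250,
                                mobility_schedule = interval_set(0, 30)),
                 seed = 1),
    "immobility")
})

test_that("simulate_lfp ripple counts follow the programmed Poisson law", {
  # 600 s, 300 s immobility, 0.3 Hz -> ~90 events (slightly fewer after the
  # refractory thinning); 3 sqrt(90) band around 90
  counts <- vapply(1:3, function(s) {
    nrow(simulate_lfp(lfp_sim_config(duration_s = 600, rate_hz = 1250),
                      seed = s)$truth)
  }, numeric(1))
  expect_true(all(abs(counts - 90) <= 3 * sqrt(90)))
})

test_that("simulate_ipsc_trace composes drift, kernel and noise as declared", {
  cfg0 <- ipsc_sim_config(duration_s = 5, event_rate_hz = 0, noise_sd_pa = 0,
                          drift_amp_pa = 8)
  sim0 <- simulate_ipsc_trace(cfg0, seed = 1)
  t <- signal_times(sim0$signal)
  expect_equal(sim0$signal$values, 8 * sin(2 * pi * 0.05 * t),
               tolerance = 1e-12)
  # a single noise-free event has unit-peak-normalized amplitude
  k <- 0
  for (s in 1:50) {
    sim1 <- simulate_ipsc_trace(
      ipsc_sim_config(duration_s = 4, event_rate_hz = 0.25, noise_sd_pa = 0,
                      drift_amp_pa = 0, amp_cv = 0), seed = s)
    if (nrow(sim1$truth) == 1) { k <- s; break }
  }
  expect_gt(k, 0)
  expect_equal(max(sim1$signal$values), 50, tolerance = 1e-6)
  # Poisson event count at 5 Hz over 120 s
  n <- nrow(simulate_ipsc_trace(ipsc_sim_config(duration_s = 120,
                                                rate_hz = 5000),
                                seed = 2)$truth)
  expect_true(abs(n - 600) <= 3 * sqrt(600))
  expect_error(ipsc_sim_config(rise_ms = 10, decay_ms = 5), "rise")
})

test_that("simulate_photometry shares artifacts across channels and is seeded", {
  cfg <- photometry_sim_config(duration_s = 120, rate_hz = 250)
  a <- simulate_photometry(cfg, seed = 3)
  b <- simulate_photometry(cfg, seed = 3)
  expect_identical(a$track$x_m, b$track$x_m)
  expect_identical(a$f465$values, b$f465$values)
  # no coupling: 465 and 405 differ only by scale, bleach ratio and noise
  cfg0 <- photometry_sim_config(duration_s = 60, rate_hz = 250,
                                coupling_gain = 0, artifact_amp = 0,
                                noise_sd = 0)
  s0 <- simulate_photometry(cfg0, seed = 1)
  expect_equal(s0$f465$values / s0$f405$values,
               rep(100 / 60, length(s0$f465$values)), tolerance = 1e-9)
  expect_equal(max(s0$activity$values), 0)
})

test_that("simulate_nol_track ground truth uses the scorer's membership rule", {
  cfg <- nol_config()
  sim <- simulate_nol_track(cfg, duration_s = 300, bias = 0.5, seed = 2)
  et <- exploration_times(sim$track, cfg)
  expect_equal(et$time_s, sim$truth$time_s, tolerance = 1e-12)
  sim_b <- simulate_nol_track(cfg, duration_s = 300, bias = 0.5, seed = 2)
  expect_identical(sim$truth, sim_b$truth)
  # positions remain inside the arena
  expect_true(all(sim$track$x_m >= 0 & sim$track$x_m <= cfg$arena_m[1]))
  expect_true(all(sim$track$y_m >= 0 & sim$track$y_m <= cfg$arena_m[2]))
})

test_that("unbiased walks explore the two object zones symmetrically", {
  # slow mixing makes single sessions noisy; symmetry is assessed on zone
  # time pooled over seeds
  tm <- rowSums(vapply(1:8, function(s) {
    simulate_nol_track(nol_config(), duration_s = 1200, bias = 0,
                       seed = s)$truth$time_s
  }, numeric(2)))
  expect_gt(tm[1] / tm[2], 0.8)
  expect_lt(tm[1] / tm[2], 1.25)
})

test_that("simulate_stain_image bookkeeping matches its own rendering", {
  cfg <- stain_sim_config(noise_sd = 0)
  sim <- simulate_stain_image(cfg, seed = 6)
  expect_equal(sim$image$n_roi, cfg$n_cells)
  expect_equal(nrow(sim$truth), cfg$n_cells)
  # dot-free configuration: dot channel is pure background
  s0 <- simulate_stain_image(stain_sim_config(dot_density_in = 0,
                                              dot_density_out = 0,
                                              noise_sd = 0), seed = 1)
  expect_true(all(s0$image$channels$dots == s0$image$channels$dots[1, 1]))
  expect_identical(simulate_stain_image(cfg, seed = 6)$truth, sim$truth)
  # impossible packing errors out
  expect_error(
    simulate_stain_image(stain_sim_config(size_px = 80, n_cells = 40,
                                          max_place_tries = 200), seed = 1),
    "overlap")
})
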