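test_that("ripple envelope matches rectified-sinusoid and stopband oracles", {
  rate <- 1250
  t <- (0:(20 * rate - 1)) / rate
  zero <- uniform_signal(numeric(length(t)), rate, 0, "mV")
  expect_equal(max(abs(ripple_envelope(zero)$values)), 0)
  A <- 0.4
  s150 <- uniform_signal(A * sin(2 * pi * 150 * t), rate, 0, "mV")
  env <- ripple_envelope(s150)$values
  mid <- env[(5 * rate):(15 * rate)]
  # smoothed rectified sinusoid ~ 2A/pi
  expect_gt(mean(mid), 0.55 * A)
  expect_lt(mean(mid), 0.75 * A)
  s10 <- uniform_signal(A * sin(2 * pi * 10 * t), rate, 0, "mV")
  expect_lt(mean(ripple_envelope(s10)$values[(5 * rate):(15 * rate)]),
            0.02 * A)
  expect_error(ripple_envelope(uniform_signal(rnorm(100), 400, 0, "mV")),
               "Nyquist")
})

test_that("band edges meet the 40 dB stopband requirement at 0.8x and 1.2x", {
  rate <- 2000
  t <- (0:(10 * rate - 1)) / rate
  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- hippoquant:::fft_bandpass(x, rate, 70, 250)
    mid <- (2 * rate):(8 * rate)
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_lt(20 * log10(gain_at(0.8 * 70)), -40)
  expect_lt(20 * log10(gain_at(1.2 * 250)), -40)
  expect_gt(gain_at(150), 0.99)
})

test_that("baseline statistics depend only on immobility samples", {
  rate <- 500
  set.seed(1)
  env <- uniform_signal(abs(rnorm(60 * rate)), rate, 0, "dimensionless")
  imm <- interval_set(c(0, 30), c(20, 50))
  bs <- baseline_stats(env, imm)
  vals <- restrict(env, imm)
  expect_equal(bs$mu, mean(vals))
  expect_equal(bs$sd, sd(vals))
  # altering mobility-period samples changes nothing
  env2 <- env
  mob <- in_intervals(signal_times(env), iv_complement(imm, 0, 60))
  env2$values[mob] <- env2$values[mob] * 100 + 7
  bs2 <- baseline_stats(env2, imm)
  expect_equal(bs2$mu, bs$mu)
  expect_equal(bs2$sd, bs$sd)
  # whole-span restriction equals global stats
  bs3 <- baseline_stats(env, interval_set(0, 60))
  expect_equal(bs3$mu, mean(env$values))
  expect_error(baseline_stats(env, interval_set(0, 5)), "minimum")
})

test_that("a flat envelope yields no events and thresholds act monotonically", {
  rate <- 500
  flat <- uniform_signal(rep(1, 30 * rate), rate, 0, "dimensionless")
  bs <- structure(list(mu = 1, sd = 0.1, source_intervals = NULL,
                       n_samples = 100), class = "baseline_stats")
  expect_equal(nrow(detect_swr(flat, bs)), 0)
  sim <- simulate_lfp(lfp_sim_config(duration_s = 300, rate_hz = 1250),
                      seed = 8)
  env <- ripple_envelope(sim$signal)
  b <- baseline_stats(env, sim$immobility)
  counts <- vapply(c(2, 3, 4, 5), function(th) {
    nrow(detect_swr(env, b, ripple_params(threshold_sd = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected events recover programmed ripples and SD calibration", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 300, rate_hz = 1250),
                      seed = 21)
  run <- swr_run(sim)
  expect_gte(run$score$recall, 0.9)
  expect_gte(run$score$precision, 0.9)
  matched <- run$events_immobile$max_power_sd[run$score$matches$detected]
  expect_lt(max(abs(matched - 6)), 1)
})

test_that("swr_rate counts immobility-peaked events over immobility time", {
  ev <- event_table(onset_s = c(1, 5, 12), peak_s = c(1.1, 5.1, 12.1),
                    offset_s = c(1.2, 5.2, 12.2), amplitude = 1:3)
  imm <- interval_set(c(0, 10), c(6, 14))
  expect_equal(swr_rate(ev, imm), 3 / 10)
  expect_equal(swr_rate(event_table(), imm), 0)
  expect_equal(swr_rate(ev, interval_set(0, 2), denominator = "total",
                        total_duration_s = 20), 1 / 20)
  expect_error(swr_rate(ev, interval_set()), "> 0")
})

test_that("common-threshold pooling matches per-session and pooled statistics", {
  # threshold identity is assessed on ripple-free baseline sessions, where
  # the envelope statistics are estimated from the full immobility time
  cfg <- lfp_sim_config(duration_s = 300, rate_hz = 1250, ripple_rate_hz = 0,
                        theta_amp_mv = 0, gamma_amp_mv = 0)
  s1 <- simulate_lfp(cfg, seed = 31)
  s2 <- simulate_lfp(cfg, seed = 32)
  mk <- function(s) list(envelope = ripple_envelope(s$signal),
                         immobility = s$immobility)
  # statistically identical sessions: pooled threshold within 1% of each
  res <- detect_swr_common_threshold(list(mk(s1), mk(s2)))
  th_pool <- res$stats$mu + 3 * res$stats$sd
  for (s in list(s1, s2)) {
    b <- baseline_stats(ripple_envelope(s$signal), s$immobility)
    expect_lt(abs((b$mu + 3 * b$sd) - th_pool) / th_pool, 0.01)
  }
  # single session (with ripples) degenerates to plain detection
  sr <- simulate_lfp(lfp_sim_config(duration_s = 200, rate_hz = 1250),
                     seed = 33)
  one <- detect_swr_common_threshold(list(mk(sr)))
  br <- baseline_stats(ripple_envelope(sr$signal), sr$immobility)
  plain <- detect_swr(ripple_envelope(sr$signal), br)
  expect_equal(as.data.frame(one$events[[1]]), as.data.frame(plain))
  b1 <- baseline_stats(ripple_envelope(s1$signal), s1$immobility)
  # noisier session: pooled threshold strictly between per-session ones
  s3 <- s2
  s3$signal$values <- s3$signal$values * 1.5
  res2 <- detect_swr_common_threshold(list(mk(s1), mk(s3)))
  b3 <- baseline_stats(ripple_envelope(s3$signal), s3$immobility)
  th1 <- b1$mu + 3 * b1$sd
  th3 <- b3$mu + 3 * b3$sd
  th_p <- res2$stats$mu + 3 * res2$stats$sd
  expect_true(th_p > min(th1, th3) && th_p < max(th1, th3))
  # heterogeneous rates are rejected
  bad <- list(mk(s1),
              list(envelope = uniform_signal(rnorm(1000), 500),
                   immobility = interval_set(0, 2)))
  expect_error(detect_swr_common_threshold(bad), "heterogeneous")
})

test_that("SD-unit outputs are invariant to rescaling the raw LFP", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 200, rate_hz = 1250),
                      seed = 41)
  base <- swr_run(sim)
  scaled <- sim
  scaled$signal <- uniform_signal(sim$signal$values * 10, 1250, 0, "mV")
  res <- swr_run(scaled)
  expect_equal(res$rate, base$rate, tolerance = 1e-9)
  expect_equal(res$events$mean_power_sd, base$events$mean_power_sd,
               tolerance = 1e-6)
  expect_equal(res$events$max_power_sd, base$events$max_power_sd,
               tolerance = 1e-6)
})
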