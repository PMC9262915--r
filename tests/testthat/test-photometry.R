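test_that("a perfect affine channel pair gives identically zero dF/F", {
  t <- (0:4999) / 250
  f405 <- uniform_signal(60 * exp(-t / 500) + 2 * sin(2 * pi * 0.1 * t),
                         250, 0, "a.u.")
  f465 <- uniform_signal(2 * f405$values + 3, 250, 0, "a.u.")
  expect_lt(max(abs(isosbestic_dff(f465, f405)$values)), 1e-9)
  expect_error(isosbestic_dff(f465, uniform_signal(rep(5, 5000), 250)),
               "zero variance")
})

test_that("dF/F is invariant to common gain and rejects shared artifacts", {
  sim <- simulate_photometry(photometry_sim_config(duration_s = 120,
                                                   rate_hz = 250), seed = 4)
  d1 <- isosbestic_dff(sim$f465, sim$f405)
  f465k <- uniform_signal(sim$f465$values * 3.7, 250, 0, "a.u.")
  f405k <- uniform_signal(sim$f405$values * 3.7, 250, 0, "a.u.")
  expect_equal(isosbestic_dff(f465k, f405k)$values, d1$values,
               tolerance = 1e-9)
  # imposing one more shared fractional artifact barely moves dF/F
  cfg0 <- photometry_sim_config(duration_s = 120, rate_hz = 250,
                                artifact_amp = 0, noise_sd = 0.05)
  a <- simulate_photometry(cfg0, seed = 9)
  art <- 1 + 0.05 * sin(2 * pi * 0.2 * signal_times(a$f465))
  f465a <- uniform_signal(a$f465$values * art, 250, 0, "a.u.")
  f405a <- uniform_signal(a$f405$values * art, 250, 0, "a.u.")
  d0 <- isosbestic_dff(a$f465, a$f405)$values
  da <- isosbestic_dff(f465a, f405a)$values
  # the artifact swings fluorescence by 5%; the residual dF/F change stays
  # below 10% of that fractional size (0.5 percentage points)
  expect_lt(sd(da - d0), 0.1 * 5)
})

test_that("a programmed 5 percent transient is recovered", {
  t <- (0:(300 * 250 - 1)) / 250
  bleach <- exp(-t / 2000)
  act <- 0.05 * exp(-((t - 150)^2) / (2 * 2^2))       # 5% Gaussian transient
  set.seed(2)
  f465 <- uniform_signal(100 * bleach * (1 + act) + rnorm(length(t), sd = .02),
                         250, 0, "a.u.")
  f405 <- uniform_signal(60 * bleach + rnorm(length(t), sd = .02),
                         250, 0, "a.u.")
  d <- isosbestic_dff(f465, f405)
  expect_lt(abs(max(d$values) - 5), 0.25)
})

test_that("mobility segmentation matches its thresholds and the generator", {
  n <- 300
  still <- kinematics(track((0:(n - 1)) / 15, rep(0.1, n), rep(0.1, n), 15))
  seg0 <- segment_mobility(still)
  expect_equal(nrow(seg0$mobility), 0)
  expect_equal(iv_duration(seg0$immobility), n / 15)
  xm <- 0.01 + cumsum(rep(0.1 / 15, n))
  moving <- kinematics(track((0:(n - 1)) / 15, xm - xm[1] + 0.01,
                             rep(0.1, n), 15))
  seg1 <- segment_mobility(moving)
  expect_equal(iv_duration(seg1$mobility), n / 15)
  sim <- simulate_photometry(photometry_sim_config(duration_s = 300,
                                                   rate_hz = 250), seed = 2)
  seg <- segment_mobility(sim$track)
  expect_gte(iv_jaccard(seg$mobility, sim$bouts), 0.9)
})

test_that("transition-triggered averages align and propagate uncertainty", {
  rate <- 100
  n <- 60 * rate
  # deterministic +1 step at every transition
  trans <- c(10, 25, 40)
  x <- numeric(n)
  for (tr in trans) x[(tr * rate + 1):n] <- x[(tr * rate + 1):n] + 1
  sig <- uniform_signal(x, rate, 0, "dimensionless")
  eta <- transition_triggered_average(sig, trans, window_s = c(2, 2))
  step <- eta$mean - eta$mean[1]
  expect_equal(step[eta$t_s < 0], rep(0, sum(eta$t_s < 0)), tolerance = 1e-9)
  post <- step[eta$t_s > 0]
  expect_equal(post, rep(post[1], length(post)), tolerance = 1e-9)
  expect_equal(eta$n, 3)
  # constant signal flags zero variance
  etaz <- transition_triggered_average(uniform_signal(rep(2, n), rate),
                                       trans, c(1, 1))
  expect_true(etaz$zero_variance)
  expect_equal(max(abs(etaz$mean)), 0)
  expect_error(transition_triggered_average(sig, c(-5), c(2, 2)), "window")
})

test_that("locomotion-onset ETA of simulated calcium rises after t = 0", {
  ok <- vapply(1:8, function(s) {
    sim <- simulate_photometry(photometry_sim_config(duration_s = 300,
                                                     rate_hz = 250), seed = s)
    d <- isosbestic_dff(sim$f465, sim$f405)
    eta <- transition_triggered_average(d, sim$bouts$start_s, c(2, 2))
    mean(eta$mean[eta$t_s > 0 & eta$t_s < 1.5]) >
      mean(eta$mean[eta$t_s < 0])
  }, logical(1))
  expect_gte(sum(ok), 7)
})

test_that("acceleration response curves recover coupling and nulls", {
  sim <- simulate_photometry(photometry_sim_config(duration_s = 600,
                                                   rate_hz = 250), seed = 6)
  d <- isosbestic_dff(sim$f465, sim$f405)
  trk <- kinematics(sim$track)
  arc <- acceleration_response_curve(d, trk, n_bins = 8)
  expect_true(all(arc$n >= 1))
  # ties at zero acceleration may collapse equal-count bins on one side
  expect_lte(nrow(arc), 16)
  expect_setequal(unique(arc$side), c("acceleration", "deceleration"))
  # response increases from deceleration to acceleration bins
  fit <- lm(mean_z ~ accel_mps2, data = arc)
  expect_gt(coef(fit)[2], 0)
  # null: dF/F decoupled from motion stays within its standard errors
  null <- simulate_photometry(photometry_sim_config(duration_s = 600,
                                                    rate_hz = 250,
                                                    coupling_gain = 0),
                              seed = 7)
  dn <- isosbestic_dff(null$f465, null$f405)
  arcn <- acceleration_response_curve(dn, kinematics(null$track), n_bins = 8)
  expect_gt(mean(abs(arcn$mean_z) <= 3 * arcn$sem), 0.9)
  expect_error(acceleration_response_curve(d, trk[1:20, ], n_bins = 8),
               "pairs")
})

test_that("modulation index has its closed form, antisymmetry and null", {
  x <- seq(-2, 2, length.out = 200)
  g <- 0.7
  mi <- modulation_index(x, g * x)
  expect_equal(mi$index, 2 * g * quantile(abs(x), 0.95, names = FALSE),
               tolerance = 1e-6)
  mi_neg <- modulation_index(x, -g * x)
  expect_equal(mi_neg$index, -mi$index, tolerance = 1e-6)
  # permutation null: uncoupled dF/F gives an index within the null band
  set.seed(5)
  xr <- rnorm(2000)
  yr <- rnorm(2000)
  obs <- abs(modulation_index(xr, yr)$index)
  nulls <- vapply(1:199, function(i) {
    abs(modulation_index(sample(xr), yr)$index)
  }, numeric(1))
  expect_lt(obs, quantile(nulls, 0.975))
  expect_error(modulation_index(abs(xr), yr), "both signs")
  expect_error(modulation_index(xr[1:5], yr[1:5]), "at least 10")
})

test_that("the modulation index orders sessions by coupling gain", {
  ok <- vapply(1:6, function(s) {
    idx <- vapply(c(0.05, 0.065, 0.08), function(g) {
      sim <- simulate_photometry(
        photometry_sim_config(duration_s = 300, rate_hz = 250,
                              coupling_gain = g), seed = s)
      session_modulation_index(sim)$index
    }, numeric(1))
    all(diff(idx) > 0)
  }, logical(1))
  expect_gte(sum(ok), 5)
})
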