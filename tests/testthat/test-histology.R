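test_that("roi means respect common thresholding", {
  mask <- matrix(0L, 40, 40)
  mask[5:10, 5:10] <- 1L
  mask[20:28, 20:28] <- 2L
  ch <- matrix(7, 40, 40)
  img <- annotated_image(list(a = ch), pixel_size_um = 1, roi_masks = mask)
  mi <- roi_mean_intensity(img, "a", threshold = 3)
  expect_equal(mi$mean_intensity, c(7, 7))
  expect_equal(roi_mean_intensity(img, "a", threshold = 10)$mean_intensity,
               c(0, 0))
  # suprathreshold mode averages only the surviving pixels
  ch2 <- ch
  ch2[5:10, 5:7] <- 1
  img2 <- annotated_image(list(a = ch2), 1, mask)
  expect_lt(roi_mean_intensity(img2, "a", threshold = 3)$mean_intensity[1], 7)
  expect_equal(roi_mean_intensity(img2, "a", threshold = 3,
                                  mode = "suprathreshold")$mean_intensity[1],
               7)
  expect_error(roi_mean_intensity(img, "missing"), "unknown channel")
})

test_that("noise-free synthetic images return programmed intensities", {
  sim <- simulate_stain_image(stain_sim_config(noise_sd = 0), seed = 4)
  mi <- roi_mean_intensity(sim$image, "arom", threshold = 0)
  expect_lt(max(abs(mi$mean_intensity / sim$truth$arom_intensity - 1)), 0.02)
})

test_that("perimetric rings match the analytic annulus and stay disjoint", {
  npx <- 200
  px <- 0.5
  mask <- matrix(0L, npx, npx)
  mask[make_disk_mask(npx, 100, 100, 20)] <- 1L     # r = 10 um
  ring <- perimetric_ring(mask, 1, ring_width_um = 3.8, pixel_size_um = px)
  expect_false(any(ring & (mask == 1L)))
  area <- sum(ring) * px^2
  analytic <- pi * ((10 + 3.8)^2 - 10^2)
  expect_lt(abs(area - analytic), 2 * pi * (10 + 3.8) * px)
  expect_false(attr(ring, "clipped"))
  # zero width -> empty ring; distant cells -> disjoint rings
  expect_equal(sum(perimetric_ring(mask, 1, 0, px)), 0)
  mask2 <- mask
  mask2[make_disk_mask(npx, 40, 40, 16)] <- 2L
  r1 <- perimetric_ring(mask2, 1, 3.8, px)
  r2 <- perimetric_ring(mask2, 2, 3.8, px)
  expect_false(any(r1 & r2))
  # ring touching the border is flagged clipped
  mask3 <- matrix(0L, 60, 60)
  mask3[make_disk_mask(60, 6, 30, 5)] <- 1L
  expect_true(attr(perimetric_ring(mask3, 1, 3.8, 1), "clipped"))
  expect_error(perimetric_ring(mask, 99, 3.8, px), "label")
})

test_that("dot densities are exact on clean images and monotone in threshold", {
  sim <- simulate_stain_image(stain_sim_config(noise_sd = 0), seed = 4)
  for (k in seq_len(sim$image$n_roi)) {
    dd <- dot_density(sim$image, "dots", k, threshold = 50)
    expect_equal(dd$n_dots, sim$truth$n_dots[k])
  }
  dd1 <- dot_density(sim$image, "dots", 1, threshold = 50)
  dd2 <- dot_density(sim$image, "dots", 1, threshold = 100)
  expect_lte(dd2$density_per_um2, dd1$density_per_um2)
  empty <- dot_density(sim$image, "pv", 1, threshold = 1e6)
  expect_equal(empty$density_per_um2, 0)
  expect_error(dot_density(sim$image, "dots",
                           matrix(FALSE, 360, 360), threshold = 50),
               "zero area")
})

test_that("chance colocalization flips only the signal channel", {
  sim <- simulate_stain_image(stain_sim_config(noise_sd = 0), seed = 9)
  cc <- chance_colocalization(sim$image, "dots", 1, threshold = 50)
  expect_equal(cc$observed$roi_area_um2, cc$chance$roi_area_um2)
  # flipping twice restores the observed measurement exactly
  img2 <- sim$image
  ch <- img2$channels$dots
  img2$channels$dots <- ch[nrow(ch):1, , drop = FALSE]
  cc2 <- chance_colocalization(img2, "dots", 1, threshold = 50)
  expect_equal(cc2$chance$n_dots, cc$observed$n_dots)
  expect_equal(cc2$chance$density_per_um2, cc$observed$density_per_um2)
})

test_that("dots programmed inside cells are enriched over chance", {
  ok <- vapply(1:10, function(s) {
    sim <- simulate_stain_image(stain_sim_config(), seed = s)
    obs <- 0; ch <- 0
    for (k in seq_len(sim$image$n_roi)) {
      cc <- chance_colocalization(sim$image, "dots", k, threshold = 50)
      obs <- obs + cc$observed$n_dots
      ch <- ch + cc$chance$n_dots
    }
    obs > ch
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("a uniform dot field shows no enrichment beyond noise", {
  sim <- simulate_stain_image(
    stain_sim_config(dot_density_in = 0.01, dot_density_out = 0.01),
    seed = 3)
  diffs <- vapply(seq_len(sim$image$n_roi), function(k) {
    cc <- chance_colocalization(sim$image, "dots", k, threshold = 50)
    cc$observed$density_per_um2 - cc$chance$density_per_um2
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-12)
})

test_that("cumulative curves average per animal on a common grid", {
  single <- cumulative_curves(c(1, 4, 9), rep("m1", 3), n_bins = 6)
  expect_equal(single$mean, as.numeric(single$per_animal[1, ]))
  expect_equal(single$mean[length(single$mean)], 1)
  # identical values: step from 0 to 1 at that value
  same <- cumulative_curves(rep(5, 10), rep("m1", 10), n_bins = 4)
  expect_equal(same$mean[same$edges >= 5][1], 1)
  # two shifted animals: mean curve strictly between them at interior bins
  v <- c(rnorm(200, 10, 1), rnorm(200, 14, 1))
  an <- rep(c("a", "b"), each = 200)
  cv <- cumulative_curves(v, an, n_bins = 18)
  interior <- cv$mean > 0.05 & cv$mean < 0.95
  expect_true(all(cv$mean[interior] <= cv$per_animal["a", interior] + 1e-12))
  expect_true(all(cv$mean[interior] >= cv$per_animal["b", interior] - 1e-12))
  expect_error(cumulative_curves(numeric(0), character(0)), "no finite")
})
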