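test_that("a fixed spec and seed reproduce phantoms bit-identically", {
  spec <- phantom_spec(5, c(384, 384), psf_sigma_nm = 15,
                       noise = "gaussian", snr = 10, seed = 42)
  a <- render_microtubules(spec, 2, 62.1)
  b <- render_microtubules(spec, 2, 62.1)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  spec2 <- phantom_spec(2, c(512, 512), psf_sigma_nm = 15,
                        noise = "poisson", peak_counts = 200, seed = 7)
  n1 <- render_npc_field(spec2, 2, 53.5, corner_prob = 0.7)
  n2 <- render_npc_field(spec2, 2, 53.5, corner_prob = 0.7)
  expect_identical(n1$stack$voxels, n2$stack$voxels)
})

test_that("microtubule rendering enforces Nyquist and handles n = 0", {
  spec <- phantom_spec(40, c(64, 64), psf_sigma_nm = 15, seed = 1)
  expect_error(render_microtubules(spec, 1, 62.1), "Nyquist")
  spec0 <- phantom_spec(5, c(64, 64), psf_sigma_nm = 15, seed = 1)
  out <- render_microtubules(spec0, 0, 62.1)
  expect_equal(sum(out$stack$voxels), 0)
  expect_equal(nrow(out$truth), 0)
})

test_that("sidewall separability follows the two-Gaussian peak geometry", {
  # transverse profile of two parallel lines blurred by the PSF: two local
  # maxima 62.1 nm apart for sigma = 15, merged into one for sigma = 60 —
  # matching the analytic sum-of-two-Gaussians evaluation
  x <- seq(-150, 150, by = 0.5)
  expect_equal(n_local_maxima(two_gauss(x, 62.1, 15)), 2L)
  expect_equal(n_local_maxima(two_gauss(x, 62.1, 60)), 1L)
  for (sg in c(15, 60)) {
    spec <- phantom_spec(5, c(512, 512), psf_sigma_nm = sg, noise = "none",
                         seed = 3)
    mt <- render_microtubules(spec, 1, 62.1, orientation_policy = 0)
    box <- boxes_from_truth(mt$truth, length_nm = 240)[[1]]
    pr <- extract_profile(mt$stack, box, step_nm = 1)
    n_max <- n_local_maxima(exmqc:::moving_average(pr$intensities, 3))
    expect_equal(n_max, if (sg == 15) 2L else 1L)
    if (sg == 15) {
      y <- exmqc:::moving_average(pr$intensities, 3)
      lm <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
      pk <- pr$positions_nm[lm]
      expect_equal(abs(diff(pk)), 62.1, tolerance = 0.05)
    }
  }
})

test_that("NPC truth geometry matches the chord-length formula", {
  spec <- phantom_spec(2, c(256, 256), psf_sigma_nm = 15, noise = "none",
                       seed = 5)
  np <- render_npc_field(spec, 1, radius_nm = 53.5, corner_prob = 1)
  co <- np$truth$corners
  expect_true(all(co$present))
  d <- sqrt(diff(co$x_nm)^2 + diff(co$y_nm)^2)
  expect_equal(d, rep(2 * 53.5 * sin(pi / 8), 7), tolerance = 1e-9)
})

test_that("corner labeling probabilities behave binomially", {
  spec <- phantom_spec(4, c(1024, 1024), psf_sigma_nm = 15, noise = "none",
                       seed = 11)
  full <- render_npc_field(spec, 60, 53.5, corner_prob = 1)
  counts_full <- tapply(full$truth$corners$present, full$truth$corners$npc,
                        sum)
  expect_true(all(counts_full == 8))
  half <- render_npc_field(spec, 60, 53.5, corner_prob = 0.5)
  mean_corners <- mean(tapply(half$truth$corners$present,
                              half$truth$corners$npc, sum))
  # binomial(8, 0.5): mean 4, se over 60 NPCs = sqrt(8*.25/60) = 0.18
  expect_lt(abs(mean_corners - 4), 3.5 * sqrt(8 * 0.25 / 60))
})

test_that("rendered intensity is conserved under PSF convolution", {
  spec <- phantom_spec(2, c(256, 256), psf_sigma_nm = 12, noise = "none",
                       seed = 9)
  np <- render_npc_field(spec, 1, 53.5, corner_prob = 1)
  total <- sum(np$stack$voxels) * prod(spec$pixel_size_nm)
  expected <- 8 * 2 * pi * 12^2       # 8 unit-amplitude Gaussian emitters
  expect_equal(total, expected, tolerance = 1e-6)
})

test_that("unit consistency: common rescaling of pixel size and expansion factor", {
  spec <- phantom_spec(5, c(384, 384), psf_sigma_nm = 15, noise = "none",
                       seed = 13)
  mt <- render_microtubules(spec, 1, 62.1)
  # same voxels presented as physically 20x larger with expansion factor 20
  scaled <- image_stack(mt$stack$voxels, 5 * 20, expansion_factor = 20)
  box <- boxes_from_truth(mt$truth)[[1]]
  f1 <- fit_double_gaussian(extract_profile(mt$stack, box))
  f2 <- fit_double_gaussian(extract_profile(scaled, box))
  expect_equal(f1$peak_to_peak_nm, f2$peak_to_peak_nm, tolerance = 1e-9)
})

test_that("frc pairs share signal and differ only in noise", {
  spec <- phantom_spec(5, c(384, 384), psf_sigma_nm = 15, noise = "none",
                       seed = 2)
  mt <- render_microtubules(spec, 2, 62.1)
  clean <- make_frc_pair(mt$stack, spec)
  expect_identical(clean[[1]]$voxels, clean[[2]]$voxels)
  noisy_spec <- phantom_spec(5, c(384, 384), psf_sigma_nm = 15,
                             noise = "gaussian", snr = 5, seed = 2)
  noisy <- make_frc_pair(mt$stack, noisy_spec)
  expect_false(identical(noisy[[1]]$voxels, noisy[[2]]$voxels))
  again <- make_frc_pair(mt$stack, noisy_spec)
  expect_identical(noisy[[1]]$voxels, again[[1]]$voxels)
  # averaging many independent realizations converges on the clean signal
  hi_snr <- phantom_spec(5, c(384, 384), psf_sigma_nm = 15,
                         noise = "gaussian", snr = 1000, seed = 2)
  pair <- make_frc_pair(mt$stack, hi_snr)
  avg <- (pair[[1]]$voxels + pair[[2]]$voxels) / 2
  expect_lt(max(abs(avg - mt$stack$voxels)), 0.01 * max(mt$stack$voxels))
})

test_that("warp pairs store the exact field and amplitude 0 is the identity", {
  spec <- phantom_spec(5, c(192, 192), psf_sigma_nm = 15, noise = "none",
                       seed = 8)
  wp0 <- make_warp_pair(spec, amplitude_nm = 0)
  expect_identical(wp0$reference$voxels, wp0$warped$voxels)
  expect_true(all(wp0$truth$ux_nm == 0))
  wp <- make_warp_pair(spec, amplitude_nm = 10, correlation_length_nm = 100)
  rms <- sqrt(mean(wp$truth$ux_nm^2 + wp$truth$uy_nm^2))
  expect_equal(rms, 10, tolerance = 1e-9)
  expect_false(identical(wp$reference$voxels, wp$warped$voxels))
})

test_that("synapse phantoms respect geometry contracts", {
  spec <- phantom_spec(c(8, 8, 12), c(128, 128, 28), psf_sigma_nm = 15,
                       noise = "none", seed = 4)
  expect_error(render_synapse_pair(spec, 1, nanodomain_size_nm = 400),
               "larger than the cluster")
  sy <- render_synapse_pair(spec, 1, nanodomain_size_nm = 60,
                            n_nanodomains = 2, trans_offset_nm = 0,
                            cleft_nm = 40)
  expect_equal(dim(sy$stack$voxels)[4], 2L)
  hot <- sy$truth$hotspots
  ref <- hot[hot$channel == "reference", ]
  mea <- hot[hot$channel == "measured", ]
  # trans offset 0: measured hotspots sit exactly one cleft away from
  # their reference partners
  d <- sqrt((ref$x_nm - mea$x_nm)^2 + (ref$y_nm - mea$y_nm)^2 +
              (ref$z_nm - mea$z_nm)^2)
  expect_equal(d, rep(40, nrow(ref)), tolerance = 1e-9)
})
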