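test_that("FFT autocorrelation equals the exhaustive pair oracle", {
  set.seed(7)
  d <- c(11, 11, 9)
  v <- array(runif(prod(d)), d)
  cc <- arrayInd(seq_len(prod(d)), d)
  mask <- array((cc[, 1] - 6)^2 + (cc[, 2] - 6)^2 +
                  ((cc[, 3] - 5) * 1.4)^2 <= 20, d)
  vs <- c(4, 4, 6)
  roi <- roi_from_array(v, mask, vs)
  got <- autocorrelation_ga(roi, shell_nm = 5, max_radius_nm = 60)
  want <- oracle_ga(roi$coords, roi$intensities, vs, 5, 60)
  expect_lt(max(abs(got$g_a - want), na.rm = TRUE), 1e-6)
  expect_equal(is.na(got$g_a), is.na(want))
})

test_that("uniform clusters sit at baseline 1; scaling leaves g_a unchanged", {
  d <- c(10, 10, 8)
  cc <- arrayInd(seq_len(prod(d)), d)
  mask <- array((cc[, 1] - 5.5)^2 + (cc[, 2] - 5.5)^2 +
                  ((cc[, 3] - 4.5) * 1.3)^2 <= 15, d)
  v <- array(3, d)
  roi <- roi_from_array(v, mask, c(5, 5, 7))
  cur <- autocorrelation_ga(roi, 5, 50)
  expect_true(all(abs(cur$g_a[!is.na(cur$g_a)] - 1) < 1e-9))
  set.seed(3)
  v2 <- array(runif(prod(d)) + 0.5, d)
  r1 <- roi_from_array(v2, mask, c(5, 5, 7))
  r2 <- roi_from_array(v2 * 13, mask, c(5, 5, 7))
  expect_equal(autocorrelation_ga(r1, 5, 50)$g_a,
               autocorrelation_ga(r2, 5, 50)$g_a, tolerance = 1e-12)
})

test_that("distances honor anisotropic voxel sizes", {
  # the same isotropic Gaussian blob sampled on two voxel aspect ratios
  # must give the same g_a(r) in nm
  mk <- function(vs, d) {
    cc <- arrayInd(seq_len(prod(d)), d)
    ctr <- (d + 1) / 2
    r2 <- ((cc[, 1] - ctr[1]) * vs[1])^2 + ((cc[, 2] - ctr[2]) * vs[2])^2 +
      ((cc[, 3] - ctr[3]) * vs[3])^2
    v <- array(1 + 3 * exp(-r2 / (2 * 30^2)), d)
    mask <- array(r2 <= 80^2, d)
    roi_from_array(v, mask, vs)
  }
  c1 <- autocorrelation_ga(mk(c(8, 8, 8), c(23, 23, 23)), 10, 100)
  c2 <- autocorrelation_ga(mk(c(4, 4, 16), c(45, 45, 12)), 10, 100)
  ok <- !is.na(c1$g_a) & !is.na(c2$g_a)
  expect_lt(max(abs(c1$g_a[ok] - c2$g_a[ok])), 0.06)
})

test_that("segmentation recovers the true synapse count and respects k_sigma", {
  spec <- phantom_spec(c(8, 8, 12), c(256, 256, 28), psf_sigma_nm = 15,
                       noise = "gaussian", snr = 15, seed = 31)
  sy <- render_synapse_pair(spec, 6, nanodomain_size_nm = 60,
                            n_nanodomains = 2, cleft_nm = 50)
  for (ch in c("reference", "measured")) {
    rois <- segment_synapses(get_channel(sy$stack, ch), k_sigma = 7)
    expect_equal(length(rois), 6L)
  }
  # an all-background image yields an empty list, no error
  noise_only <- image_stack(array(rnorm(32 * 32 * 8), c(32, 32, 8)),
                            c(8, 8, 12))
  expect_equal(length(segment_synapses(noise_only, k_sigma = 7)), 0L)
  # raising the threshold never increases the component count
  ref <- get_channel(sy$stack, "reference")
  n_at <- vapply(c(5, 7, 12, 25), function(k)
    length(segment_synapses(ref, k_sigma = k)), integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("channel pairing matches juxtaposed clusters", {
  spec <- phantom_spec(c(8, 8, 12), c(256, 256, 28), psf_sigma_nm = 15,
                       noise = "gaussian", snr = 15, seed = 31)
  sy <- render_synapse_pair(spec, 6, cleft_nm = 50)
  ra <- segment_synapses(get_channel(sy$stack, "reference"))
  rb <- segment_synapses(get_channel(sy$stack, "measured"))
  pairs <- pair_clusters(ra, rb)
  expect_equal(nrow(pairs), 6L)
  expect_true(all(pairs$centroid_dist_nm < 150))
})

test_that("enrichment is 1 for a uniform measured cluster and peaks at 0 for aligned hotspots", {
  d <- c(24, 24, 16); vs <- c(8, 8, 12)
  cc <- arrayInd(seq_len(prod(d)), d)
  ctr <- c(12, 12, 8)
  r2 <- ((cc[, 1] - ctr[1]) * vs[1])^2 + ((cc[, 2] - ctr[2]) * vs[2])^2 +
    ((cc[, 3] - ctr[3]) * vs[3])^2
  mask <- array(r2 <= 90^2, d)
  unif <- roi_from_array(array(4, d), mask, vs)
  refroi <- roi_from_array(array(exp(-r2 / (2 * 25^2)), d), mask, vs)
  cur <- cross_enrichment(unif, refroi, shell_nm = 10, max_radius_nm = 120)
  expect_true(all(abs(cur$enrichment[!is.na(cur$enrichment)] - 1) < 1e-9))
  # measured hotspot centered on the reference peak: enrichment peaks at
  # r = 0 and decays to ~1 near the hotspot scale
  mea <- roi_from_array(array(1 + 4 * exp(-r2 / (2 * 25^2)), d), mask, vs)
  cur2 <- cross_enrichment(mea, refroi, shell_nm = 10, max_radius_nm = 150)
  expect_equal(which.max(cur2$enrichment), 1L)
  expect_gt(cur2$enrichment[1], 2)
  expect_lt(abs(cur2$enrichment[9] - 1), 0.35)
  # displacing the measured hotspot far from the reference peak inverts
  # the relation: at r = 0 the measured cluster is depleted
  r2_off <- ((cc[, 1] - ctr[1]) * vs[1] - 100)^2 +
    ((cc[, 2] - ctr[2]) * vs[2])^2 + ((cc[, 3] - ctr[3]) * vs[3])^2
  mea_off <- roi_from_array(array(1 + 4 * exp(-r2_off / (2 * 25^2)), d),
                            mask, vs)
  cur3 <- cross_enrichment(mea_off, refroi, shell_nm = 10,
                           max_radius_nm = 150)
  expect_lte(cur3$enrichment[1], 1)
  # affine intensity invariance of the measured channel scale
  mea2 <- roi_from_array(array(5 * (1 + 4 * exp(-r2 / (2 * 25^2))), d),
                         mask, vs)
  expect_equal(cross_enrichment(mea2, refroi, 10, 150)$enrichment,
               cur2$enrichment, tolerance = 1e-12)
})

test_that("nanodomain size is read from the flattening radius", {
  # analytic g_a curve for a Gaussian hotspot of known FWHM
  mkcurve <- function(fwhm, rmax = 200, shell = 5, amp = 0.5) {
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    r <- seq(shell / 2, rmax, by = shell)
    structure(data.frame(radius_nm = r,
                         g_a = 1 + amp * exp(-r^2 / (4 * sig^2)),
                         n_pairs = 1000),
              class = c("autocorr_curve", "data.frame"))
  }
  nd60 <- nanodomain_size(mkcurve(60))
  expect_true(nd60$defined)
  expect_lt(abs(nd60$size_nm - 60), 20)
  # contrast independence: a 4x brighter hotspot reads the same size
  nd60b <- nanodomain_size(mkcurve(60, amp = 2))
  expect_lt(abs(nd60b$size_nm - nd60$size_nm), 11)
  # larger hotspots read as larger sizes
  nd100 <- nanodomain_size(mkcurve(100))
  expect_gt(nd100$size_nm, nd60$size_nm)
  # flat curve: undefined, flagged
  flat <- mkcurve(60, amp = 0)
  expect_false(nanodomain_size(flat)$defined)
  # locality: appending flat tail shells does not move the estimate
  cu <- mkcurve(60)
  tail_r <- seq(max(cu$radius_nm) + 5, max(cu$radius_nm) + 100, by = 5)
  ext <- structure(rbind(cu, data.frame(radius_nm = tail_r,
                                        g_a = min(cu$g_a),
                                        n_pairs = 1000)),
                   class = c("autocorr_curve", "data.frame"))
  expect_equal(nanodomain_size(ext)$size_nm, nd60$size_nm, tolerance = 6)
  expect_error(nanodomain_size(mkcurve(60, rmax = 15)), "5 shells")
})

test_that("rendered hotspots elevate g_a at small radii, decaying toward baseline", {
  spec <- phantom_spec(c(8, 8, 12), c(128, 128, 28), psf_sigma_nm = 10,
                       noise = "gaussian", snr = 30, seed = 51)
  sy <- render_synapse_pair(spec, 1, nanodomain_size_nm = 60,
                            n_nanodomains = 2, cleft_nm = 50,
                            envelope = "uniform", cluster_radius_nm = 140)
  rois <- segment_synapses(get_channel(sy$stack, "reference"), k_sigma = 7)
  cu <- autocorrelation_ga(rois[[1]], 8, 170)
  g <- cu$g_a[!is.na(cu$g_a)]
  r <- cu$radius_nm[!is.na(cu$g_a)]
  # elevated at radii below the hotspot size, decayed well past it
  expect_gt(mean(g[r < 60]), 1.05)
  expect_gt(mean(g[r < 60]) - mean(g[r > 120]), 0.1)
})

test_that("SNR follows its definition and invariances", {
  d <- c(32, 32, 8)
  set.seed(5)
  v <- array(rnorm(prod(d), 0, 10), d)
  v[10:14, 10:14, 3:5] <- 70
  st <- image_stack(v, c(8, 8, 12))
  mask <- array(TRUE, d); mask[5:20, 5:20, ] <- FALSE
  roi <- roi_from_array(v, array(FALSE, d) | (v == 70), c(8, 8, 12))
  got <- snr(st, roi, mask)
  expect_equal(got, 70 / stats::sd(v[mask]), tolerance = 1e-9)
  # roi drawn inside background: SNR about 0-1
  set.seed(6)
  bgroi_mask <- array(FALSE, d); bgroi_mask[25:28, 25:28, 6:7] <- TRUE
  bgroi <- roi_from_array(v, bgroi_mask & mask, c(8, 8, 12))
  expect_lt(abs(snr(st, bgroi, mask)), 1)
  # global intensity scaling cancels
  st2 <- image_stack(v * 3.7, c(8, 8, 12))
  roi2 <- roi_from_array(v * 3.7, v == 70, c(8, 8, 12))
  expect_equal(snr(st2, roi2, mask), got, tolerance = 1e-9)
  expect_error(snr(image_stack(array(1, d), c(8, 8, 12)),
                   roi, mask), "zero background")
})
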