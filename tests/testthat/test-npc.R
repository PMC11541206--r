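render_one_npc <- function(radius_nm = 53.5, psf = 5, pixel = 2,
                           noise = "none", snr = 10, seed = 1,
                           corner_prob = 1, rotation = "random",
                           n_px = 160) {
  spec <- phantom_spec(pixel, c(n_px, n_px), psf_sigma_nm = psf,
                       noise = noise, snr = snr, seed = seed)
  np <- render_npc_field(spec, 1, radius_nm, corner_prob, rotation)
  list(stack = np$stack, truth = np$truth,
       center = as.numeric(np$truth$npcs[1, c("cx_nm", "cy_nm")]))
}

test_that("radial profile peak recovers a sharply imaged ring radius", {
  one <- render_one_npc(53.5, psf = 5)
  rp <- radial_profile_radius(one$stack, one$center)
  expect_lt(abs(rp$radius_nm - 53.5), 1)
  # automatic center finding agrees with the provided one
  rp_auto <- radial_profile_radius(one$stack)
  expect_lt(abs(rp_auto$radius_nm - rp$radius_nm), 1)
  # intensity scaling leaves the radius untouched
  sc <- image_stack(7 * one$stack$voxels, one$stack$pixel_size_nm)
  expect_equal(radial_profile_radius(sc, one$center)$radius_nm,
               rp$radius_nm, tolerance = 1e-9)
})

test_that("a point source has no interior radial peak", {
  spec <- phantom_spec(2, c(96, 96), psf_sigma_nm = 10, noise = "none",
                       seed = 2)
  img <- exmqc:::add_spots(array(0, spec$shape), spec$pixel_size_nm,
                           rbind(c(95, 95)), 10)
  st <- image_stack(img, 2)
  expect_error(radial_profile_radius(st, c(95, 95)), "no interior peak")
})

test_that("corner counting is exact, rotation invariant and monotone in threshold", {
  one <- render_one_npc(53.5, psf = 8, rotation = 0)
  cc <- count_corners(one$stack, one$center, 53.5)
  expect_equal(cc$n_corners, 8L)
  expect_true(all(cc$sector_present))
  # rotation invariance: any ring phase yields the same count
  for (rot in seq(0, 42, length.out = 15)) {
    onr <- render_one_npc(53.5, psf = 8, rotation = rot)
    ccr <- count_corners(onr$stack, onr$center, 53.5)
    expect_equal(ccr$n_corners, 8L)
  }
  # monotone non-increasing in threshold, never exceeding 8
  counts <- vapply(c(0.2, 0.6, 0.9, 1.5), function(th)
    count_corners(one$stack, one$center, 53.5, threshold = th)$n_corners,
    integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts <= 8))
  expect_error(count_corners(one$stack, c(-500, -500), 20), "empty annulus")
})

test_that("partially labeled rings are flagged slot by slot", {
  pat <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  one <- render_one_npc(53.5, psf = 8, rotation = 10,
                        corner_prob = as.numeric(pat), seed = 3)
  # with probabilities 0/1 the rendered corner set equals the pattern
  expect_equal(one$truth$corners$present, pat)
  cc <- count_corners(one$stack, one$center, 53.5)
  expect_equal(cc$n_corners, sum(pat))
  # the flagged sectors must point at the true corner angles
  true_ang <- sort(one$truth$corners$angle_deg[pat] %% 360)
  got_ang <- sort(cc$sector_angle_deg[cc$sector_present])
  expect_true(all(abs(((got_ang - true_ang + 180) %% 360) - 180) < 22.5))
})

test_that("adjacent-corner distances match the chord formula", {
  one <- render_one_npc(53.5, psf = 8, rotation = 17, seed = 4)
  ring <- analyze_npc(one$stack, one$center)
  expect_equal(length(ring$distances_nm), 8L)
  chord <- 2 * 53.5 * sin(pi / 8)
  expect_lt(max(abs(ring$distances_nm - chord)), 2)
  # only opposite corners present: no adjacency, empty result
  opp <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  two <- render_one_npc(53.5, psf = 8, rotation = 5,
                        corner_prob = as.numeric(opp), seed = 5)
  ring2 <- list(center_nm = two$center, radius_nm = 53.5,
                sector_present = opp,
                sector_angle_deg = two$truth$corners$angle_deg)
  expect_length(corner_distances(two$stack, ring2), 0)
})

test_that("population report: statistics, selection rule, histogram", {
  mk_ring <- function(radius, ncor, dists = numeric(0))
    structure(list(radius_nm = radius, n_corners = ncor,
                   distances_nm = dists), class = "npc_ring")
  rep1 <- npc_population_report(list(mk_ring(50, 8, c(40, 42)),
                                     mk_ring(55, 5), mk_ring(60, 6),
                                     mk_ring(90, 2)))
  # the 2-corner ring is excluded from radius stats but kept in the histogram
  expect_equal(rep1$radius_mean_nm, 55)
  expect_equal(rep1$radius_median_nm, 55)
  expect_equal(rep1$n_radius, 3L)
  expect_equal(sum(rep1$corner_histogram), 4)
  expect_equal(unname(rep1$corner_histogram[as.character(2)]), 1)
  expect_equal(rep1$distance_mean_nm, 41)
  expect_equal(rep1$n_distances, 2L)
})

test_that("corner-count histogram of a labeled population is binomial", {
  spec <- phantom_spec(4, c(1024, 1024), psf_sigma_nm = 8, noise = "none",
                       seed = 29)
  np <- render_npc_field(spec, 60, 53.5, corner_prob = 0.8)
  counts <- integer(0)
  for (i in seq_len(nrow(np$truth$npcs))) {
    cen <- as.numeric(np$truth$npcs[i, c("cx_nm", "cy_nm")])
    cr <- crop_stack(np$stack, cen, 110)
    cc <- count_corners(cr$stack, cen - cr$origin_nm, 53.5)
    counts <- c(counts, cc$n_corners)
  }
  # noiseless rendering: measured counts equal the generated corner sets
  truth_counts <- tapply(np$truth$corners$present, np$truth$corners$npc, sum)
  expect_equal(as.integer(counts), as.integer(truth_counts))
  # and the generated sets are Binomial(8, 0.8)
  obs <- table(factor(counts, levels = 0:8))
  p <- stats::dbinom(0:8, 8, 0.8)
  suppressWarnings(chi <- stats::chisq.test(obs, p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("ring detection finds phantom rings in a field", {
  spec <- phantom_spec(4, c(512, 512), psf_sigma_nm = 10, noise = "none",
                       seed = 33)
  np <- render_npc_field(spec, 4, 53.5)
  pts <- detect_rings(np$stack, 53.5)
  expect_equal(nrow(pts), 4L)
  tr <- as.matrix(np$truth$npcs[, c("cx_nm", "cy_nm")])
  dmin <- apply(tr, 1, function(p)
    min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)))
  expect_true(all(dmin < 25))
})
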