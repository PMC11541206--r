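#' Ring radius from an azimuthally averaged radial profile
#'
#' Measures a nuclear-pore-style ring: starting from a coarse center (or
#' the intensity-weighted centroid of the thresholded neighborhood), the
#' center is refined by intensity-weighted centroid-of-annulus iteration,
#' the intensity is averaged over annuli, and the ring radius is the
#' parabolic-interpolated peak of that radial profile in biological nm.
#' A profile whose maximum sits in the innermost bin (no interior peak —
#' e.g. a point source at the center) is an error.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param center_nm approximate ring center (biological nm); `NULL` uses
#'   the thresholded-intensity centroid of the whole image.
#' @param max_radius_nm profile extent.
#' @param bin_nm annulus width; default = pixel size.
#' @param refine_rounds centroid-of-annulus refinement iterations.
#' @return list: `radius_nm`, `center_nm` (refined), `curve` (data.frame
#'   `radius_nm`, `intensity`, `n_pix`).
#' @export
radial_profile_radius <- function(stack, center_nm = NULL,
                                  max_radius_nm = 120, bin_nm = NULL,
                                  refine_rounds = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (length(dim(v)) != 2L) stop("expects a 2D plane")
  px <- bio_pixel_size(stack)
  if (is.null(bin_nm)) bin_nm <- min(px)
  xs <- (seq_len(nrow(v)) - 1) * px[1]
  ys <- (seq_len(ncol(v)) - 1) * px[2]
  if (is.null(center_nm)) {
    thr <- stats::quantile(v, 0.75)
    w <- pmax(v - thr, 0)
    if (sum(w) == 0) stop("no signal above threshold to locate a center")
    center_nm <- c(sum(outer(xs, rep(1, ncol(v))) * w),
                   sum(outer(rep(1, nrow(v)), ys) * w)) / sum(w)
  }
  profile_at <- function(cen) {
    DX <- outer(xs - cen[1], rep(1, ncol(v)))
    DY <- outer(rep(1, nrow(v)), ys - cen[2])
    dd <- sqrt(DX^2 + DY^2)
    keep <- dd <= max_radius_nm
    sh <- shell_index(dd[keep], bin_nm)
    nshell <- as.integer(ceiling(max_radius_nm / bin_nm))
    f <- factor(sh, levels = seq_len(nshell))
    list(mean = as.vector(tapply(v[keep], f, mean)),
         n = as.vector(table(f)),
         r = (seq_len(nshell) - 0.5) * bin_nm,
         dd = dd, keep = keep)
  }
  for (round in seq_len(refine_rounds + 1L)) {
    pr <- profile_at(center_nm)
    ok <- !is.na(pr$mean)
    ipk <- which.max(ifelse(ok, pr$mean, -Inf))
    if (round > refine_rounds) break
    # centroid of the peak annulus, intensity weighted
    r0 <- pr$r[ipk]
    ann <- pr$dd >= r0 - 2 * bin_nm & pr$dd <= r0 + 2 * bin_nm
    w <- pmax(v, 0) * ann
    if (sum(w) == 0) break
    center_nm <- c(sum(outer(xs, rep(1, ncol(v))) * w),
                   sum(outer(rep(1, nrow(v)), ys) * w)) / sum(w)
  }
  if (ipk <= 1L)
    stop("radial profile has no interior peak (no ring at this center)")
  radius <- parabolic_peak(pr$r, ifelse(ok, pr$mean, 0), ipk)
  list(radius_nm = radius, center_nm = center_nm,
       curve = data.frame(radius_nm = pr$r, intensity = pr$mean,
                          n_pix = pr$n))
}

#' Count labeled corners of an eightfold-symmetric ring
#'
#' The Counting Corners rule: intensity is collected in an annulus from
#' `alpha * radius` to `radius / alpha`, divided into eight 45-degree
#' sectors; a sector counts as a visible corner when its peak intensity,
#' normalized to the brightest point of the annulus, exceeds `threshold`.
#' The rotation of the sector partition is set from the 8th circular
#' harmonic of the annulus' azimuthal intensity profile, so sector centers
#' land on the eightfold corner lattice: corners are never split across a
#' sector boundary, and the count is rotation invariant by construction.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param center_nm ring center (biological nm).
#' @param radius_nm ring radius (from [radial_profile_radius()]).
#' @param alpha annulus shape parameter (inner/outer radius scaling).
#' @param threshold normalized sector-signal threshold.
#' @return list: `n_corners`, `sector_present` (logical, 8),
#'   `sector_angle_deg` (sector centers at the chosen phase),
#'   `sector_signal` (normalized), `phase_deg`.
#' @export
count_corners <- function(stack, center_nm, radius_nm, alpha = 0.93,
                          threshold = 0.6) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  px <- bio_pixel_size(stack)
  xs <- (seq_len(nrow(v)) - 1) * px[1] - center_nm[1]
  ys <- (seq_len(ncol(v)) - 1) * px[2] - center_nm[2]
  DX <- outer(xs, rep(1, ncol(v)))
  DY <- outer(rep(1, nrow(v)), ys)
  dd <- sqrt(DX^2 + DY^2)
  inside <- dd >= alpha * radius_nm & dd <= radius_nm / alpha
  if (!any(inside)) stop("empty annulus")
  ang <- (atan2(DY[inside], DX[inside]) * 180 / pi) %% 360
  val <- v[inside]
  gmax <- max(val)
  if (gmax <= 0) stop("annulus carries no signal")
  # azimuthal intensity profile of the annulus (radially averaged,
  # circularly smoothed): the basis for both the sector alignment and the
  # per-corner direction refinement
  nb <- 180L
  bin <- floor(ang / (360 / nb)) %% nb + 1L
  aprof <- as.vector(tapply(val, factor(bin, levels = seq_len(nb)), mean))
  aprof[is.na(aprof)] <- 0
  aprof_s <- aprof
  for (h in c(-2L, -1L, 1L, 2L))
    aprof_s <- aprof_s + aprof[(seq_len(nb) + h - 1L) %% nb + 1L]
  aprof_s <- aprof_s / 5
  bin_ang <- (seq_len(nb) - 0.5) * (360 / nb)
  base <- min(aprof_s)
  # sector alignment from the 8th circular harmonic: sector centers land
  # on the eightfold corner lattice, so a corner is never split across a
  # boundary (which would double-count it); rotation invariant by
  # construction
  zz <- sum(pmax(aprof_s - base, 0) * exp(1i * 8 * bin_ang * pi / 180))
  phi0 <- ((Arg(zz) * 180 / pi) / 8) %% 45
  phase <- (phi0 - 22.5) %% 45
  sec <- floor(((ang - phase) %% 360) / 45) + 1L
  smax <- vapply(1:8, function(k) {
    x <- val[sec == k]
    if (length(x) == 0) 0 else max(x)
  }, numeric(1))
  norm <- smax / gmax
  pres <- norm >= threshold
  refine_at <- function(th0) {
    near <- which(abs(((bin_ang - th0 + 180) %% 360) - 180) <= 14)
    w <- pmax(aprof_s[near] - base, 0)^2
    if (sum(w) == 0) return(th0 %% 360)
    th <- bin_ang[near] * pi / 180
    (atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi) %% 360
  }
  lat <- (phi0 + 45 * (0:7)) %% 360
  # order lattice angles by the sector that contains them
  ord <- order(((lat - phase) %% 360))
  corner_angle <- vapply(lat[ord], refine_at, numeric(1))
  list(n_corners = sum(pres), sector_present = pres,
       sector_angle_deg = (phase + 45 * (0:7) + 22.5) %% 360,
       corner_angle_deg = corner_angle,
       sector_signal = norm, phase_deg = phase)
}

#' Adjacent-corner distances by line-profile two-peak fitting
#'
#' For every adjacent pair of corners flagged present, a line intensity
#' profile is taken through the two corner positions (the refined
#' intensity-weighted corner directions on the ring, emulating a line
#' selection drawn through the visible corners) and the distance between
#' its two peaks is measured with the double-Gaussian fit — the same
#' estimator used for microtubule sidewalls. Fewer than two adjacent
#' present corners yields an empty result.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param ring result of [analyze_npc()] (or a list with `center_nm`,
#'   `radius_nm`, `sector_present`, `sector_angle_deg`).
#' @param margin_nm profile extension beyond each corner.
#' @param width_nm averaging width of the line profile.
#' @return numeric vector of corner-to-corner distances (nm), one per
#'   converged adjacent-pair fit.
#' @export
corner_distances <- function(stack, ring, margin_nm = 30, width_nm = 10) {
  pres <- ring$sector_present
  angs <- ring$corner_angle_deg %||% ring$sector_angle_deg
  out <- numeric(0)
  for (k in 1:8) {
    k2 <- if (k == 8) 1L else k + 1L
    if (!(pres[k] && pres[k2])) next
    a1 <- angs[k] * pi / 180; a2 <- angs[k2] * pi / 180
    p1 <- ring$center_nm + ring$radius_nm * c(cos(a1), sin(a1))
    p2 <- ring$center_nm + ring$radius_nm * c(cos(a2), sin(a2))
    chord <- sqrt(sum((p2 - p1)^2))
    mid <- (p1 + p2) / 2
    angle <- atan2(p2[2] - p1[2], p2[1] - p1[1]) * 180 / pi
    box <- profile_box(mid[1], mid[2], angle, chord + 2 * margin_nm,
                       width_nm)
    prof <- tryCatch(extract_profile(stack, box), error = function(e) NULL)
    if (is.null(prof)) next
    fit <- fit_double_gaussian(prof)
    if (isTRUE(fit$converged)) out <- c(out, fit$peak_to_peak_nm)
  }
  out
}

#' Analyze one NPC ring: radius, corners, adjacent-corner distances
#'
#' Convenience wrapper chaining [radial_profile_radius()],
#' [count_corners()] and [corner_distances()].
#'
#' @param stack a 2D single-channel [image_stack].
#' @param center_nm approximate ring center.
#' @param alpha,threshold Counting Corners parameters.
#' @param max_radius_nm radial profile extent.
#' @param measure_distances also measure adjacent-corner distances.
#' @return object of class `npc_ring`.
#' @export
analyze_npc <- function(stack, center_nm = NULL, alpha = 0.93,
                        threshold = 0.6, max_radius_nm = 120,
                        measure_distances = TRUE) {
  rp <- radial_profile_radius(stack, center_nm, max_radius_nm)
  cc <- count_corners(stack, rp$center_nm, rp$radius_nm, alpha, threshold)
  ring <- structure(c(rp[c("radius_nm", "center_nm", "curve")], cc,
                      list(alpha = alpha, threshold = threshold)),
                    class = "npc_ring")
  ring$distances_nm <- if (measure_distances)
    corner_distances(stack, ring) else numeric(0)
  ring
}

#' @export
print.npc_ring <- function(x, ...) {
  cat(sprintf("<npc_ring> radius %.1f nm, %d/8 corners", x$radius_nm,
              x$n_corners))
  if (length(x$distances_nm))
    cat(sprintf(", adjacent-corner distance %.1f nm (mean of %d)",
                mean(x$distances_nm), length(x$distances_nm)))
  cat("\n")
  invisible(x)
}

#' Population summary of NPC rings
#'
#' Radius statistics include only rings with at least `min_corners` visible
#' corners (the standard top-view selection rule); the corner-count
#' histogram includes every ring; distance statistics pool all measured
#' adjacent-corner distances.
#'
#' @param rings list of `npc_ring` objects.
#' @param min_corners radius-statistics inclusion threshold.
#' @return list with `n_rings`, `radius_mean_nm`, `radius_median_nm`,
#'   `radius_sd_nm`, `n_radius`, `corner_histogram` (counts for 0..8),
#'   `distance_mean_nm`, `distance_median_nm`, `distance_sd_nm`,
#'   `n_distances`.
#' @export
npc_population_report <- function(rings, min_corners = 4L) {
  if (inherits(rings, "npc_ring")) rings <- list(rings)
  if (length(rings) == 0) stop("no rings")
  radii <- vapply(rings, `[[`, numeric(1), "radius_nm")
  ncor <- vapply(rings, `[[`, numeric(1), "n_corners")
  dist <- unlist(lapply(rings, function(r) r$distances_nm %||% numeric(0)))
  sel <- ncor >= min_corners
  hist <- table(factor(ncor, levels = 0:8))
  list(n_rings = length(rings),
       radius_mean_nm = if (any(sel)) mean(radii[sel]) else NA_real_,
       radius_median_nm = if (any(sel)) stats::median(radii[sel]) else NA_real_,
       radius_sd_nm = if (sum(sel) > 1) stats::sd(radii[sel]) else 0,
       n_radius = sum(sel),
       corner_histogram = hist,
       distance_mean_nm = if (length(dist)) mean(dist) else NA_real_,
       distance_median_nm = if (length(dist)) stats::median(dist) else NA_real_,
       distance_sd_nm = if (length(dist) > 1) stats::sd(dist) else 0,
       n_distances = length(dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect candidate ring centers in a full field
#'
#' Blob detection at the expected ring scale: the image is smoothed to the
#' ring's outer radius and local maxima above a relative threshold, at
#' least one ring diameter apart, are returned as candidate centers. A
#' manually curated center list can always be supplied downstream instead.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param radius_nm expected ring radius.
#' @param rel_threshold minimum peak height relative to the global maximum.
#' @return matrix of candidate centers (nm), one row each.
#' @export
detect_rings <- function(stack, radius_nm = 53.5, rel_threshold = 0.3) {
  stopifnot(inherits(stack, "image_stack"))
  px <- bio_pixel_size(stack)
  sm <- gauss_smooth2d(stack$voxels, radius_nm / min(px) / 1.5)
  nx <- nrow(sm); ny <- ncol(sm)
  thr <- rel_threshold * max(sm)
  cand <- which(sm > thr)
  ci <- arrayInd(cand, dim(sm))
  r_px <- as.integer(ceiling(radius_nm / min(px)))
  is_max <- vapply(seq_len(nrow(ci)), function(r) {
    i <- ci[r, 1]; j <- ci[r, 2]
    nb <- sm[max(1, i - r_px):min(nx, i + r_px),
             max(1, j - r_px):min(ny, j + r_px)]
    sm[i, j] >= max(nb)
  }, logical(1))
  pts <- ci[is_max, , drop = FALSE]
  cbind(x_nm = (pts[, 1] - 1) * px[1], y_nm = (pts[, 2] - 1) * px[2])
}
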