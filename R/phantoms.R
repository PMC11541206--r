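#' Phantom rendering specification
#'
#' Describes the grid, optics and noise of a synthetic image. Coordinates and
#' pixel sizes of phantoms are in *biological* nm (the scale of the original
#' specimen); rendered stacks carry `expansion_factor = 1` so physical and
#' biological units coincide, and a unit-consistency property guarantees that
#' rescaling both by a common expansion factor leaves every nm-valued
#' estimate unchanged.
#'
#' The PSF is an isotropic Gaussian of width `psf_sigma_nm` — the standard
#' confocal approximation; the default 15 nm corresponds to a ~300 nm optical
#' sigma divided by a 20x expansion factor. Emitters are rendered by analytic
#' Gaussian evaluation on the grid (not by binning then blurring), which
#' avoids quantization bias at 2-5 nm pixel sizes.
#'
#' @param pixel_size_nm sampling in biological nm (scalar or per axis).
#' @param shape voxel counts per axis, length 2 or 3.
#' @param psf_sigma_nm isotropic Gaussian PSF sigma in biological nm.
#' @param noise one of `"none"`, `"gaussian"` (additive, s.d. = peak/`snr`) or
#'   `"poisson"` (image scaled so its maximum is `peak_counts`, Poisson drawn,
#'   scaled back).
#' @param snr peak-signal-to-noise ratio for `"gaussian"` noise.
#' @param peak_counts expected photon count at the brightest voxel for
#'   `"poisson"` noise.
#' @param seed integer; fully determines the phantom (per-structure RNG
#'   streams are split deterministically from it).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(pixel_size_nm, shape, psf_sigma_nm = 15,
                         noise = c("none", "gaussian", "poisson"),
                         snr = 10, peak_counts = 200, seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L || any(shape < 1L))
    stop("'shape' must give 2 or 3 positive voxel counts")
  pixel_size_nm <- rep_len(as.numeric(pixel_size_nm), length(shape))
  if (any(pixel_size_nm <= 0)) stop("pixel_size_nm must be > 0")
  if (psf_sigma_nm < 0) stop("psf_sigma_nm must be >= 0")
  structure(list(pixel_size_nm = pixel_size_nm, shape = shape,
                 psf_sigma_nm = psf_sigma_nm, noise = noise, snr = snr,
                 peak_counts = peak_counts, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Apply the spec's noise model to a clean array. Uses the current RNG state
# (callers seed a deterministic sub-stream first).
apply_noise <- function(v, spec) {
  switch(spec$noise,
    none = v,
    gaussian = {
      peak <- max(v)
      if (peak <= 0) return(v)
      v + stats::rnorm(length(v), sd = peak / spec$snr)
    },
    poisson = {
      peak <- max(v)
      if (peak <= 0) return(v)
      scale <- spec$peak_counts / peak
      out <- stats::rpois(length(v), lambda = pmax(v, 0) * scale) / scale
      array(out, dim(v))
    })
}

# Add isotropic Gaussian spots (peak amplitude `amp`) at nm coordinates
# `centers` (matrix, one row per spot) to a 2D or 3D array. Separable
# analytic evaluation over a +/- 6 sigma window.
add_spots <- function(img, px, centers, sigma_nm, amp = 1) {
  if (NROW(centers) == 0) return(img)
  centers <- matrix(centers, ncol = length(px))
  amp <- rep_len(amp, nrow(centers))
  d <- dim(img)
  for (s in seq_len(nrow(centers))) {
    ax <- vector("list", length(px))
    ok <- TRUE
    for (a in seq_along(px)) {
      c_a <- centers[s, a]
      lo <- max(1L, floor((c_a - 6 * sigma_nm) / px[a]) + 1L)
      hi <- min(d[a], ceiling((c_a + 6 * sigma_nm) / px[a]) + 1L)
      if (lo > hi) { ok <- FALSE; break }
      idx <- lo:hi
      ax[[a]] <- list(idx = idx,
                      g = exp(-((idx - 1) * px[a] - c_a)^2 / (2 * sigma_nm^2)))
    }
    if (!ok) next
    if (length(px) == 2L) {
      blk <- amp[s] * outer(ax[[1]]$g, ax[[2]]$g)
      img[ax[[1]]$idx, ax[[2]]$idx] <-
        img[ax[[1]]$idx, ax[[2]]$idx] + blk
    } else {
      blk <- amp[s] * outer(outer(ax[[1]]$g, ax[[2]]$g), ax[[3]]$g)
      img[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] <-
        img[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] + blk
    }
  }
  img
}

# Add a PSF-convolved finite line source between nm points p0 and p1 to a 2D
# image: Gaussian in the transverse direction, erf-smoothed caps along the
# line.
add_line <- function(img, px, p0, p1, sigma_nm, amp = 1) {
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) return(add_spots(img, px, rbind(p0), sigma_nm, amp))
  dvec <- (p1 - p0) / L
  lo <- pmin(p0, p1) - 6 * sigma_nm
  hi <- pmax(p0, p1) + 6 * sigma_nm
  i0 <- max(1L, floor(lo[1] / px[1]) + 1L); i1 <- min(nrow(img), ceiling(hi[1] / px[1]) + 1L)
  j0 <- max(1L, floor(lo[2] / px[2]) + 1L); j1 <- min(ncol(img), ceiling(hi[2] / px[2]) + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  xs <- ((i0:i1) - 1) * px[1] - p0[1]
  ys <- ((j0:j1) - 1) * px[2] - p0[2]
  X <- outer(xs, rep(1, length(ys)))
  Y <- outer(rep(1, length(xs)), ys)
  tpar <- X * dvec[1] + Y * dvec[2]
  dperp <- -X * dvec[2] + Y * dvec[1]
  val <- amp * exp(-dperp^2 / (2 * sigma_nm^2)) * 0.5 *
    (stats::pnorm(tpar / sigma_nm) - stats::pnorm((tpar - L) / sigma_nm))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + val
  img
}

# Non-overlapping tile centers (nm) for laying out n structures on the grid,
# keeping a margin from image edges. Errors when tiles get too small.
tile_centers <- function(spec, n, min_tile_nm) {
  ext <- (spec$shape[1:2] - 1) * spec$pixel_size_nm[1:2]
  ntx <- max(1L, floor(ext[1] / min_tile_nm))
  nty <- max(1L, floor(ext[2] / min_tile_nm))
  if (ntx * nty < n)
    stop("image too small: cannot place ", n, " structures of extent ",
         min_tile_nm, " nm on a ", ext[1], " x ", ext[2], " nm field")
  tw <- ext[1] / ntx; th <- ext[2] / nty
  k <- seq_len(n) - 1L
  cbind(x = (k %% ntx + 0.5) * tw, y = (k %/% ntx + 0.5) * th)
}

empty_image <- function(spec) array(0, spec$shape)

#' Render a field of synthetic microtubule segments
#'
#' Each segment is a pair of parallel line sources (the immunolabeled
#' sidewalls) separated by `separation_nm`, convolved with the Gaussian PSF
#' and subjected to the spec's noise model. The ground truth records each
#' segment's center, axis direction and separation, which drives the
#' parameter-recovery tests of the transverse-profile pipeline.
#'
#' @param spec a [phantom_spec] (2D shape).
#' @param n_segments number of segments.
#' @param separation_nm sidewall peak separation (ground truth), nm.
#' @param orientation_policy `"random"` (uniform in \[0, 180)), or a fixed
#'   angle in degrees.
#' @param segment_length_nm length of each segment, nm.
#' @return list with `stack` ([image_stack]) and `truth` (data.frame with
#'   one row per segment: `cx_nm, cy_nm, angle_deg, separation_nm,
#'   length_nm`).
#' @export
render_microtubules <- function(spec, n_segments, separation_nm,
                                orientation_policy = "random",
                                segment_length_nm = 500) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$shape) == 2L)
  if (separation_nm <= 2 * max(spec$pixel_size_nm))
    stop("separation ", separation_nm,
         " nm is below the Nyquist limit for pixel size ",
         max(spec$pixel_size_nm), " nm")
  truth <- data.frame(segment = integer(0), cx_nm = numeric(0),
                      cy_nm = numeric(0), angle_deg = numeric(0),
                      separation_nm = numeric(0), length_nm = numeric(0))
  img <- empty_image(spec)
  if (n_segments > 0) {
    min_tile <- segment_length_nm + separation_nm + 14 * spec$psf_sigma_nm
    ctr <- tile_centers(spec, n_segments, min_tile)
    for (s in seq_len(n_segments)) {
      set.seed(sub_seed(spec$seed, s))
      ang <- if (identical(orientation_policy, "random"))
        stats::runif(1, 0, 180) else as.numeric(orientation_policy)
      th <- ang * pi / 180
      dvec <- c(cos(th), sin(th))
      nvec <- c(-sin(th), cos(th))
      cen <- ctr[s, ] + stats::runif(2, -0.05, 0.05) * min_tile
      half <- segment_length_nm / 2
      for (side in c(-0.5, 0.5)) {
        off <- cen + side * separation_nm * nvec
        img <- add_line(img, spec$pixel_size_nm, off - half * dvec,
                        off + half * dvec, spec$psf_sigma_nm)
      }
      truth[s, ] <- list(s, cen[1], cen[2], ang, separation_nm,
                         segment_length_nm)
    }
    set.seed(sub_seed(spec$seed, 0L))
    img <- array(apply_noise(img, spec), dim(img))
  }
  list(stack = image_stack(img, spec$pixel_size_nm),
       truth = truth)
}

#' Render a field of synthetic nuclear pore complex rings
#'
#' Each NPC is eight point emitters equally spaced on a circle of radius
#' `radius_nm`, each corner present with its slot's labeling probability,
#' blurred by the PSF. The ring phase (rotation of the corner positions) is
#' drawn uniformly per NPC unless fixed.
#'
#' @param spec a [phantom_spec] (2D shape).
#' @param n_npcs number of rings.
#' @param radius_nm ring radius (ground truth), nm.
#' @param corner_prob per-slot labeling probability; scalar or length 8.
#' @param ring_rotation `"random"` or a fixed phase in degrees.
#' @return list with `stack`, and `truth` containing `npcs` (center, radius,
#'   rotation per ring) and `corners` (per slot: angle, position, present
#'   flag).
#' @export
render_npc_field <- function(spec, n_npcs, radius_nm = 53.5,
                             corner_prob = 1, ring_rotation = "random") {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$shape) == 2L)
  if (radius_nm <= 0) stop("radius_nm must be > 0")
  corner_prob <- rep_len(corner_prob, 8L)
  img <- empty_image(spec)
  npcs <- data.frame(npc = integer(0), cx_nm = numeric(0), cy_nm = numeric(0),
                     radius_nm = numeric(0), rotation_deg = numeric(0))
  corners <- data.frame(npc = integer(0), slot = integer(0),
                        angle_deg = numeric(0), x_nm = numeric(0),
                        y_nm = numeric(0), present = logical(0))
  if (n_npcs > 0) {
    min_tile <- 2 * radius_nm + 14 * spec$psf_sigma_nm
    ctr <- tile_centers(spec, n_npcs, min_tile)
    for (s in seq_len(n_npcs)) {
      set.seed(sub_seed(spec$seed, s))
      rot <- if (identical(ring_rotation, "random"))
        stats::runif(1, 0, 45) else as.numeric(ring_rotation)
      present <- stats::runif(8) < corner_prob
      ang <- rot + 45 * (0:7)
      cen <- ctr[s, ] + stats::runif(2, -0.1, 0.1) * radius_nm
      px_nm <- cen[1] + radius_nm * cos(ang * pi / 180)
      py_nm <- cen[2] + radius_nm * sin(ang * pi / 180)
      img <- add_spots(img, spec$pixel_size_nm,
                       cbind(px_nm, py_nm)[present, , drop = FALSE],
                       spec$psf_sigma_nm)
      npcs[s, ] <- list(s, cen[1], cen[2], radius_nm, rot)
      corners <- rbind(corners, data.frame(
        npc = s, slot = 1:8, angle_deg = ang, x_nm = px_nm, y_nm = py_nm,
        present = present))
    }
    set.seed(sub_seed(spec$seed, 0L))
    img <- array(apply_noise(img, spec), dim(img))
  }
  list(stack = image_stack(img, spec$pixel_size_nm),
       truth = list(npcs = npcs, corners = corners))
}

#' Render a two-channel synaptic cluster phantom
#'
#' Emulates juxtaposed presynaptic/postsynaptic protein clusters: per
#' synapse, a disc-like cluster envelope is rendered in each channel,
#' separated by `cleft_nm` along a random axis; inside each cluster,
#' `n_nanodomains` Gaussian hotspots of FWHM `nanodomain_size_nm` are placed,
#' and the measured-channel hotspots are displaced laterally (perpendicular
#' to the cleft axis) from the reference-channel hotspots by
#' `trans_offset_nm`. Both channels are rendered on identical grids.
#'
#' The envelope is either `"soft"` (Gaussian falloff) or `"uniform"` (sharp
#' ellipsoid indicator, rendered without PSF blur so its interior is exactly
#' flat — the degenerate case for which the autocorrelation baseline is 1).
#'
#' @param spec a [phantom_spec] (3D shape).
#' @param n_synapses number of synapse pairs.
#' @param nanodomain_size_nm hotspot FWHM, nm.
#' @param n_nanodomains hotspots per cluster (0 = envelope only).
#' @param trans_offset_nm lateral displacement of measured-channel hotspots.
#' @param cleft_nm separation between the two clusters' centers.
#' @param cluster_radius_nm in-plane cluster radius scale.
#' @param cluster_thickness_nm axial cluster half-thickness scale.
#' @param envelope `"soft"` or `"uniform"`.
#' @return list with `stack` (4-D voxels, channels `reference`, `measured`)
#'   and `truth` (synapse table plus per-hotspot centers by channel).
#' @export
render_synapse_pair <- function(spec, n_synapses, nanodomain_size_nm = 60,
                                n_nanodomains = 2, trans_offset_nm = 0,
                                cleft_nm = 50, cluster_radius_nm = 120,
                                cluster_thickness_nm = 50,
                                envelope = c("soft", "uniform")) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$shape) == 3L)
  envelope <- match.arg(envelope)
  if (nanodomain_size_nm <= 0) stop("nanodomain_size_nm must be > 0")
  if (nanodomain_size_nm > 2 * cluster_radius_nm)
    stop("nanodomain (", nanodomain_size_nm,
         " nm) larger than the cluster it must fit in")
  px <- spec$pixel_size_nm
  ext <- (spec$shape - 1) * px
  ch <- array(0, c(spec$shape, 2L))
  syn <- data.frame(synapse = integer(0), cx_nm = numeric(0),
                    cy_nm = numeric(0), cz_nm = numeric(0),
                    ax = numeric(0), ay = numeric(0), az = numeric(0))
  hot <- data.frame(synapse = integer(0), channel = character(0),
                    domain = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                    z_nm = numeric(0))
  if (n_synapses > 0) {
    min_tile <- 2 * (cluster_radius_nm + cleft_nm) + 10 * spec$psf_sigma_nm
    ctr <- tile_centers(spec, n_synapses, min_tile)
    sig_nd <- nanodomain_size_nm / (2 * sqrt(2 * log(2)))
    sig_eff <- sqrt(sig_nd^2 + spec$psf_sigma_nm^2)
    for (s in seq_len(n_synapses)) {
      set.seed(sub_seed(spec$seed, s))
      # cleft axis: random unit vector, moderate z-component so both
      # clusters stay well inside the (thin) z extent
      axv <- c(stats::rnorm(2), 0.3 * stats::rnorm(1))
      axv <- axv / sqrt(sum(axv^2))
      cen <- c(ctr[s, ], ext[3] / 2)
      # orthonormal in-plane basis perpendicular to the axis
      e1 <- c(-axv[2], axv[1], 0); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(axv[2] * e1[3] - axv[3] * e1[2],
              axv[3] * e1[1] - axv[1] * e1[3],
              axv[1] * e1[2] - axv[2] * e1[1])
      cen_ref <- cen - axv * cleft_nm / 2
      cen_mea <- cen + axv * cleft_nm / 2
      for (ci in 1:2) {
        cc <- if (ci == 1) cen_ref else cen_mea
        ch[, , , ci] <- add_envelope(ch[, , , ci], px, cc, axv,
                                     cluster_radius_nm, cluster_thickness_nm,
                                     envelope)
      }
      if (n_nanodomains > 0) {
        rr <- 0.6 * cluster_radius_nm * sqrt(stats::runif(n_nanodomains))
        th <- stats::runif(n_nanodomains, 0, 2 * pi)
        for (d in seq_len(n_nanodomains)) {
          inplane <- rr[d] * (cos(th[d]) * e1 + sin(th[d]) * e2)
          p_ref <- cen_ref + inplane
          phi <- stats::runif(1, 0, 2 * pi)
          lat <- trans_offset_nm * (cos(phi) * e1 + sin(phi) * e2)
          p_mea <- cen_mea + inplane + lat
          ch[, , , 1] <- add_spots(ch[, , , 1], px, rbind(p_ref), sig_eff, 2)
          ch[, , , 2] <- add_spots(ch[, , , 2], px, rbind(p_mea), sig_eff, 2)
          hot <- rbind(hot,
            data.frame(synapse = s, channel = c("reference", "measured"),
                       domain = d,
                       x_nm = c(p_ref[1], p_mea[1]),
                       y_nm = c(p_ref[2], p_mea[2]),
                       z_nm = c(p_ref[3], p_mea[3])))
        }
      }
      syn[s, ] <- list(s, cen[1], cen[2], cen[3], axv[1], axv[2], axv[3])
    }
    for (ci in 1:2) {
      set.seed(sub_seed(spec$seed, -ci))
      ch[, , , ci] <- apply_noise(ch[, , , ci], spec)
    }
  }
  list(stack = image_stack(ch, px, channel_names = c("reference", "measured")),
       truth = list(synapses = syn, hotspots = hot))
}

# Disc-like cluster envelope: Gaussian ("soft") or indicator ("uniform")
# falloff, anisotropic along the cleft axis. Evaluated over a bounding box.
add_envelope <- function(vol, px, center, axis, r_perp, r_ax, kind) {
  d <- dim(vol)
  half <- rep(2.5 * max(r_perp, r_ax), 3)
  lo <- pmax(1L, floor((center - half) / px) + 1L)
  hi <- pmin(d, ceiling((center + half) / px) + 1L)
  if (any(lo > hi)) return(vol)
  xs <- ((lo[1]:hi[1]) - 1) * px[1] - center[1]
  ys <- ((lo[2]:hi[2]) - 1) * px[2] - center[2]
  zs <- ((lo[3]:hi[3]) - 1) * px[3] - center[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  ta <- X * axis[1] + Y * axis[2] + Z * axis[3]
  dp2 <- pmax(0, X^2 + Y^2 + Z^2 - ta^2)
  q <- dp2 / r_perp^2 + ta^2 / r_ax^2
  val <- if (kind == "soft") exp(-q / 2) else (q <= 1) * 1.0
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + val
  vol
}

#' Generate a warped image pair with a known deformation field
#'
#' Renders a texture-rich base image (random point emitters blurred by the
#' PSF), then resamples it through a smooth random displacement field
#' (Gaussian-filtered white noise scaled to an exact RMS magnitude). The
#' field maps coordinates of the warped image to coordinates of the
#' reference, matching the convention of [nonrigid_register()], so the
#' stored truth is directly comparable to a recovered field.
#'
#' @param spec a [phantom_spec] (2D shape).
#' @param amplitude_nm RMS displacement magnitude of the field, nm.
#' @param correlation_length_nm Gaussian correlation length of the field, nm.
#' @param n_points number of random emitters in the base image.
#' @return list with `reference`, `warped` (both [image_stack]) and `truth`
#'   holding `ux_nm`, `uy_nm` displacement matrices.
#' @export
make_warp_pair <- function(spec, amplitude_nm, correlation_length_nm = 200,
                           n_points = 400) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$shape) == 2L)
  if (amplitude_nm < 0) stop("amplitude_nm must be >= 0")
  px <- spec$pixel_size_nm
  ext <- (spec$shape - 1) * px
  margin <- 6 * spec$psf_sigma_nm
  set.seed(sub_seed(spec$seed, 1L))
  pts <- cbind(stats::runif(n_points, margin, ext[1] - margin),
               stats::runif(n_points, margin, ext[2] - margin))
  base <- add_spots(empty_image(spec), px, pts, spec$psf_sigma_nm,
                    amp = stats::runif(n_points, 0.5, 1.5))
  set.seed(sub_seed(spec$seed, 2L))
  if (amplitude_nm > 0) {
    sig_px <- correlation_length_nm / mean(px)
    ux <- gauss_smooth2d(matrix(stats::rnorm(prod(spec$shape)), spec$shape[1]),
                         sig_px)
    uy <- gauss_smooth2d(matrix(stats::rnorm(prod(spec$shape)), spec$shape[1]),
                         sig_px)
    rms <- sqrt(mean(ux^2 + uy^2))
    ux <- ux * amplitude_nm / rms
    uy <- uy * amplitude_nm / rms
  } else {
    ux <- uy <- matrix(0, spec$shape[1], spec$shape[2])
  }
  ij <- expand.grid(i = seq_len(spec$shape[1]), j = seq_len(spec$shape[2]))
  warped <- matrix(
    bilinear_sample(base, ij$i + as.vector(ux) / px[1],
                    ij$j + as.vector(uy) / px[2]),
    spec$shape[1], spec$shape[2])
  set.seed(sub_seed(spec$seed, 3L))
  ref_noisy <- array(apply_noise(base, spec), dim(base))
  set.seed(sub_seed(spec$seed, 4L))
  war_noisy <- array(apply_noise(warped, spec), dim(warped))
  list(reference = image_stack(ref_noisy, px),
       warped = image_stack(war_noisy, px),
       truth = list(ux_nm = ux, uy_nm = uy))
}

#' Generate an independent-noise image pair for FRC
#'
#' Two realizations sharing the same underlying signal and differing only in
#' noise; with `noise = "none"` in the spec the outputs are bit-identical.
#'
#' @param stack a clean single-channel [image_stack] (the shared signal).
#' @param spec a [phantom_spec] supplying the noise model and seed.
#' @return list of two [image_stack]s.
#' @export
make_frc_pair <- function(stack, spec) {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "phantom_spec"))
  out <- vector("list", 2L)
  for (k in 1:2) {
    set.seed(sub_seed(spec$seed, 100L + k))
    v <- apply_noise(stack$voxels, spec)
    out[[k]] <- image_stack(array(v, dim(stack$voxels)),
                            stack$pixel_size_nm, stack$expansion_factor)
  }
  out
}
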