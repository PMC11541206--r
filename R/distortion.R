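#' Deformation field container
#'
#' Per-pixel displacement vectors, in biological nm, mapping coordinates of
#' the rigid-registered post-expansion image to coordinates of the
#' pre-expansion image; the basis of the r.m.s.-error-vs-length curve.
#'
#' @param ux_nm,uy_nm displacement components (matrices, nm).
#' @param valid_mask logical matrix: pixels with reliable correspondence.
#' @param pixel_size_nm biological pixel size of the grid.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(ux_nm, uy_nm, valid_mask = NULL,
                              pixel_size_nm) {
  stopifnot(all(dim(ux_nm) == dim(uy_nm)))
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(ux_nm), ncol(ux_nm))
  structure(list(ux_nm = ux_nm, uy_nm = uy_nm, valid_mask = valid_mask,
                 pixel_size_nm = rep_len(pixel_size_nm, 2)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  m <- sqrt(x$ux_nm^2 + x$uy_nm^2)[x$valid_mask]
  cat(sprintf("<deformation_field> %d x %d px, RMS |u| = %.2f nm (%.0f%% valid)\n",
              nrow(x$ux_nm), ncol(x$ux_nm), sqrt(mean(m^2)),
              100 * mean(x$valid_mask)))
  invisible(x)
}

# Similarity warp: sample `img` at T(x) where T rotates by theta (rad),
# scales by s and translates by (tx, ty) px around the image center.
warp_similarity <- function(img, theta, s, tx, ty) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  dxc <- ij$i - cx; dyc <- ij$j - cy
  xs <- cx + s * (cos(theta) * dxc - sin(theta) * dyc) + tx
  ys <- cy + s * (sin(theta) * dxc + cos(theta) * dyc) + ty
  matrix(bilinear_sample(img, xs, ys), nx, ny)
}

ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid (similarity) pre-registration of a pre/post-expansion pair
#'
#' Replaces the interactive rigid-body step of the classical workflow with
#' an automatic similarity registration: the post-expansion image is first
#' resampled into the pre-expansion biological coordinate frame using the
#' expansion factors, a phase-correlation pass initializes the translation,
#' and Nelder-Mead then maximizes the intensity correlation over
#' translation, rotation and residual isotropic scale. The recovered scale
#' times the nominal factor ratio is itself an expansion-factor estimate.
#'
#' @param pre,post 2D single-channel [image_stack]s.
#' @param min_correlation registration fails (error) below this NCC floor.
#' @return list: `transform` (`theta_deg`, `scale`, `tx_px`, `ty_px`, `ncc`,
#'   `expansion_scale`), and `post_aligned` ([image_stack] on the pre grid).
#' @export
rigid_register <- function(pre, post, min_correlation = 0.1) {
  stopifnot(inherits(pre, "image_stack"), inherits(post, "image_stack"))
  a <- pre$voxels; b <- post$voxels
  if (length(dim(a)) != 2L || length(dim(b)) != 2L)
    stop("rigid_register expects 2D planes")
  pxa <- bio_pixel_size(pre); pxb <- bio_pixel_size(post)
  # resample post onto pre's biological grid
  rel <- pxb[1] / pxa[1]
  if (abs(rel - 1) > 1e-9 || !all(dim(b) == dim(a))) {
    ij <- expand.grid(i = seq_len(nrow(a)), j = seq_len(ncol(a)))
    b <- matrix(bilinear_sample(b, (ij$i - 1) / rel + 1,
                                (ij$j - 1) * (pxa[2] / pxb[2]) + 1),
                nrow(a), ncol(a))
  }
  # phase-correlation translation initialization
  FA <- stats::fft(a); FB <- stats::fft(b)
  cp <- FA * Conj(FB)
  cp <- cp / pmax(Mod(cp), 1e-12)
  cc <- Re(stats::fft(cp, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  tx0 <- if (pk[1] > nrow(a) / 2) pk[1] - nrow(a) else pk[1]
  ty0 <- if (pk[2] > ncol(a) / 2) pk[2] - ncol(a) else pk[2]
  obj <- function(p) {
    w <- warp_similarity(b, p[1], exp(p[2]), p[3], p[4])
    -ncc(a, w)
  }
  opt <- stats::optim(c(0, 0, -tx0, -ty0), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8,
                                     parscale = c(0.02, 0.02, 1, 1)))
  p <- opt$par
  final_ncc <- -opt$value
  if (final_ncc < min_correlation)
    stop(sprintf("rigid registration failed: correlation %.3f below floor %.3f",
                 final_ncc, min_correlation))
  aligned <- warp_similarity(b, p[1], exp(p[2]), p[3], p[4])
  list(transform = list(theta_deg = p[1] * 180 / pi, scale = exp(p[2]),
                        tx_px = p[3], ty_px = p[4], ncc = final_ncc,
                        expansion_scale = rel * exp(p[2]) *
                          post$expansion_factor / pre$expansion_factor),
       post_aligned = image_stack(aligned, pre$pixel_size_nm,
                                  pre$expansion_factor))
}

#' Nonrigid registration by multiresolution block matching
#'
#' Estimates the residual smooth displacement field between a rigidly
#' aligned image pair. Both images are Gaussian presmoothed (sigma 4 px by
#' default, matching the standard distortion-analysis preprocessing); a
#' coarse-to-fine grid of control nodes is then matched by normalized
#' cross-correlation over a local search window with subpixel quadratic
#' refinement, and the node displacements are interpolated to the full grid
#' and Gaussian-regularized. The field maps post-aligned coordinates to pre
#' coordinates: `pre(x + u(x)) ~ post_aligned(x)`.
#'
#' @param pre,post_aligned 2D single-channel [image_stack]s on the same
#'   grid.
#' @param preprocess_sigma_px Gaussian presmoothing sigma (pixels).
#' @param node_spacing_px control-node spacings, coarse to fine.
#' @param min_node_ncc nodes whose best match correlates below this are
#'   marked unreliable.
#' @return a [deformation_field] (nm, biological units).
#' @export
nonrigid_register <- function(pre, post_aligned, preprocess_sigma_px = 4,
                              node_spacing_px = c(32, 16, 8),
                              min_node_ncc = 0.3) {
  stopifnot(inherits(pre, "image_stack"), inherits(post_aligned, "image_stack"))
  a <- pre$voxels; b <- post_aligned$voxels
  if (!all(dim(a) == dim(b))) stop("images must share a grid; rigid-register first")
  px <- bio_pixel_size(pre)
  a <- gauss_smooth2d(a, preprocess_sigma_px)
  b <- gauss_smooth2d(b, preprocess_sigma_px)
  nx <- nrow(a); ny <- ncol(a)
  ux <- matrix(0, nx, ny); uy <- matrix(0, nx, ny)
  vmask <- matrix(FALSE, nx, ny)
  sd_floor <- 0.02 * stats::sd(b)
  for (spacing in node_spacing_px) {
    half <- max(4L, as.integer(round(0.75 * spacing)))   # patch half-size
    search <- max(2L, as.integer(ceiling(spacing / 4)))
    nodes_x <- seq(half + search + 1L, nx - half - search, by = spacing)
    nodes_y <- seq(half + search + 1L, ny - half - search, by = spacing)
    if (length(nodes_x) < 2 || length(nodes_y) < 2) next
    nux <- matrix(NA_real_, length(nodes_x), length(nodes_y))
    nuy <- matrix(NA_real_, length(nodes_x), length(nodes_y))
    for (i in seq_along(nodes_x)) for (j in seq_along(nodes_y)) {
      cxn <- nodes_x[i]; cyn <- nodes_y[j]
      patch <- b[(cxn - half):(cxn + half), (cyn - half):(cyn + half)]
      if (stats::sd(patch) < sd_floor) next
      # current field estimate at the node (integer part)
      u0x <- round(ux[cxn, cyn]); u0y <- round(uy[cxn, cyn])
      best <- -Inf; bx <- 0L; by <- 0L
      scores <- matrix(-Inf, 2L * search + 1L, 2L * search + 1L)
      for (dx in -search:search) for (dy in -search:search) {
        sx <- cxn + u0x + dx; sy <- cyn + u0y + dy
        if (sx - half < 1 || sx + half > nx || sy - half < 1 || sy + half > ny)
          next
        ref <- a[(sx - half):(sx + half), (sy - half):(sy + half)]
        sc <- ncc(patch, ref)
        scores[dx + search + 1L, dy + search + 1L] <- sc
        if (sc > best) { best <- sc; bx <- dx; by <- dy }
      }
      if (!is.finite(best) || best < min_node_ncc) next
      # subpixel refinement: separable quadratic through the score peak
      fx <- 0; fy <- 0
      ib <- bx + search + 1L; jb <- by + search + 1L
      if (ib > 1 && ib < nrow(scores) &&
          all(is.finite(scores[(ib - 1):(ib + 1), jb]))) {
        d2 <- scores[ib - 1, jb] - 2 * scores[ib, jb] + scores[ib + 1, jb]
        if (d2 < 0) fx <- 0.5 * (scores[ib - 1, jb] - scores[ib + 1, jb]) / d2
      }
      if (jb > 1 && jb < ncol(scores) &&
          all(is.finite(scores[ib, (jb - 1):(jb + 1)]))) {
        d2 <- scores[ib, jb - 1] - 2 * scores[ib, jb] + scores[ib, jb + 1]
        if (d2 < 0) fy <- 0.5 * (scores[ib, jb - 1] - scores[ib, jb + 1]) / d2
      }
      nux[i, j] <- u0x + bx + max(-0.5, min(0.5, fx))
      nuy[i, j] <- u0y + by + max(-0.5, min(0.5, fy))
    }
    if (all(is.na(nux))) next
    filled_x <- fill_na(nux); filled_y <- fill_na(nuy)
    ux <- interp_nodes(filled_x, nodes_x, nodes_y, nx, ny)
    uy <- interp_nodes(filled_y, nodes_x, nodes_y, nx, ny)
    ux <- gauss_smooth2d(ux, spacing / 3)
    uy <- gauss_smooth2d(uy, spacing / 3)
    vr <- range(nodes_x); vc <- range(nodes_y)
    vmask[] <- FALSE
    vmask[vr[1]:vr[2], vc[1]:vc[2]] <- TRUE
  }
  if (!any(vmask))
    stop("nonrigid registration found no reliable correspondences")
  deformation_field(ux * px[1], uy * px[2], vmask, px)
}

# Replace NAs in a node grid by the mean of finite neighbors (iterative).
fill_na <- function(m) {
  if (!anyNA(m)) return(m)
  for (it in 1:100) {
    na <- which(is.na(m), arr.ind = TRUE)
    if (nrow(na) == 0) break
    filled <- FALSE
    for (r in seq_len(nrow(na))) {
      i <- na[r, 1]; j <- na[r, 2]
      nb <- m[max(1, i - 1):min(nrow(m), i + 1),
              max(1, j - 1):min(ncol(m), j + 1)]
      nb <- nb[is.finite(nb)]
      if (length(nb) > 0) { m[i, j] <- mean(nb); filled <- TRUE }
    }
    if (!filled) { m[is.na(m)] <- 0; break }
  }
  m
}

# Bilinear interpolation of node values to the full pixel grid, constant
# extrapolation outside the node hull.
interp_nodes <- function(nodevals, nodes_x, nodes_y, nx, ny) {
  xi <- stats::approx(nodes_x, seq_along(nodes_x), xout = seq_len(nx),
                      rule = 2)$y
  yi <- stats::approx(nodes_y, seq_along(nodes_y), xout = seq_len(ny),
                      rule = 2)$y
  ij <- expand.grid(i = xi, j = yi)
  matrix(bilinear_sample(nodevals, ij$i, ij$j), nx, ny)
}

#' r.m.s. measurement error as a function of measurement length
#'
#' For each length L, samples point pairs (p, q) with |p - q| = L uniformly
#' inside the field's valid region and evaluates how the deformation changes
#' their separation: `err = |(q + u(q)) - (p + u(p))| - L`. The r.m.s. of
#' `err` over pairs is the measurement error a distance measurement of
#' length L would suffer from the expansion distortion.
#'
#' @param field a [deformation_field].
#' @param lengths_nm measurement lengths; default log-spaced 100 nm - 10 um,
#'   clipped to the field extent.
#' @param n_samples pairs per length.
#' @param seed RNG seed for pair sampling.
#' @return data.frame of class `rms_curve`: `length_nm, rms_nm, sd_nm, n`.
#' @export
rms_error_curve <- function(field, lengths_nm = NULL, n_samples = 1000,
                            seed = 1L) {
  stopifnot(inherits(field, "deformation_field"))
  px <- field$pixel_size_nm
  ext <- (dim(field$ux_nm) - 1) * px
  if (is.null(lengths_nm))
    lengths_nm <- exp(seq(log(100), log(min(10000, 0.8 * min(ext))),
                          length.out = 12))
  if (any(lengths_nm > min(ext)))
    stop("requested length exceeds the field extent")
  set.seed(seed)
  vm <- field$valid_mask * 1.0
  sample_u <- function(x_nm, y_nm, comp) {
    bilinear_sample(comp, x_nm / px[1] + 1, y_nm / px[2] + 1)
  }
  out <- data.frame(length_nm = lengths_nm, rms_nm = NA_real_,
                    sd_nm = NA_real_, n = NA_integer_)
  for (li in seq_along(lengths_nm)) {
    L <- lengths_nm[li]
    err <- numeric(0)
    tries <- 0L
    while (length(err) < n_samples && tries < 20L) {
      m <- 2L * (n_samples - length(err))
      p1 <- cbind(stats::runif(m, 0, ext[1]), stats::runif(m, 0, ext[2]))
      th <- stats::runif(m, 0, 2 * pi)
      p2 <- p1 + L * cbind(cos(th), sin(th))
      inside <- p2[, 1] >= 0 & p2[, 1] <= ext[1] &
        p2[, 2] >= 0 & p2[, 2] <= ext[2]
      okv <- inside &
        bilinear_sample(vm, p1[, 1] / px[1] + 1, p1[, 2] / px[2] + 1) > 0.5 &
        bilinear_sample(vm, pmax(p2[, 1], 0) / px[1] + 1,
                        pmax(p2[, 2], 0) / px[2] + 1) > 0.5
      if (any(okv)) {
        a <- p1[okv, , drop = FALSE]; b2 <- p2[okv, , drop = FALSE]
        da <- cbind(sample_u(a[, 1], a[, 2], field$ux_nm),
                    sample_u(a[, 1], a[, 2], field$uy_nm))
        db <- cbind(sample_u(b2[, 1], b2[, 2], field$ux_nm),
                    sample_u(b2[, 1], b2[, 2], field$uy_nm))
        d <- (b2 + db) - (a + da)
        err <- c(err, sqrt(rowSums(d^2)) - L)
      }
      tries <- tries + 1L
    }
    if (length(err) < 10)
      stop("insufficient valid pairs at length ", L, " nm")
    err <- err[seq_len(min(length(err), n_samples))]
    out$rms_nm[li] <- sqrt(mean(err^2))
    out$sd_nm[li] <- stats::sd(err)
    out$n[li] <- length(err)
  }
  class(out) <- c("rms_curve", "data.frame")
  out
}

#' @export
plot.rms_curve <- function(x, ...) {
  graphics::plot(x$length_nm, x$rms_nm, type = "b", pch = 16, log = "x",
                 xlab = "measurement length (nm)",
                 ylab = "r.m.s. error (nm)", ...)
  graphics::polygon(c(x$length_nm, rev(x$length_nm)),
                    c(x$rms_nm + x$sd_nm, rev(pmax(x$rms_nm - x$sd_nm, 0))),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
}
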