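#' Define a profile box
#'
#' A rectangular sampling region for transverse intensity profiles: centered
#' at `(cx, cy)` (biological nm), with its *long* axis at `angle_deg`
#' (degrees, 0 = +x) lying perpendicular to the structure of interest and
#' its short axis (width) running along the structure. Intensities are
#' averaged across the width, producing a profile along the long axis.
#'
#' @param cx_nm,cy_nm box center, biological nm.
#' @param angle_deg orientation of the long (profile) axis, degrees.
#' @param length_nm extent along the profile axis.
#' @param width_nm extent averaged over (along the structure); the default
#'   185 nm follows the standard sidewall-averaging window.
#' @return object of class `profile_box`.
#' @export
profile_box <- function(cx_nm, cy_nm, angle_deg, length_nm, width_nm = 185) {
  if (length_nm <= 0 || width_nm <= 0) stop("degenerate box")
  structure(list(cx = cx_nm, cy = cy_nm, angle = angle_deg,
                 length = length_nm, width = width_nm),
            class = "profile_box")
}

#' Extract a box-averaged transverse intensity profile
#'
#' Samples the image by bilinear interpolation on a grid rotated into the
#' box frame, averages across the box width, and normalizes the profile to
#' peak value 1. Sample spacing along the profile axis is the (biological)
#' pixel size unless overridden.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param box a [profile_box] (coordinates in biological nm).
#' @param step_nm sample spacing along the profile; default = pixel size.
#' @param normalize normalize to peak 1 (default `TRUE`).
#' @return object of class `transverse_profile`: `positions_nm` (centered on
#'   the box), `intensities`, and the box.
#' @export
extract_profile <- function(stack, box, step_nm = NULL, normalize = TRUE) {
  stopifnot(inherits(stack, "image_stack"), inherits(box, "profile_box"))
  v <- stack$voxels
  if (length(dim(v)) != 2L) stop("extract_profile expects a 2D stack")
  px <- bio_pixel_size(stack)
  if (is.null(step_nm)) step_nm <- min(px)
  th <- box$angle * pi / 180
  dvec <- c(cos(th), sin(th))          # long (profile) axis
  wvec <- c(-sin(th), cos(th))         # short (averaging) axis
  # symmetric sample grids about the box center, whatever the step
  nt <- floor(box$length / step_nm)
  tpos <- (0:nt - nt / 2) * step_nm
  nw <- floor(box$width / min(px))
  wpos <- (0:nw - nw / 2) * min(px)
  # all sample points: outer sum of the two axes
  Xs <- box$cx + outer(tpos * dvec[1], wpos * wvec[1], `+`)
  Ys <- box$cy + outer(tpos * dvec[2], wpos * wvec[2], `+`)
  xi <- Xs / px[1] + 1
  yi <- Ys / px[2] + 1
  nx <- nrow(v); ny <- ncol(v)
  if (any(xi < 1 - 1e-6) || any(xi > nx + 1e-6) ||
      any(yi < 1 - 1e-6) || any(yi > ny + 1e-6))
    stop("profile box extends outside the image")
  vals <- matrix(bilinear_sample(v, as.vector(xi), as.vector(yi)),
                 nrow = length(tpos))
  prof <- rowMeans(vals)
  if (normalize) {
    m <- max(prof)
    if (m > 0) prof <- prof / m
  }
  structure(list(positions_nm = tpos, intensities = prof, box = box),
            class = "transverse_profile")
}

#' @export
print.transverse_profile <- function(x, ...) {
  cat("<transverse_profile> ", length(x$positions_nm), " samples over ",
      signif(diff(range(x$positions_nm)), 4), " nm\n", sep = "")
  invisible(x)
}

#' @export
plot.transverse_profile <- function(x, ...) {
  graphics::plot(x$positions_nm, x$intensities, type = "b", pch = 16,
                 xlab = "position (nm)", ylab = "normalized intensity", ...)
}

#' Fit a sum of two Gaussians to a transverse profile
#'
#' Least-squares fit of `a1*G(x; mu1, s1) + a2*G(x; mu2, s2) + baseline` by
#' Levenberg-Marquardt. Initialization takes the two highest local maxima of
#' the lightly smoothed profile; sigmas start at a PSF-scale width and are
#' bounded in `[2 nm, length/2]`. Peaks are canonically ordered `mu1 < mu2`.
#' Failure to converge, or peak collapse (`|mu2 - mu1|` under one sample
#' spacing), is flagged via `converged = FALSE`, never raised.
#'
#' @param profile a `transverse_profile`.
#' @param init_sigma_nm starting sigma for both peaks.
#' @return object of class `double_gaussian_fit` with elements `mu1_nm,
#'   mu2_nm, sigma1_nm, sigma2_nm, a1, a2, baseline, peak_to_peak_nm,
#'   r_squared, converged`.
#' @export
fit_double_gaussian <- function(profile, init_sigma_nm = 10) {
  stopifnot(inherits(profile, "transverse_profile"))
  x <- profile$positions_nm
  y <- profile$intensities
  if (length(x) < 7) stop("need at least 7 samples to fit two Gaussians")
  dx <- x[2] - x[1]
  failed <- function() structure(
    list(mu1_nm = NA_real_, mu2_nm = NA_real_, sigma1_nm = NA_real_,
         sigma2_nm = NA_real_, a1 = NA_real_, a2 = NA_real_,
         baseline = NA_real_, peak_to_peak_nm = NA_real_,
         r_squared = NA_real_, converged = FALSE, profile = profile),
    class = "double_gaussian_fit")
  ys <- moving_average(y, 3L)
  n <- length(ys)
  locmax <- which(ys > c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf))
  locmax <- locmax[order(ys[locmax], decreasing = TRUE)]
  if (length(locmax) < 2) return(failed())
  i1 <- locmax[1]
  # second peak: highest local max at least 2 samples away
  cand <- locmax[abs(locmax - i1) >= 2][1]
  if (is.na(cand)) return(failed())
  start <- list(a1 = max(y[i1] - min(y), 1e-3),
                mu1 = x[i1], s1 = init_sigma_nm,
                a2 = max(y[cand] - min(y), 1e-3),
                mu2 = x[cand], s2 = init_sigma_nm,
                b = min(y))
  lowb <- c(0, min(x), 2, 0, min(x), 2, -Inf)
  uppb <- c(Inf, max(x), diff(range(x)) / 2, Inf, max(x),
            diff(range(x)) / 2, Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
          a2 * exp(-(x - mu2)^2 / (2 * s2^2)) + b,
      start = start, lower = lowb, upper = uppb,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(failed())
  p <- as.list(stats::coef(fit))
  if (p$mu1 > p$mu2) p <- list(a1 = p$a2, mu1 = p$mu2, s1 = p$s2,
                               a2 = p$a1, mu2 = p$mu1, s2 = p$s1, b = p$b)
  sep <- p$mu2 - p$mu1
  if (sep < dx) return(failed())
  resid <- y - stats::predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(mu1_nm = p$mu1, mu2_nm = p$mu2, sigma1_nm = p$s1,
                 sigma2_nm = p$s2, a1 = p$a1, a2 = p$a2, baseline = p$b,
                 peak_to_peak_nm = sep, r_squared = r2, converged = TRUE,
                 profile = profile),
            class = "double_gaussian_fit")
}

#' @export
print.double_gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<double_gaussian_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<double_gaussian_fit> peaks at %.2f / %.2f nm (p2p %.2f nm), R^2 = %.4f\n",
              x$mu1_nm, x$mu2_nm, x$peak_to_peak_nm, x$r_squared))
  invisible(x)
}

#' @export
coef.double_gaussian_fit <- function(object, ...) {
  c(mu1_nm = object$mu1_nm, mu2_nm = object$mu2_nm,
    sigma1_nm = object$sigma1_nm, sigma2_nm = object$sigma2_nm,
    a1 = object$a1, a2 = object$a2, baseline = object$baseline)
}

#' @export
predict.double_gaussian_fit <- function(object, positions_nm = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  if (is.null(positions_nm)) positions_nm <- object$profile$positions_nm
  with(object, a1 * exp(-(positions_nm - mu1_nm)^2 / (2 * sigma1_nm^2)) +
         a2 * exp(-(positions_nm - mu2_nm)^2 / (2 * sigma2_nm^2)) + baseline)
}

#' Population statistics of peak-to-peak distances
#'
#' Mean and sample s.d. of the sidewall peak-to-peak distance over converged
#' fits. With a single fit the s.d. is undefined; it is reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param fits list of `double_gaussian_fit` objects.
#' @return list: `mean_nm`, `sd_nm`, `n`, `sd_defined`.
#' @export
population_stats <- function(fits) {
  if (inherits(fits, "double_gaussian_fit")) fits <- list(fits)
  sep <- vapply(fits, function(f) {
    if (isTRUE(f$converged)) f$peak_to_peak_nm else NA_real_
  }, numeric(1))
  sep <- sep[!is.na(sep)]
  if (length(sep) == 0) stop("no converged fits")
  list(mean_nm = mean(sep),
       sd_nm = if (length(sep) > 1) stats::sd(sep) else 0,
       n = length(sep),
       sd_defined = length(sep) > 1)
}

#' Boxes for phantom microtubule segments
#'
#' Builds one transverse [profile_box] per segment from a phantom ground
#' truth table (box long axis perpendicular to the recorded segment axis) —
#' the auto-selector used by the recovery tests.
#'
#' @param truth truth data.frame from [render_microtubules()].
#' @param length_nm profile length; default covers the separation plus PSF
#'   tails.
#' @param width_nm averaging width along the microtubule.
#' @return list of [profile_box] objects.
#' @export
boxes_from_truth <- function(truth, length_nm = NULL, width_nm = 185) {
  lapply(seq_len(nrow(truth)), function(s) {
    L <- if (is.null(length_nm)) 4 * truth$separation_nm[s] else length_nm
    profile_box(truth$cx_nm[s], truth$cy_nm[s],
                truth$angle_deg[s] + 90, L, width_nm)
  })
}
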