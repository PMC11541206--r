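#' Write an image stack to TIFF with a JSON calibration sidecar
#'
#' Voxels are written as 32-bit float TIFF (one directory per z-plane /
#' channel); pixel sizes (nm), the expansion factor, array shape and channel
#' names go to `<path>.json` so that [read_stack()] round-trips the stack
#' bit-exactly together with its calibration.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  # tiff stores [0, 1] floats; normalize and record the affine intensity
  # map in the sidecar so read_stack() can undo it.
  lo <- min(v); hi <- max(v)
  vn <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  # planes as a (y, x) list, transposing our (x, y) convention
  planes <- if (length(d) == 2L) list(t(vn))
  else {
    flat <- array(vn, c(d[1], d[2], prod(d[-(1:2)])))
    lapply(seq_len(dim(flat)[3]), function(k) t(flat[, , k]))
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(shape = d, pixel_size_nm = stack$pixel_size_nm,
               expansion_factor = stack$expansion_factor,
               channel_names = stack$channel_names,
               intensity_offset = lo, intensity_scale = hi - lo)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Calibration comes from the JSON sidecar written by [write_stack()] when
#' present; otherwise `pixel_size_override` must be given — a plain TIFF
#' without pixel-size metadata and without an override is an error, never a
#' silent default.
#'
#' @param path TIFF path.
#' @param pixel_size_override physical pixel size in nm (scalar or per axis);
#'   overrides any sidecar value when non-`NULL`.
#' @param expansion_factor linear expansion factor; overrides the sidecar.
#' @return an [image_stack].
#' @export
read_stack <- function(path, pixel_size_override = NULL,
                       expansion_factor = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else NULL
  if (is.null(meta)) {
    if (is.null(pixel_size_override))
      stop("'", path, "' carries no pixel-size metadata; ",
           "supply pixel_size_override")
    v <- simplify2array(lapply(planes, t))
    if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
    if (dim(v)[3] == 1L) dim(v) <- dim(v)[1:2]
    meta <- list(shape = dim(v), pixel_size_nm = pixel_size_override,
                 expansion_factor = if (is.null(expansion_factor)) 1
                 else expansion_factor,
                 channel_names = NULL)
  } else {
    v <- simplify2array(lapply(planes, t))
    dim(v) <- as.integer(meta$shape)
    if (!is.null(meta$intensity_scale))
      v <- v * meta$intensity_scale + meta$intensity_offset
    if (!is.null(pixel_size_override)) meta$pixel_size_nm <- pixel_size_override
    if (!is.null(expansion_factor)) meta$expansion_factor <- expansion_factor
    if (length(meta$channel_names) == 0) meta$channel_names <- NULL
  }
  image_stack(v, meta$pixel_size_nm, meta$expansion_factor,
              meta$channel_names)
}

#' Matched landmark pairs for expansion-factor estimation
#'
#' @param pre_points,post_points matrices of matched coordinates (nm,
#'   physical), one row per landmark, 2 or 3 columns; matched by row index.
#' @return object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(pre_points, post_points) {
  pre_points <- as.matrix(pre_points); post_points <- as.matrix(post_points)
  if (nrow(pre_points) != nrow(post_points))
    stop("pre and post point sets must have equal length")
  if (nrow(pre_points) < 2) stop("need at least 2 matched landmarks")
  structure(list(pre = pre_points, post = post_points),
            class = "landmark_pairs")
}

#' Read a landmark CSV
#'
#' Expected columns: `id, pre_x, pre_y[, pre_z], post_x, post_y[, post_z]`,
#' all in physical nm.
#'
#' @param path CSV path.
#' @return a [landmark_pairs] object.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path)
  pre_cols <- intersect(c("pre_x", "pre_y", "pre_z"), names(d))
  post_cols <- intersect(c("post_x", "post_y", "post_z"), names(d))
  if (length(pre_cols) < 2 || length(post_cols) != length(pre_cols))
    stop("landmark CSV needs matching pre_*/post_* coordinate columns")
  landmark_pairs(d[pre_cols], d[post_cols])
}

#' Expansion factor from landmark distances
#'
#' The linear expansion factor is estimated the way it is measured at the
#' bench: as the ratio of post- to pre-expansion distance between pairs of
#' landmarks. All unordered landmark pairs are used; the summary is the mean
#' and s.d. of the per-pair ratios. The estimate is invariant under rigid
#' motion of either point set.
#'
#' @param pairs a [landmark_pairs] object.
#' @return list with `factor` (mean ratio), `sd`, `n_pairs` and `per_pair`
#'   (data.frame of pre/post distances and ratios).
#' @export
expansion_factor_from_landmarks <- function(pairs) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  n <- nrow(pairs$pre)
  comb <- utils::combn(n, 2)
  pre_d <- sqrt(colSums((t(pairs$pre[comb[1, ], , drop = FALSE]) -
                         t(pairs$pre[comb[2, ], , drop = FALSE]))^2))
  post_d <- sqrt(colSums((t(pairs$post[comb[1, ], , drop = FALSE]) -
                          t(pairs$post[comb[2, ], , drop = FALSE]))^2))
  if (any(pre_d == 0)) stop("zero pre-expansion distance between landmarks ",
                            paste(comb[, pre_d == 0][1:2], collapse = ","))
  ratio <- post_d / pre_d
  list(factor = mean(ratio),
       sd = if (length(ratio) > 1) stats::sd(ratio) else 0,
       n_pairs = length(ratio),
       per_pair = data.frame(i = comb[1, ], j = comb[2, ],
                             pre_nm = pre_d, post_nm = post_d, ratio = ratio))
}

#' Standard preprocessing: rolling-ball background subtraction, smoothing,
#' projection
#'
#' Applies, in order: rolling-ball background subtraction (grayscale opening
#' with a disc structuring element of the given radius, per plane for
#' z-stacks), optional Gaussian smoothing, optional maximum-intensity
#' z-projection. A radius or sigma of 0 disables that step. Output is
#' clamped at 0 (rolling-ball convention) and the parameters used are
#' attached as a `provenance` attribute.
#'
#' @param stack an [image_stack] (single channel).
#' @param rolling_ball_radius_px structuring-element radius in pixels.
#' @param gaussian_sigma_px Gaussian smoothing sigma in pixels.
#' @param max_project if `TRUE` and the stack is 3D, maximum-project along z.
#' @return a preprocessed [image_stack].
#' @export
preprocess <- function(stack, rolling_ball_radius_px = 50,
                       gaussian_sigma_px = 0, max_project = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.null(stack$channel_names))
    stop("preprocess expects a single-channel stack; use get_channel()")
  v <- stack$voxels
  d <- dim(v)
  if (rolling_ball_radius_px < 0 || gaussian_sigma_px < 0)
    stop("radius and sigma must be >= 0")
  if (rolling_ball_radius_px > 0 &&
      2 * rolling_ball_radius_px + 1 > min(d[1:2]))
    stop("rolling-ball radius exceeds the image extent")
  sub_bg <- function(m) {
    if (rolling_ball_radius_px == 0) return(m)
    brush <- EBImage::makeBrush(2L * as.integer(rolling_ball_radius_px) + 1L,
                                shape = "disc")
    # EBImage grayscale morphology operates on [0, 1]; opening commutes
    # with affine intensity maps, so normalize, open, map back.
    lo <- min(m); hi <- max(m)
    if (hi == lo) return(m - m)          # constant image: background = image
    bg <- lo + (hi - lo) *
      EBImage::opening((m - lo) / (hi - lo), brush)
    pmax(m - bg, 0)
  }
  smooth <- function(m) {
    if (gaussian_sigma_px == 0) return(m)
    gauss_smooth2d(m, gaussian_sigma_px)
  }
  if (length(d) == 2L) {
    v <- smooth(sub_bg(v))
  } else {
    for (k in seq_len(d[3])) v[, , k] <- smooth(sub_bg(v[, , k]))
    if (max_project) v <- apply(v, c(1, 2), max)
  }
  px <- stack$pixel_size_nm
  if (length(dim(v)) == 2L && length(px) == 3L) px <- px[1:2]
  out <- image_stack(v, px, stack$expansion_factor)
  attr(out, "provenance") <- list(rolling_ball_radius_px = rolling_ball_radius_px,
                                  gaussian_sigma_px = gaussian_sigma_px,
                                  max_project = max_project)
  out
}
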