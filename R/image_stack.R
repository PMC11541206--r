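#' Image stack with physical calibration
#'
#' The universal carrier for all analyses in this package: an N-D voxel grid
#' (2D plane, 3D z-stack, optionally with a trailing channel axis) together
#' with the per-axis physical pixel size at the detector (nm) and the linear
#' expansion factor. Every nm-valued quantity reported downstream is in
#' *biological units*, i.e. physical size divided by the expansion factor.
#'
#' Coordinate convention: voxel `(i, j[, k])` (1-based R indices) has its
#' center at physical position `(i - 1) * pixel_size_nm[1]`, etc. The first
#' array dimension is x, the second y, the third z.
#'
#' @param voxels numeric array, 2D `(x, y)` or 3D `(x, y, z)`; a trailing
#'   channel dimension is allowed when `channel_names` is given.
#' @param pixel_size_nm per-spatial-axis physical sampling in nm; recycled to
#'   the number of spatial axes.
#' @param expansion_factor dimensionless linear expansion factor (>= 1).
#' @param channel_names optional character vector naming the channels along
#'   the last dimension of `voxels`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_nm, expansion_factor = 1,
                        channel_names = NULL) {
  if (is.null(dim(voxels))) stop("'voxels' must be a matrix or array")
  nd <- length(dim(voxels))
  n_spatial <- if (is.null(channel_names)) nd else nd - 1L
  if (n_spatial < 2L || n_spatial > 3L)
    stop("image_stack supports 2 or 3 spatial dimensions, got ", n_spatial)
  if (!is.null(channel_names) &&
      length(channel_names) != dim(voxels)[nd])
    stop("channel_names length does not match the last array dimension")
  pixel_size_nm <- rep_len(as.numeric(pixel_size_nm), n_spatial)
  if (any(!is.finite(pixel_size_nm)) || any(pixel_size_nm <= 0))
    stop("all pixel sizes must be positive and finite")
  expansion_factor <- as.numeric(expansion_factor)
  if (!is.finite(expansion_factor) || expansion_factor < 1)
    stop("expansion_factor must be >= 1")
  structure(list(
    voxels = voxels,
    pixel_size_nm = pixel_size_nm,
    expansion_factor = expansion_factor,
    channel_names = channel_names
  ), class = "image_stack")
}

#' Biological pixel size of a stack
#'
#' Physical pixel size divided by the expansion factor: the sampling of the
#' original (pre-expansion) specimen, the unit in which all distances are
#' reported.
#'
#' @param stack an [image_stack].
#' @return numeric vector, nm per voxel along each spatial axis.
#' @export
bio_pixel_size <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$pixel_size_nm / stack$expansion_factor
}

#' Number of spatial dimensions of a stack
#' @param stack an [image_stack].
#' @return 2 or 3.
#' @export
n_spatial_dims <- function(stack) length(stack$pixel_size_nm)

#' Extract one channel of a multi-channel stack
#'
#' @param stack an [image_stack] with a channel axis.
#' @param channel channel index or name.
#' @return a single-channel [image_stack] sharing calibration.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$channel_names)) {
    if (identical(channel, 1L) || identical(channel, 1)) return(stack)
    stop("stack has no channel axis")
  }
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  nd <- length(dim(stack$voxels))
  idx <- c(rep(list(quote(expr = )), nd - 1L), list(channel))
  v <- do.call(`[`, c(list(stack$voxels), idx, list(drop = FALSE)))
  dim(v) <- dim(stack$voxels)[-nd]
  image_stack(v, stack$pixel_size_nm, stack$expansion_factor)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", paste(d, collapse = " x "), "\n", sep = "")
  cat("  pixel size (physical nm): ",
      paste(signif(x$pixel_size_nm, 6), collapse = ", "), "\n", sep = "")
  cat("  expansion factor: ", x$expansion_factor,
      "  (biological nm/px: ",
      paste(signif(bio_pixel_size(x), 6), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$channel_names))
    cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Crop a square region out of a 2D stack
#'
#' Returns the sub-stack covering `center_nm` +/- `half_nm` (biological nm)
#' together with the origin of the crop, so coordinates can be mapped
#' between frames: `coord_in_crop = coord - origin_nm`.
#'
#' @param stack a 2D single-channel [image_stack].
#' @param center_nm region center, biological nm.
#' @param half_nm half-width of the crop.
#' @return list: `stack` (the crop) and `origin_nm`.
#' @export
crop_stack <- function(stack, center_nm, half_nm) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (length(dim(v)) != 2L) stop("crop_stack expects a 2D stack")
  px <- bio_pixel_size(stack)
  i0 <- max(1L, floor((center_nm[1] - half_nm) / px[1]) + 1L)
  i1 <- min(nrow(v), ceiling((center_nm[1] + half_nm) / px[1]) + 1L)
  j0 <- max(1L, floor((center_nm[2] - half_nm) / px[2]) + 1L)
  j1 <- min(ncol(v), ceiling((center_nm[2] + half_nm) / px[2]) + 1L)
  if (i0 >= i1 || j0 >= j1) stop("empty crop")
  list(stack = image_stack(v[i0:i1, j0:j1], stack$pixel_size_nm,
                           stack$expansion_factor),
       origin_nm = c((i0 - 1L) * px[1], (j0 - 1L) * px[2]))
}
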