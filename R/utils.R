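# Internal numeric helpers shared across modules.

# Deterministic sub-seed for per-structure RNG streams. Keeps everything
# below .Machine$integer.max so set.seed() accepts it.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 65521) * 31013 + 7919 * ((as.double(k) + 1) %% 65521)
  as.integer(s %% 2147483647)
}

# Vectorized bilinear sampling of a 2D matrix at fractional 1-based indices.
# Out-of-bounds points return `fill`.
bilinear_sample <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= nx - 1 & y0 <= ny - 1
  # clamp exact upper edge into the last cell
  edge_x <- xi >= nx & xi <= nx + 1e-9
  edge_y <- yi >= ny & yi <= ny + 1e-9
  x0[edge_x] <- nx - 1; fx[edge_x] <- 1
  y0[edge_y] <- ny - 1; fy[edge_y] <- 1
  ok <- ok | ((x0 >= 1 & y0 >= 1 & x0 <= nx - 1 & y0 <= ny - 1) & (edge_x | edge_y))
  out <- rep(fill, length(xi))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- cbind(x0k,      y0k)
    i10 <- cbind(x0k + 1L, y0k)
    i01 <- cbind(x0k,      y0k + 1L)
    i11 <- cbind(x0k + 1L, y0k + 1L)
    out[ok] <- img[i00] * (1 - fxk) * (1 - fyk) +
      img[i10] * fxk * (1 - fyk) +
      img[i01] * (1 - fxk) * fyk +
      img[i11] * fxk * fyk
  }
  out
}

# Separable Gaussian smoothing of a 2D matrix, reflective boundaries.
# sigma in pixels; sigma = 0 returns the input.
gauss_smooth2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # cap the kernel at the image size so single reflection stays in range;
  # beyond that the result is indistinguishable from global averaging
  r <- max(1L, min(ceiling(3 * sigma), min(dim(img)) - 1L))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx[idx < 1] <- 2 - idx[idx < 1]        # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth_axis(t(smooth_axis(img))))
}

# Moving average with window w (odd), edges truncated.
moving_average <- function(x, w = 3L) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(x[j], na.rm = TRUE)
  }
  out
}

# Parabolic (3-point) interpolation of a local maximum at index i of y
# sampled at uniform spacing dx starting at x0. Returns the refined x.
parabolic_peak <- function(x, y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  x[i] + delta * (x[i] - x[i - 1])
}

# Shell index for a vector of distances, 1-based; bin b covers
# [(b-1)*width, b*width).
shell_index <- function(d_nm, width_nm) pmax(1L, 1L + as.integer(floor(d_nm / width_nm + 1e-9)))
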