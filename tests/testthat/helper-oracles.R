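# Independent brute-force oracles used to pin the production implementations.

# Exhaustive pair-enumeration autocorrelation g_a(r): double loop over all
# voxel pairs (including self pairs at r = 0), shell-binned, normalized by
# the uniform-object baseline (mean^2).
oracle_ga <- function(coords, ints, voxel_size_nm, shell_nm, max_radius_nm) {
  pos <- sweep(coords, 2, voxel_size_nm, `*`)
  D <- as.matrix(stats::dist(pos))
  P <- outer(ints, ints)
  nshell <- as.integer(ceiling(max_radius_nm / shell_nm))
  sh <- floor(D / shell_nm + 1e-9) + 1
  g <- vapply(seq_len(nshell), function(k) {
    sel <- sh == k & D <= max_radius_nm
    if (!any(sel)) NA_real_ else mean(P[sel])
  }, numeric(1))
  g / mean(ints)^2
}

# Brute-force grayscale opening (erosion then dilation) with a flat disc of
# the given radius; direct loops, no library calls.
brute_rolling_ball <- function(m, radius) {
  nx <- nrow(m); ny <- ncol(m)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  ero <- matrix(Inf, nx, ny)
  for (r in seq_len(nrow(offs))) {
    i <- pmin(pmax(seq_len(nx) + offs$dx[r], 1), nx)
    j <- pmin(pmax(seq_len(ny) + offs$dy[r], 1), ny)
    ero <- pmin(ero, m[i, j])
  }
  dil <- matrix(-Inf, nx, ny)
  for (r in seq_len(nrow(offs))) {
    i <- pmin(pmax(seq_len(nx) + offs$dx[r], 1), nx)
    j <- pmin(pmax(seq_len(ny) + offs$dy[r], 1), ny)
    dil <- pmax(dil, ero[i, j])
  }
  dil
}

# Analytic two-sidewall profile: sum of two unit Gaussians at +/- sep/2.
two_gauss <- function(x, sep, sigma, a = 1, baseline = 0) {
  a * exp(-(x - sep / 2)^2 / (2 * sigma^2)) +
    a * exp(-(x + sep / 2)^2 / (2 * sigma^2)) + baseline
}

# Wrap positions/intensities as a transverse_profile for direct fitting.
as_profile <- function(positions_nm, intensities) {
  structure(list(positions_nm = positions_nm, intensities = intensities,
                 box = NULL),
            class = "transverse_profile")
}

# Build a cluster_roi directly from an intensity array and a mask.
roi_from_array <- function(v, mask, voxel_size_nm, channel = NA_character_) {
  coords <- arrayInd(which(mask), dim(v))
  ints <- v[which(mask)]
  exmqc:::new_cluster_roi(coords, ints, dim(v), voxel_size_nm,
                          coords[which.max(ints), ], channel)
}

# Count strict-or-plateau local maxima of a sampled curve.
n_local_maxima <- function(y) {
  n <- length(y)
  sum(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}
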