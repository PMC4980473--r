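# Spatial support for the synthetic cohort: a small 3D grid with an
# ellipsoidal "brain" mask and smooth Gaussian-blob component maps,
# mimicking spatially smoothed network maps.

#' Ellipsoidal brain mask on a voxel grid
#'
#' @param dim Grid dimensions (3 integers).
#' @param scale Semi-axes as a fraction of the half-extent of each axis.
#' @return Logical array of dimension `dim`.
#' @export
ellipsoid_mask <- function(dim = c(16, 16, 8), scale = 1.0) {
  stopifnot(length(dim) == 3)
  ctr <- (dim - 1) / 2
  semi <- ctr * scale
  g <- expand.grid(x = 0:(dim[1] - 1), y = 0:(dim[2] - 1), z = 0:(dim[3] - 1))
  v <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(v <= 1, dim = dim)
}

#' Smooth compact spatial map from Gaussian blobs
#'
#' Sums isotropic 3D Gaussian bumps centred at `centers` (0-based voxel
#' coordinates), truncates small amplitudes to exact zero to keep the map
#' compact, and scales to unit maximum.
#'
#' @param dim Grid dimensions.
#' @param centers Matrix (n x 3) of 0-based blob centres.
#' @param sigma Blob standard deviation in voxels.
#' @param trunc Amplitudes below this fraction of the maximum are zeroed.
#' @return Numeric array of dimension `dim` with values in [0, 1].
#' @export
gaussian_blob_map <- function(dim, centers, sigma = 1.8, trunc = 0.01) {
  centers <- matrix(centers, ncol = 3)
  g <- expand.grid(x = 0:(dim[1] - 1), y = 0:(dim[2] - 1), z = 0:(dim[3] - 1))
  m <- rep(0, nrow(g))
  for (i in seq_len(nrow(centers))) {
    d2 <- (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 + (g$z - centers[i, 3])^2
    m <- m + exp(-d2 / (2 * sigma^2))
  }
  m <- m / max(m)
  m[m < trunc] <- 0
  array(m, dim = dim)
}
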