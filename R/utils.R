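#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm dnorm runif sd var setNames
#' @importFrom utils read.csv packageVersion
#' @importFrom tools md5sum
#' @importFrom RNifti readNifti writeNifti asNifti pixdim
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
NULL

# DFT sample frequencies (cycles per unit length) in the standard layout:
# zero frequency at index 1, positive frequencies first, then negative.
fft_freq <- function(n, d = 1) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * d)
}

# Signed integer DFT grid offsets (voxel units), same wraparound layout.
fft_offsets <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Expand three axis vectors to full 3D arrays (kx varies along dim 1, ...).
axis_grid <- function(vx, vy, vz) {
  nx <- length(vx); ny <- length(vy); nz <- length(vz)
  list(
    x = array(vx, dim = c(nx, ny, nz)),
    y = array(rep(vy, each = nx), dim = c(nx, ny, nz)),
    z = array(rep(vz, each = nx * ny), dim = c(nx, ny, nz))
  )
}

ifftn <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# Convolve along one array axis with a short symmetric kernel, zero boundary.
# Implemented as a banded-matrix multiply after rotating the axis to the
# front; n up to a few hundred so the dense band matrix is cheap.
axis_convolve <- function(arr, kernel, axis) {
  d <- dim(arr)
  stopifnot(axis >= 1, axis <= length(d))
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- max(1L, j - r):min(n, j + r)
    band[i, j] <- kernel[i - j + r + 1L]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- band %*% matrix(a, nrow = n)
  dim(a) <- da
  aperm(a, order(perm))
}

# Isotropic 3D Gaussian smoothing, sigma in voxel units, truncated at 4*sigma,
# zero-padded boundaries. sigma = 0 returns the input unchanged.
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma))
  kernel <- stats::dnorm(seq(-r, r), sd = sigma)
  kernel <- kernel / sum(kernel)
  for (axis in seq_along(dim(arr))) {
    arr <- axis_convolve(arr, kernel, axis)
  }
  arr
}

# Deterministic sub-seed derivation so one user seed drives independent
# stages without reusing identical streams. Kept below 2^31.
derive_seed <- function(seed, tag) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(tag)) * 9973) %% 2147483647
}

stop_qsm <- function(...) stop(sprintf(...), call. = FALSE)
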