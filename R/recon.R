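#' Temporal phase unwrapping along the echo dimension
#'
#' Per-voxel 1D unwrapping: each successive echo phase is shifted by a
#' multiple of 2 pi to lie within pi of the value extrapolated from the
#' previously unwrapped echoes (the second echo is compared against the
#' first directly). Absolute wraps at the first echo are not recoverable.
#'
#' @param phases 4D array of wrapped phases, radians (space x echo).
#' @param echo_times Echo times, seconds.
#' @return 4D array of unwrapped phases.
#' @export
temporal_unwrap <- function(phases, echo_times) {
  d <- dim(phases)
  K <- d[4]
  if (K != length(echo_times)) stop_qsm("echo count mismatch")
  if (K < 2) {
    warning("temporal_unwrap: single echo, returned unchanged")
    return(phases)
  }
  P <- matrix(phases, ncol = K)
  U <- P
  for (k in 2:K) {
    pred <- if (k == 2) U[, 1] else
      U[, k - 1] + (U[, k - 1] - U[, 1]) /
        (echo_times[k - 1] - echo_times[1]) *
        (echo_times[k] - echo_times[k - 1])
    U[, k] <- P[, k] + 2 * pi * round((pred - P[, k]) / (2 * pi))
  }
  array(U, dim = d)
}

#' Multi-echo fieldmap fitting
#'
#' Estimates the off-resonance field per voxel by magnitude-weighted
#' linear least squares of the temporally unwrapped phase against echo
#' time, with an intercept for initial/coil phase:
#' `phi(TE) = phi0 + 2 pi fB TE`. Voxels without at least two echoes of
#' nonzero magnitude get `fB = 0` and are flagged unreliable.
#'
#' @param echoes An `echo_series`.
#' @return List: `field` (a `field_map`, Hz), `phi0` (radians),
#'   `reliable` (3D logical array).
#' @export
fit_fieldmap <- function(echoes) {
  d <- dim(echoes$signal)
  K <- d[4]
  if (K < 2) stop_qsm("fieldmap fitting needs at least 2 echoes")
  te <- echoes$protocol$echo_times
  ph <- temporal_unwrap(Arg(echoes$signal), te)
  W <- matrix(Mod(echoes$signal), ncol = K)
  Y <- matrix(ph, ncol = K)
  X <- matrix(te, nrow = nrow(W), ncol = K, byrow = TRUE)
  sw <- rowSums(W)
  sx <- rowSums(W * X)
  sy <- rowSums(W * Y)
  sxx <- rowSums(W * X^2)
  sxy <- rowSums(W * X * Y)
  det <- sw * sxx - sx^2
  reliable <- rowSums(W > 0) >= 2 & det > .Machine$double.eps * sxx
  slope <- ifelse(reliable, (sw * sxy - sx * sy) / det, 0)
  phi0 <- ifelse(reliable, (sxx * sy - sx * sxy) / det, 0)
  list(field = new_field_map(array(slope / (2 * pi), dim = d[1:3]),
                             b0 = echoes$protocol$b0,
                             gamma = echoes$protocol$gamma),
       phi0 = array(phi0, dim = d[1:3]),
       reliable = array(reliable, dim = d[1:3]))
}

#' Magnitude-based data-fidelity weight
#'
#' Spatially variable weight used in regularized dipole inversion:
#' `W = sum_i |S(TE_i)|^2 TE_i / sum_i |S(TE_i)| TE_i`, per voxel, with
#' the convention 0/0 = 0. Collapses to the magnitude image for a single
#' echo or constant magnitudes.
#'
#' @param echoes An `echo_series`.
#' @return 3D non-negative array in signal units.
#' @export
fidelity_weight <- function(echoes) {
  d <- dim(echoes$signal)
  te <- echoes$protocol$echo_times
  M <- matrix(Mod(echoes$signal), ncol = d[4])
  X <- matrix(te, nrow = nrow(M), ncol = d[4], byrow = TRUE)
  num <- rowSums(M^2 * X)
  den <- rowSums(M * X)
  array(ifelse(den > 0, num / den, 0), dim = d[1:3])
}

#' Thresholded k-space division (TKD) dipole inversion
#'
#' Simple non-regularized baseline: divides the fieldmap by the dipole
#' kernel in k-space, replacing kernel values smaller in magnitude than
#' the threshold by `sign(D) * threshold` to control noise amplification
#' near the dipole's conical zero surface. The zero-frequency sample is
#' set to 0 and the result is demeaned over the mask.
#'
#' @param field A `field_map` (Hz) or 3D array with `b0`/`gamma` given.
#' @param mask 3D logical array (body mask) for demeaning.
#' @param threshold Kernel magnitude threshold, in (0, 2/3].
#' @param voxel_size Voxel edge lengths, mm.
#' @param kernel_mode `"continuous"` or `"discrete"`.
#' @param b0,gamma Field strength (T) and gyromagnetic ratio (Hz/T); taken
#'   from `field` when it is a `field_map`.
#' @param pad_factor Zero-padding factor (default 2, matching the forward
#'   simulation).
#' @return 3D susceptibility array, ppm.
#' @export
tkd_inversion <- function(field, mask, threshold = 0.2,
                          voxel_size = c(1, 1, 1),
                          kernel_mode = "continuous",
                          b0 = NULL, gamma = NULL, pad_factor = 2) {
  if (threshold <= 0 || threshold > 2 / 3)
    stop_qsm("threshold must lie in (0, 2/3]")
  if (inherits(field, "field_map")) {
    b0 <- field$b0; gamma <- field$gamma; fB <- field$field
  } else {
    if (is.null(b0) || is.null(gamma))
      stop_qsm("b0 and gamma required when field is a plain array")
    fB <- field
  }
  d <- dim(fB)
  dp <- d * pad_factor
  pad <- array(0, dim = dp)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- fB
  kern <- make_dipole_kernel(dp, voxel_size, mode = kernel_mode)
  D <- kern$values
  Dthr <- ifelse(abs(D) >= threshold, D, ifelse(D >= 0, 1, -1) * threshold)
  chi_k <- stats::fft(pad) / Dthr
  chi_k[1, 1, 1] <- 0
  chi <- Re(ifftn(chi_k))[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  chi <- chi / (gamma * b0 * 1e-6)
  demean(chi, mask)
}

#' Log-linear R2* fitting
#'
#' Per-voxel least squares of log magnitude against echo time; the
#' negative slope, clipped at zero from below, estimates R2*. Valid on
#' water-dominant voxels; fat-containing voxels are biased by spectral
#' modulation of the magnitude and should be excluded from quantitative
#' use. Non-positive magnitudes are excluded from the fit; voxels with
#' fewer than two usable echoes return 0 and are flagged.
#'
#' @param echoes An `echo_series`.
#' @param mask Optional 3D logical array restricting the fit.
#' @return List: `r2star` (3D array, 1/s), `reliable` (3D logical).
#' @export
fit_r2star_loglinear <- function(echoes, mask = NULL) {
  d <- dim(echoes$signal)
  K <- d[4]
  if (K < 2) stop_qsm("R2* fitting needs at least 2 echoes")
  te <- echoes$protocol$echo_times
  M <- matrix(Mod(echoes$signal), ncol = K)
  use <- M > 0
  L <- matrix(0, nrow = nrow(M), ncol = K)
  L[use] <- log(M[use])
  W <- use * 1
  X <- matrix(te, nrow = nrow(M), ncol = K, byrow = TRUE)
  sw <- rowSums(W)
  sx <- rowSums(W * X)
  sy <- rowSums(W * L)
  sxx <- rowSums(W * X^2)
  sxy <- rowSums(W * X * L)
  det <- sw * sxx - sx^2
  reliable <- sw >= 2 & det > .Machine$double.eps * sxx
  slope <- ifelse(reliable, (sw * sxy - sx * sy) / det, 0)
  r2 <- pmax(-slope, 0)
  if (!is.null(mask)) {
    r2[!as.vector(mask)] <- 0
    reliable <- reliable & as.vector(mask)
  }
  list(r2star = array(r2, dim = d[1:3]),
       reliable = array(reliable, dim = d[1:3]))
}
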