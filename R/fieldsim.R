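GAMMA_HZ_PER_T <- 42.5775e6

#' Magnetic dipole kernel
#'
#' Builds the k-space dipole kernel used to synthesize the field
#' perturbation from a susceptibility distribution. Two formulations:
#' \describe{
#'   \item{continuous}{the classical closed form
#'     `D(k) = 1/3 - kz^2 / |k|^2` evaluated on the discrete DFT frequency
#'     grid (zero frequency at index 1).}
#'   \item{discrete}{a finite-difference formulation: the continuous
#'     frequencies are replaced by eigenvalues of the discrete difference
#'     operator, `k_j -> (exp(i 2 pi m_j / N_j) - 1) / voxel_j`, so
#'     `D = 1/3 - |k . b|^2 / |k|^2` on those surrogates. It converges to
#'     the continuous kernel at low frequencies and rolls off near
#'     Nyquist, which reduces aliasing around abrupt susceptibility
#'     interfaces (air, bone, fat).}
#' }
#' The zero-frequency sample is set to 0 in both modes (the mean field is
#' not determined by the dipole model).
#'
#' @param shape Grid dimensions.
#' @param voxel_size Voxel edge lengths in mm.
#' @param b0_axis Main-field direction (array axes); default `c(0, 0, 1)`,
#'   the array z-axis.
#' @param mode `"continuous"` or `"discrete"`.
#' @return A `dipole_kernel` object with the real-valued kernel in
#'   `$values`.
#' @export
make_dipole_kernel <- function(shape, voxel_size = c(1, 1, 1),
                               b0_axis = c(0, 0, 1),
                               mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (any(shape < 1)) stop_qsm("shape must be positive")
  nb <- sqrt(sum(b0_axis^2))
  if (nb == 0) stop_qsm("b0_axis must be a nonzero vector")
  b <- b0_axis / nb

  if (mode == "continuous") {
    g <- axis_grid(fft_freq(shape[1], voxel_size[1]),
                   fft_freq(shape[2], voxel_size[2]),
                   fft_freq(shape[3], voxel_size[3]))
    k2 <- g$x^2 + g$y^2 + g$z^2
    kz <- g$x * b[1] + g$y * b[2] + g$z * b[3]
    D <- 1 / 3 - kz^2 / k2
    D[1, 1, 1] <- 0
  } else {
    th <- function(n) 2 * pi * (0:(n - 1)) / n
    g <- axis_grid((exp(1i * th(shape[1])) - 1) / voxel_size[1],
                   (exp(1i * th(shape[2])) - 1) / voxel_size[2],
                   (exp(1i * th(shape[3])) - 1) / voxel_size[3])
    k2 <- Mod(g$x)^2 + Mod(g$y)^2 + Mod(g$z)^2
    kb <- g$x * b[1] + g$y * b[2] + g$z * b[3]
    D <- 1 / 3 - Mod(kb)^2 / k2
    D[1, 1, 1] <- 0
  }
  structure(list(values = D, shape = shape, voxel_size = voxel_size,
                 b0_axis = b, mode = mode),
            class = "dipole_kernel")
}

#' @export
print.dipole_kernel <- function(x, ...) {
  cat(sprintf("<dipole_kernel> %s, %s mode, B0 axis (%s)\n",
              paste(x$shape, collapse = "x"), x$mode,
              paste(signif(x$b0_axis, 3), collapse = ", ")))
  invisible(x)
}

new_field_map <- function(field, b0, gamma = GAMMA_HZ_PER_T) {
  structure(list(field = field, b0 = b0, gamma = gamma),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %s voxels, B0 = %g T, range %.2f..%.2f Hz\n",
              paste(dim(x$field), collapse = "x"), x$b0,
              min(x$field), max(x$field)))
  invisible(x)
}

#' Forward dipole-field synthesis
#'
#' Computes the off-resonance fieldmap induced by local plus background
#' susceptibility sources: the total map (in ppm) is zero-padded by a
#' factor of 2 along each dimension to suppress circular-convolution
#' aliasing, multiplied by the dipole kernel in k-space, inverse
#' transformed, cropped back, and scaled by `gamma * B0 * 1e-6` to Hz.
#'
#' @param chi_local 3D local susceptibility array, ppm.
#' @param chi_background Optional 3D background susceptibility array, ppm
#'   (same grid); `NULL` for none.
#' @param voxel_size Voxel edge lengths in mm.
#' @param kernel_mode `"continuous"` or `"discrete"`.
#' @param b0 Main field strength, Tesla.
#' @param gamma Gyromagnetic ratio, Hz/T.
#' @param b0_axis Main-field direction.
#' @param pad_factor Zero-padding factor (default 2).
#' @return A `field_map` object with the field in Hz.
#' @export
forward_field <- function(chi_local, chi_background = NULL,
                          voxel_size = c(1, 1, 1),
                          kernel_mode = "discrete", b0 = 3,
                          gamma = GAMMA_HZ_PER_T, b0_axis = c(0, 0, 1),
                          pad_factor = 2) {
  chi <- chi_local
  if (!is.null(chi_background)) {
    if (!identical(dim(chi_background), dim(chi)))
      stop_qsm("chi_local and chi_background shapes differ")
    chi <- chi + chi_background
  }
  d <- dim(chi)
  dp <- d * pad_factor
  pad <- array(0, dim = dp)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- chi
  kern <- make_dipole_kernel(dp, voxel_size, b0_axis, kernel_mode)
  f <- Re(ifftn(stats::fft(pad) * kern$values))
  f <- f[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  new_field_map(f * gamma * b0 * 1e-6, b0 = b0, gamma = gamma)
}

#' Extend a volume for background-field simulation
#'
#' Emulates the body continuing beyond the imaged slab: appends
#' axially-flipped copies of the volume below and above (so tissue does
#' not end abruptly at the slab faces) and zero-pads symmetrically along
#' the other two dimensions, tripling every dimension. A 192 x 192 x 80
#' phantom becomes 576 x 576 x 240. [crop_background_extension()] inverts
#' the operation exactly.
#'
#' @param volume 3D array.
#' @return 3D array with every dimension tripled; the central block is
#'   voxel-identical to the input.
#' @export
extend_for_background <- function(volume) {
  d <- dim(volume)
  out <- array(0, dim = 3 * d)
  xs <- d[1] + seq_len(d[1])
  ys <- d[2] + seq_len(d[2])
  flipped <- volume[, , rev(seq_len(d[3])), drop = FALSE]
  out[xs, ys, seq_len(d[3])] <- flipped
  out[xs, ys, d[3] + seq_len(d[3])] <- volume
  out[xs, ys, 2 * d[3] + seq_len(d[3])] <- flipped
  out
}

#' Crop the central block of a background-extended volume
#'
#' @param volume 3D array with dimensions divisible by 3, as produced by
#'   [extend_for_background()].
#' @return The central 3D block (original volume).
#' @export
crop_background_extension <- function(volume) {
  d <- dim(volume)
  if (any(d %% 3 != 0)) stop_qsm("dimensions must be divisible by 3")
  n <- d / 3
  volume[n[1] + seq_len(n[1]), n[2] + seq_len(n[2]), n[3] + seq_len(n[3]),
         drop = FALSE]
}

#' Demean a susceptibility map over a mask
#'
#' Subtracts the masked mean so the susceptibility is expressed relative
#' to a zero reference before forward simulation, as dipole inversion only
#' determines susceptibility up to a constant.
#'
#' @param chi 3D array, ppm.
#' @param mask 3D logical array, non-empty.
#' @return 3D array whose masked mean is 0.
#' @export
demean <- function(chi, mask) {
  if (!any(mask)) stop_qsm("demean: empty mask")
  chi[mask] <- chi[mask] - mean(chi[mask])
  chi
}
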