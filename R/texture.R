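#' Min-max normalize a volume over a mask
#'
#' Affine rescaling of the masked voxels to the unit interval; voxels
#' outside the mask are set to 0. Used to bring the water, fat and R2*
#' volumes onto a common 0--1 scale before texture modulation.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array, non-empty.
#' @return 3D array in `[0, 1]` over the mask, 0 outside.
#' @export
normalize_unit <- function(volume, mask) {
  if (!any(mask)) stop_qsm("normalize_unit: empty mask")
  v <- volume[mask]
  rng <- range(v)
  out <- array(0, dim = dim(volume))
  if (diff(rng) == 0) {
    warning("normalize_unit: constant volume over mask; returning zeros")
    return(out)
  }
  out[mask] <- (v - rng[1]) / diff(rng)
  out
}

#' Per-class means of the normalized property volumes
#'
#' Arithmetic means of the unit-normalized R2*, water and fat volumes over
#' each full binary class mask. These means center the texture modulators,
#' which is what makes the synthetic class means exact.
#'
#' @param props A `property_volumes` object.
#' @param labels A `tissue_labels` object.
#' @param class_ids Classes to evaluate; defaults to every class present
#'   in the label volume.
#' @return Data frame with one row per class: `class_id`, `mean_r2_norm`,
#'   `mean_rhoW_norm`, `mean_rhoF_norm`, `n_voxels`.
#' @export
class_statistics <- function(props, labels, class_ids = NULL) {
  lab <- labels$labels
  if (is.null(class_ids)) class_ids <- sort(unique(as.integer(lab)))
  rows <- lapply(class_ids, function(id) {
    m <- lab == id
    if (!any(m)) stop_qsm("class_statistics: empty mask for class %d", id)
    data.frame(class_id = id,
               mean_r2_norm = mean(props$r2_norm[m]),
               mean_rhoW_norm = mean(props$rhoW_norm[m]),
               mean_rhoF_norm = mean(props$rhoF_norm[m]),
               n_voxels = sum(m))
  })
  do.call(rbind, rows)
}

stats_row <- function(stats, id) {
  r <- stats[stats$class_id == id, ]
  if (nrow(r) != 1) stop_qsm("no class statistics for class %d", id)
  r
}

params_row <- function(params, id) {
  r <- params[params$class_id == id, ]
  if (nrow(r) != 1) stop_qsm("no tissue parameters for class %d", id)
  r
}

#' Per-class synthetic susceptibility
#'
#' Evaluates the texture model for one tissue class on the full grid: the
#' assigned class mean plus weighted, mean-centered modulators built from
#' the normalized R2*, water and fat volumes. Because the modulators are
#' centered on the class-mask means, the mean susceptibility over the
#' class mask equals the assigned mean exactly; masking and mixing happen
#' later in [partial_volume_mix()].
#'
#' @param class_id Tissue class ID.
#' @param props A `property_volumes` object.
#' @param stats Output of [class_statistics()].
#' @param params Tissue parameter table (see [tissue_parameters()]).
#' @return 3D susceptibility array in ppm, defined everywhere.
#' @export
synth_susceptibility_class <- function(class_id, props, stats, params) {
  p <- params_row(params, class_id)
  if (p$a_ppm == 0 && p$b_ppm == 0 && p$c_ppm == 0)
    return(array(p$chi_mean_ppm, dim = dim(props$rho_water)))
  s <- stats_row(stats, class_id)
  p$chi_mean_ppm +
    p$a_ppm * (props$r2_norm - s$mean_r2_norm) +
    p$b_ppm * (props$rhoW_norm - s$mean_rhoW_norm) +
    p$c_ppm * (props$rhoF_norm - s$mean_rhoF_norm)
}

#' Partial-volume mixing of per-class susceptibility maps
#'
#' Smooths each binary class mask with an isotropic Gaussian (sigma in
#' voxels, truncated at 4 sigma, zero-padded), except for classes flagged
#' `smooth_excluded` (vessels, heart, gut and air keep sharp edges). The
#' smoothed masks are normalized to per-voxel probabilities and the mixed
#' susceptibility is their weighted combination, reproducing the smooth
#' tissue interfaces caused by partial-volume effects at abdominal
#' resolutions.
#'
#' @param chi_by_class Named list of per-class susceptibility arrays; names
#'   are class IDs.
#' @param labels A `tissue_labels` object.
#' @param params Tissue parameter table with a `smooth_excluded` column.
#' @param sigma Gaussian sigma in voxel units (default 0.5).
#' @return List with `chi` (mixed ppm map), `weights` (list of Mt arrays)
#'   and `total` (M, the per-voxel weight sum).
#' @export
partial_volume_mix <- function(chi_by_class, labels, params, sigma = 0.5) {
  if (sigma < 0) stop_qsm("sigma must be >= 0")
  lab <- labels$labels
  ids <- as.integer(names(chi_by_class))
  weights <- vector("list", length(ids))
  names(weights) <- names(chi_by_class)
  total <- array(0, dim = dim(lab))
  for (i in seq_along(ids)) {
    m <- (lab == ids[i]) * 1
    p <- params_row(params, ids[i])
    if (!p$smooth_excluded && sigma > 0) m <- gaussian_smooth(m, sigma)
    weights[[i]] <- m
    total <- total + m
  }
  if (any(total == 0))
    stop_qsm("partial_volume_mix: zero total weight at %d voxels",
             sum(total == 0))
  chi <- array(0, dim = dim(lab))
  for (i in seq_along(ids)) chi <- chi + chi_by_class[[i]] * weights[[i]]
  chi <- chi / total
  list(chi = chi, weights = weights, total = total)
}

#' Synthetic R2* map
#'
#' Per class: either keep the experimental R2* voxel-wise (unmodified
#' classes) or assign the configured class mean plus a zero-mean texture
#' term proportional to the centered normalized R2* (modified classes,
#' used for pathologic scenarios). Output is clipped at zero from below.
#'
#' @param props A `property_volumes` object.
#' @param labels A `tissue_labels` object.
#' @param stats Output of [class_statistics()].
#' @param params Tissue parameter table with `modify_r2`, `r2_mean_hz`,
#'   `a_r2_hz` columns.
#' @return 3D R2* array in 1/s.
#' @export
synth_r2star <- function(props, labels, stats, params) {
  lab <- labels$labels
  out <- props$r2star_exp
  mod <- params[params$modify_r2 == 1, ]
  for (i in seq_len(nrow(mod))) {
    id <- mod$class_id[i]
    m <- lab == id
    if (!any(m)) next
    if (is.na(mod$r2_mean_hz[i]) || mod$r2_mean_hz[i] < 0)
      stop_qsm("modified class %d needs a non-negative r2_mean_hz", id)
    s <- stats_row(stats, id)
    out[m] <- mod$r2_mean_hz[i] +
      mod$a_r2_hz[i] * (props$r2_norm[m] - s$mean_r2_norm)
  }
  pmax(out, 0)
}

#' Least-squares texture-weight initialization
#'
#' Recovers the three texture weights for one class by ordinary least
#' squares of the target susceptibility (minus the class mean) on the
#' mean-centered modulators over the class mask. Equivalent to minimizing
#' the nRMSE between the modelled and target susceptibility for that
#' class. Rank-deficient designs return the minimum-norm solution
#' (SVD pseudoinverse).
#'
#' @param chi_target 3D target susceptibility (ppm).
#' @param props A `property_volumes` object.
#' @param stats Output of [class_statistics()].
#' @param labels A `tissue_labels` object.
#' @param class_id Class to fit.
#' @param chi_mean Class mean subtracted from the target; defaults to the
#'   target's mean over the class mask.
#' @return Named numeric vector `c(a, b, c)` in ppm.
#' @export
fit_texture_weights <- function(chi_target, props, stats, labels, class_id,
                                chi_mean = NULL) {
  m <- labels$labels == class_id
  if (!any(m)) stop_qsm("fit_texture_weights: empty mask for class %d",
                        class_id)
  if (sum(m) < 4)
    stop_qsm("fit_texture_weights: class %d has fewer than 4 voxels",
             class_id)
  s <- stats_row(stats, class_id)
  X <- cbind(props$r2_norm[m] - s$mean_r2_norm,
             props$rhoW_norm[m] - s$mean_rhoW_norm,
             props$rhoF_norm[m] - s$mean_rhoF_norm)
  if (is.null(chi_mean)) chi_mean <- mean(chi_target[m])
  y <- chi_target[m] - chi_mean
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  stats::setNames(as.numeric(coef), c("a", "b", "c"))
}
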