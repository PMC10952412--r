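#' Abdominal tissue classes
#'
#' The phantom distinguishes 23 internal abdominal structures plus external
#' air. Label IDs are stable: 0 is external air and 1--23 follow the
#' internal-class order (aorta through the gas regions inside the
#' gastrointestinal tract). The pathologic-lobe scenario adds an extra
#' class, ID 24, carved out of the liver.
#'
#' @return A data frame with columns `class_id` and `class`.
#' @export
tissue_classes <- function() {
  data.frame(
    class_id = 0:24,
    class = c(
      "external_air", "aorta", "inferior_vena_cava", "right_kidney",
      "left_kidney", "liver", "spleen", "gallbladder", "esophagus",
      "stomach", "pancreas", "small_intestine", "large_intestine",
      "hepatic_veins", "portal_vein", "ribs", "vertebrae",
      "intervertebral_disks", "spinal_cord", "subcutaneous_fat",
      "visceral_fat", "heart", "muscle", "internal_air", "liver_lobe"
    ),
    stringsAsFactors = FALSE
  )
}

EXTERNAL_AIR_ID <- 0L
LOBE_CLASS_ID <- 24L

class_id_of <- function(name) {
  tab <- tissue_classes()
  id <- tab$class_id[match(name, tab$class)]
  if (any(is.na(id))) stop_qsm("unknown tissue class name: %s",
                               paste(name[is.na(id)], collapse = ", "))
  id
}

new_tissue_labels <- function(labels, voxel_size = c(2, 2, 2),
                              class_names = NULL) {
  if (any(voxel_size <= 0)) stop_qsm("voxel_size components must be > 0")
  if (is.null(class_names)) {
    tab <- tissue_classes()
    present <- sort(unique(as.integer(labels)))
    class_names <- stats::setNames(
      tab$class[match(present, tab$class_id)], present)
  }
  structure(
    list(labels = labels, class_names = class_names,
         voxel_size = as.numeric(voxel_size),
         external_air_id = EXTERNAL_AIR_ID),
    class = "tissue_labels")
}

#' @export
print.tissue_labels <- function(x, ...) {
  cat(sprintf("<tissue_labels> %s voxels @ %s mm, %d classes\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              length(x$class_names)))
  invisible(x)
}

# --- procedural geometry primitives -----------------------------------------

# All primitives paint `id` into `lab` (passed/returned by value) on an
# integer grid; centers/radii are in voxel units.
paint_ellipsoid <- function(lab, center, radii, id, within = NULL) {
  g <- axis_grid(seq_len(dim(lab)[1]), seq_len(dim(lab)[2]),
                 seq_len(dim(lab)[3]))
  m <- ((g$x - center[1]) / radii[1])^2 +
       ((g$y - center[2]) / radii[2])^2 +
       ((g$z - center[3]) / radii[3])^2 <= 1
  if (!is.null(within)) m <- m & within
  lab[m] <- id
  lab
}

# Tube along one axis: circular cross-section in the other two axes.
paint_tube <- function(lab, axis, center2, radius, id, span = NULL,
                       within = NULL) {
  d <- dim(lab)
  others <- setdiff(1:3, axis)
  g <- axis_grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  co <- list(g$x, g$y, g$z)
  m <- ((co[[others[1]]] - center2[1])^2 +
        (co[[others[2]]] - center2[2])^2) <= radius^2
  if (!is.null(span)) m <- m & co[[axis]] >= span[1] & co[[axis]] <= span[2]
  if (!is.null(within)) m <- m & within
  lab[m] <- id
  lab
}

#' Generate a procedural abdominal label volume
#'
#' Builds a deterministic synthetic anatomy from geometric primitives: an
#' elliptical body cross-section extruded along the axial (z / B0) axis, a
#' subcutaneous-fat shell, ellipsoidal organs, tubes for vessels, gut and
#' spine, muscle as the remaining body tissue and external air outside the
#' body. Organ placement is jittered by the seed, so different seeds give
#' different placements with the same class inventory.
#'
#' @param shape Integer 3-vector, each dimension at least 16. The third
#'   dimension is the axial / B0 axis.
#' @param seed Integer seed; generation is a pure function of
#'   `(shape, seed)`.
#' @param voxel_size Voxel edge lengths in mm.
#' @return A `tissue_labels` object containing all 23 internal classes.
#' @export
generate_label_volume <- function(shape, seed = 1L, voxel_size = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop_qsm("shape must be three integers, each >= 16")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(seed, "anatomy"))
  jit <- function(f) f + stats::runif(1, -0.02, 0.02)

  lab <- array(EXTERNAL_AIR_ID, dim = shape)
  g <- axis_grid(seq_len(nx), seq_len(ny), seq_len(nz))
  bx <- (nx + 1) / 2; by <- (ny + 1) / 2
  body <- ((g$x - bx) / (0.46 * nx))^2 + ((g$y - by) / (0.42 * ny))^2 <= 1
  inner <- ((g$x - bx) / (0.40 * nx))^2 + ((g$y - by) / (0.36 * ny))^2 <= 1

  lab[body] <- class_id_of("subcutaneous_fat")
  lab[inner] <- class_id_of("muscle")

  # coordinates helper: fractions of each dimension -> voxels
  vx <- function(f) 1 + f * (nx - 1)
  vy <- function(f) 1 + f * (ny - 1)
  vz <- function(f) 1 + f * (nz - 1)
  rx <- function(f) max(1.2, f * nx)
  ry <- function(f) max(1.2, f * ny)
  rz <- function(f) max(1.2, f * nz)

  ell <- function(lab, name, cf, rf, within = inner) {
    paint_ellipsoid(lab,
      c(vx(jit(cf[1])), vy(jit(cf[2])), vz(jit(cf[3]))),
      c(rx(rf[1]), ry(rf[2]), rz(rf[3])),
      class_id_of(name), within = within)
  }

  # large, early structures (later paints overwrite earlier ones)
  lab <- ell(lab, "visceral_fat",   c(0.50, 0.38, 0.35), c(0.26, 0.14, 0.22))
  lab <- ell(lab, "small_intestine",c(0.50, 0.50, 0.15), c(0.18, 0.12, 0.12))
  lab <- ell(lab, "liver",          c(0.32, 0.42, 0.58), c(0.20, 0.17, 0.26))
  lab <- ell(lab, "stomach",        c(0.64, 0.40, 0.62), c(0.10, 0.09, 0.12))
  lab <- ell(lab, "spleen",         c(0.78, 0.47, 0.55), c(0.06, 0.06, 0.10))
  lab <- ell(lab, "right_kidney",   c(0.30, 0.62, 0.35), c(0.06, 0.06, 0.10))
  lab <- ell(lab, "left_kidney",    c(0.70, 0.62, 0.35), c(0.06, 0.06, 0.10))
  lab <- ell(lab, "pancreas",       c(0.54, 0.52, 0.50), c(0.14, 0.045, 0.05))
  lab <- ell(lab, "gallbladder",    c(0.40, 0.33, 0.44), c(0.04, 0.04, 0.06))
  lab <- ell(lab, "heart",          c(0.46, 0.34, 0.95), c(0.11, 0.10, 0.12))

  # spine column: vertebrae with periodic intervertebral disks, cord inside
  spine_c <- c(vx(jit(0.50)), vy(jit(0.80)))
  lab <- paint_tube(lab, 3, spine_c, rx(0.055), class_id_of("vertebrae"),
                    within = body)
  vert <- lab == class_id_of("vertebrae")
  disk_period <- max(4L, round(nz / 10))
  zidx <- g$z
  disks <- vert & (zidx %% disk_period) < 2
  lab[disks] <- class_id_of("intervertebral_disks")
  lab <- paint_tube(lab, 3, spine_c, rx(0.018), class_id_of("spinal_cord"),
                    within = vert | disks)

  # ribs: short lateral tubes inside the muscle layer
  ribs_id <- class_id_of("ribs")
  for (fx in c(0.10, 0.90)) {
    lab <- paint_tube(lab, 3, c(vx(jit(fx)), vy(jit(0.52))), rx(0.025),
                      ribs_id, span = c(vz(0.2), vz(0.9)), within = body)
  }

  # vessels: vertical tubes; hepatic/portal veins inside the liver
  liver_m <- lab == class_id_of("liver")
  lab <- paint_tube(lab, 3, c(vx(jit(0.56)), vy(jit(0.64))), rx(0.028),
                    class_id_of("aorta"), within = inner)
  lab <- paint_tube(lab, 3, c(vx(jit(0.44)), vy(jit(0.64))), rx(0.028),
                    class_id_of("inferior_vena_cava"), within = inner)
  lab <- paint_tube(lab, 1, c(vy(jit(0.42)), vz(jit(0.62))), ry(0.020),
                    class_id_of("hepatic_veins"),
                    span = c(vx(0.15), vx(0.45)), within = liver_m)
  lab <- paint_tube(lab, 3, c(vx(jit(0.38)), vy(jit(0.46))), rx(0.018),
                    class_id_of("portal_vein"),
                    span = c(vz(0.40), vz(0.75)), within = liver_m)

  # esophagus: upper-abdomen vertical tube
  lab <- paint_tube(lab, 3, c(vx(jit(0.50)), vy(jit(0.40))), rx(0.018),
                    class_id_of("esophagus"),
                    span = c(vz(0.78), vz(1.0)), within = inner)

  # gut gas: large intestine tube across x with internal air core; a
  # second gas pocket in the stomach
  gut_c <- c(vy(jit(0.70)), vz(jit(0.18)))
  lab <- paint_tube(lab, 1, gut_c, ry(0.050), class_id_of("large_intestine"),
                    span = c(vx(0.2), vx(0.8)), within = inner)
  lab <- paint_tube(lab, 1, gut_c, ry(0.022), class_id_of("internal_air"),
                    span = c(vx(0.25), vx(0.75)), within = inner)
  lab <- ell(lab, "internal_air", c(0.64, 0.38, 0.66), c(0.04, 0.035, 0.05),
             within = lab == class_id_of("stomach"))

  out <- new_tissue_labels(lab, voxel_size = voxel_size)
  missing <- setdiff(1:23, unique(as.integer(lab)))
  if (length(missing)) {
    tab <- tissue_classes()
    stop_qsm("shape %s too small to place classes: %s",
             paste(shape, collapse = "x"),
             paste(tab$class[match(missing, tab$class_id)], collapse = ", "))
  }
  out
}

# save/restore the RNG state so generators are pure in (shape, seed)
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# --- property volumes -------------------------------------------------------

# per-class signal/relaxation base levels used by the procedural generator;
# rough magnitudes typical of 3T abdominal GRE
property_baseline <- function() {
  df <- tissue_classes()
  df <- df[df$class_id <= 23, ]
  water <- c(0, 0.95, 0.95, 0.85, 0.85, 0.80, 0.85, 0.90, 0.75, 0.70,
             0.75, 0.65, 0.55, 0.95, 0.95, 0.35, 0.40, 0.70, 0.80,
             0.12, 0.15, 0.80, 0.85, 0)
  fat <- c(0, 0.03, 0.03, 0.05, 0.05, 0.08, 0.04, 0.05, 0.04, 0.05,
           0.06, 0.06, 0.08, 0.03, 0.03, 0.30, 0.35, 0.15, 0.05,
           0.90, 0.85, 0.05, 0.04, 0)
  r2 <- c(0, 25, 25, 32, 32, 42, 38, 28, 30, 31,
          30, 33, 35, 26, 26, 95, 110, 45, 28,
          55, 50, 35, 30, 0)
  df$water <- water; df$fat <- fat; df$r2 <- r2
  df
}

new_property_volumes <- function(rho_water, rho_fat, r2star_exp, labels) {
  body <- labels$labels != labels$external_air_id
  structure(
    list(rho_water = rho_water, rho_fat = rho_fat, r2star_exp = r2star_exp,
         r2_norm = normalize_unit(r2star_exp, body),
         rhoW_norm = normalize_unit(rho_water, body),
         rhoF_norm = normalize_unit(rho_fat, body),
         body_mask = body),
    class = "property_volumes")
}

#' @export
print.property_volumes <- function(x, ...) {
  cat(sprintf("<property_volumes> %s voxels; R2* range %.1f-%.1f 1/s\n",
              paste(dim(x$rho_water), collapse = "x"),
              min(x$r2star_exp), max(x$r2star_exp)))
  invisible(x)
}

#' Generate water/fat/R2* property volumes for a label volume
#'
#' Assigns per-class mean water and fat signal magnitudes (fat-dominant
#' classes get high fat signal) and R2* levels, then adds smooth spatially
#' correlated texture: Gaussian white noise low-pass filtered with a
#' 2-voxel kernel and scaled to +/-20% of the class mean, so every internal
#' class has non-degenerate within-class variation. Air carries no signal.
#' Unit-normalized counterparts (min-max over the body mask) are computed
#' with [normalize_unit()].
#'
#' @param labels A `tissue_labels` object.
#' @param seed Integer seed; output is a pure function of `(labels, seed)`.
#' @return A `property_volumes` object.
#' @export
generate_property_volumes <- function(labels, seed = 1L) {
  stopifnot(inherits(labels, "tissue_labels"))
  lab <- labels$labels
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(seed, "properties"))

  texture <- function() {
    n <- gaussian_smooth(array(stats::rnorm(length(lab)), dim = dim(lab)), 2)
    n / max(stats::sd(n), .Machine$double.eps)
  }
  base <- property_baseline()
  assemble <- function(col) {
    tex <- texture()
    out <- array(0, dim = dim(lab))
    for (i in seq_len(nrow(base))) {
      m <- lab == base$class_id[i]
      if (!any(m)) next
      mu <- base[[col]][i]
      out[m] <- mu * (1 + 0.2 * tex[m])
    }
    pmax(out, 0)
  }
  rho_water <- assemble("water")
  rho_fat <- assemble("fat")
  r2star <- assemble("r2")
  air <- lab == labels$external_air_id | lab == class_id_of("internal_air")
  rho_water[air] <- 0; rho_fat[air] <- 0; r2star[air] <- 0
  new_property_volumes(rho_water, rho_fat, r2star, labels)
}

# --- NIfTI I/O --------------------------------------------------------------

write_vol <- function(arr, path, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an anatomy (labels + properties) to NIfTI files
#'
#' @param labels A `tissue_labels` object.
#' @param props A `property_volumes` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_anatomy <- function(labels, props, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- labels$voxel_size
  paths <- c(
    labels = file.path(dir, "labels.nii.gz"),
    rho_water = file.path(dir, "rho_water.nii.gz"),
    rho_fat = file.path(dir, "rho_fat.nii.gz"),
    r2star = file.path(dir, "r2star.nii.gz"))
  write_vol(array(as.integer(labels$labels), dim(labels$labels)),
            paths["labels"], vs)
  write_vol(props$rho_water, paths["rho_water"], vs)
  write_vol(props$rho_fat, paths["rho_fat"], vs)
  write_vol(props$r2star_exp, paths["r2star"], vs)
  invisible(paths)
}

#' Load an anatomy from NIfTI files
#'
#' Reads a label volume and co-registered water/fat/R2* property volumes.
#' Voxel size is taken from the NIfTI header. All volumes must share the
#' grid shape, and every label ID must appear in the configured class
#' table.
#'
#' @param label_path Path to the integer label NIfTI.
#' @param property_paths Named character vector with entries `rho_water`,
#'   `rho_fat`, `r2star`.
#' @return A list with elements `labels` and `props`.
#' @export
load_anatomy <- function(label_path, property_paths) {
  need <- c("rho_water", "rho_fat", "r2star")
  if (!all(need %in% names(property_paths)))
    stop_qsm("property_paths must name: %s", paste(need, collapse = ", "))
  img <- RNifti::readNifti(label_path)
  lab <- array(as.integer(round(as.array(img))), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  vols <- lapply(property_paths[need], function(p) {
    v <- RNifti::readNifti(p)
    if (!identical(dim(v), dim(lab)))
      stop_qsm("property volume %s shape %s does not match labels %s",
               p, paste(dim(v), collapse = "x"),
               paste(dim(lab), collapse = "x"))
    array(as.numeric(v), dim = dim(lab))
  })
  known <- tissue_classes()$class_id
  bad <- setdiff(unique(as.integer(lab)), known)
  if (length(bad))
    stop_qsm("label volume contains IDs absent from the class table: %s",
             paste(sort(bad), collapse = ", "))
  labels <- new_tissue_labels(lab, voxel_size = vs)
  props <- new_property_volumes(vols$rho_water, vols$rho_fat, vols$r2star,
                                labels)
  list(labels = labels, props = props)
}
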