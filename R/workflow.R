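#' Scenario configuration
#'
#' Bundles everything [run_pipeline()] needs: scenario preset, grid shape,
#' seed, acquisition protocol, noise level, kernel mode and flags.
#'
#' @param scenario `"HS"`, `"PL"` or `"IO"`, or a path to a custom tissue
#'   table.
#' @param shape Grid dimensions (default `c(64, 64, 48)`).
#' @param voxel_size Voxel edge lengths, mm.
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param protocol_name `"P1"` or `"P2"`.
#' @param peak_snr Peak SNR for noise injection; `NULL` for noiseless.
#' @param kernel_mode `"discrete"` (default) or `"continuous"`.
#' @param b0 Field strength, Tesla.
#' @param gamma Gyromagnetic ratio, Hz/T.
#' @param sigma Partial-volume smoothing sigma, voxels.
#' @param lobe Lobe geometry for PL: list with `center` and `radii` as
#'   fractions of the grid, or `NULL` for an automatic placement inside
#'   the liver.
#' @param background_field Simulate the background-source field on the
#'   3x extended grid.
#' @param perfect_removal Assume perfect background-field removal: zero
#'   and mask the background-source classes before forward simulation.
#' @param renormalize_fat Rescale the fat amplitudes to unit sum.
#' @param tkd_threshold Threshold for the baseline dipole inversion.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = "HS", shape = c(64, 64, 48),
                            voxel_size = c(2, 2, 2), seed = 1L,
                            protocol_name = "P2", peak_snr = 100,
                            kernel_mode = "discrete", b0 = 3,
                            gamma = GAMMA_HZ_PER_T, sigma = 0.5,
                            lobe = NULL, background_field = FALSE,
                            perfect_removal = TRUE,
                            renormalize_fat = FALSE, tkd_threshold = 0.2) {
  structure(list(scenario = scenario, shape = as.integer(shape),
                 voxel_size = voxel_size, seed = as.integer(seed),
                 protocol_name = protocol_name, peak_snr = peak_snr,
                 kernel_mode = kernel_mode, b0 = b0, gamma = gamma,
                 sigma = sigma, lobe = lobe,
                 background_field = background_field,
                 perfect_removal = perfect_removal,
                 renormalize_fat = renormalize_fat,
                 tkd_threshold = tkd_threshold),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file; keys as in [scenario_config()].
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  do.call(scenario_config, yaml::read_yaml(path))
}

#' Insert the pathologic lobe class into the liver
#'
#' Carves an ellipsoidal region out of the liver mask and relabels it as
#' the lobe class (ID 24). The ellipsoid is restricted to liver voxels;
#' it is an error if it does not land inside the liver.
#'
#' @param labels A `tissue_labels` object.
#' @param center Ellipsoid center as fractions of the grid; `NULL` places
#'   it at the liver centroid.
#' @param radii Ellipsoid semi-axes as fractions of the grid dimensions.
#' @return A new `tissue_labels` with the lobe class present.
#' @export
insert_lobe <- function(labels, center = NULL,
                        radii = c(0.07, 0.07, 0.10)) {
  lab <- labels$labels
  liver <- lab == class_id_of("liver")
  if (!any(liver)) stop_qsm("no liver voxels to host the lobe")
  d <- dim(lab)
  if (is.null(center)) {
    # liver voxel nearest the liver centroid (centroid itself can fall in
    # a carved-out vessel)
    idx <- which(liver, arr.ind = TRUE)
    ctr <- colMeans(idx)
    center_vox <- idx[which.min(colSums((t(idx) - ctr)^2)), ]
  } else {
    center_vox <- 1 + center * (d - 1)
    if (!liver[matrix(round(center_vox), 1)])
      stop_qsm("lobe center is not inside the liver mask")
  }
  g <- axis_grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ell <- ((g$x - center_vox[1]) / pmax(1.2, radii[1] * d[1]))^2 +
         ((g$y - center_vox[2]) / pmax(1.2, radii[2] * d[2]))^2 +
         ((g$z - center_vox[3]) / pmax(1.2, radii[3] * d[3]))^2 <= 1
  lobe <- ell & liver
  if (!any(lobe)) stop_qsm("lobe ellipsoid does not intersect the liver")
  lab[lobe] <- LOBE_CLASS_ID
  new_tissue_labels(lab, voxel_size = labels$voxel_size)
}

#' Build a susceptibility/R2* scenario
#'
#' Applies the texture model with the scenario's tissue table: computes
#' class statistics, per-class susceptibility maps, partial-volume mixed
#' susceptibility and the synthetic R2* map. For PL the lobe class is
#' inserted into the liver before synthesis; for IO the compromised
#' classes (liver, spleen, pancreas, vertebrae) carry modified
#' susceptibility and R2* parameters via the preset table.
#'
#' @param labels A `tissue_labels` object.
#' @param props A `property_volumes` object.
#' @param config A `scenario_config`.
#' @return List: `labels` (with lobe for PL), `params`, `stats`,
#'   `chi_class` (per-class maps), `chi_mixed` (ppm), `r2star` (1/s),
#'   `body_mask`, `background_mask` (background-source voxels),
#'   `eval_mask` (body minus internal background sources).
#' @export
build_scenario <- function(labels, props, config = scenario_config()) {
  params <- tissue_parameters(config$scenario)
  if (identical(config$scenario, "PL")) {
    labels <- insert_lobe(labels,
                          center = config$lobe$center,
                          radii = if (is.null(config$lobe$radii))
                            c(0.07, 0.07, 0.10) else config$lobe$radii)
  }
  lab <- labels$labels
  present <- sort(unique(as.integer(lab)))
  missing <- setdiff(present, params$class_id)
  if (length(missing))
    stop_qsm("tissue table lacks rows for classes: %s",
             paste(missing, collapse = ", "))
  stats <- class_statistics(props, labels, class_ids = present)
  chi_class <- lapply(present, function(id)
    synth_susceptibility_class(id, props, stats, params))
  names(chi_class) <- present
  mix <- partial_volume_mix(chi_class, labels, params, sigma = config$sigma)
  r2 <- synth_r2star(props, labels, stats, params)

  body <- lab != labels$external_air_id
  bg_ids <- params$class_id[params$background_source == 1]
  background <- array(lab %in% bg_ids, dim = dim(lab))
  list(labels = labels, params = params, stats = stats,
       chi_class = chi_class, chi_mixed = mix$chi,
       pv_weights = mix$weights, pv_total = mix$total, r2star = r2,
       body_mask = body, background_mask = background,
       eval_mask = body & !background)
}

#' Run the full phantom pipeline
#'
#' Orchestrates anatomy generation, scenario synthesis, field simulation,
#' signal simulation, noise injection, baseline reconstruction and
#' metrics. Under the perfect background-removal assumption (the
#' default), background-source voxels (air, large intestine) are zeroed
#' and masked before the susceptibility map is demeaned and
#' forward-simulated; with `background_field = TRUE` the total field is
#' additionally computed on the 3x background-extended grid and cropped
#' back. Every stage is deterministic in `(config, seed)`.
#'
#' @param config A `scenario_config`.
#' @param output_dir Optional directory; when given, all volumes are
#'   written as NIfTI plus a JSON manifest with checksums.
#' @return List with the ground-truth maps, the simulated series, the
#'   reconstructions, and a `metric_report`.
#' @export
run_pipeline <- function(config = scenario_config(), output_dir = NULL) {
  labels <- generate_label_volume(config$shape, seed = config$seed,
                                  voxel_size = config$voxel_size)
  props <- generate_property_volumes(labels, seed = config$seed)
  scen <- build_scenario(labels, props, config)

  chi_local <- scen$chi_mixed
  chi_local[!scen$eval_mask] <- 0
  chi_local <- demean(chi_local, scen$eval_mask)

  field_total <- NULL
  if (isTRUE(config$background_field)) {
    chi_bg <- scen$chi_mixed
    chi_bg[!scen$background_mask] <- 0
    ext <- extend_for_background(chi_local + chi_bg)
    ft <- forward_field(ext, voxel_size = config$voxel_size,
                        kernel_mode = config$kernel_mode, b0 = config$b0,
                        gamma = config$gamma)
    field_total <- new_field_map(crop_background_extension(ft$field),
                                 b0 = config$b0, gamma = config$gamma)
  }
  field_local <- forward_field(chi_local, voxel_size = config$voxel_size,
                               kernel_mode = config$kernel_mode,
                               b0 = config$b0, gamma = config$gamma)

  r2star <- scen$r2star
  sim_props <- props
  if (isTRUE(config$perfect_removal)) {
    drop <- !scen$eval_mask
    sim_props$rho_water[drop] <- 0
    sim_props$rho_fat[drop] <- 0
    r2star[drop] <- 0
  }
  sim_field <- if (isTRUE(config$background_field) &&
                   !isTRUE(config$perfect_removal))
    field_total else field_local
  proto <- protocol(config$protocol_name, b0 = config$b0,
                    gamma = config$gamma)
  fat <- fat_model(renormalize = config$renormalize_fat)
  echoes <- simulate_echoes(sim_props, r2star, sim_field, proto, fat)
  noisy <- add_complex_noise(echoes, peak_snr = config$peak_snr,
                             seed = config$seed)

  fit <- fit_fieldmap(noisy)
  weight <- fidelity_weight(noisy)
  qsm <- tkd_inversion(fit$field, scen$eval_mask,
                       threshold = config$tkd_threshold,
                       voxel_size = config$voxel_size,
                       kernel_mode = "continuous")
  r2fit <- fit_r2star_loglinear(noisy, mask = scen$eval_mask)

  scale <- if (is.null(noisy$noise)) 1 else noisy$noise$scale
  report <- metric_report(list(
    fieldmap = list(x = fit$field$field, ref = sim_field$field,
                    mask = scen$eval_mask),
    r2star = list(x = r2fit$r2star, ref = r2star, mask = scen$eval_mask),
    qsm = list(x = qsm, ref = chi_local, mask = scen$eval_mask,
               is_qsm = TRUE)))

  result <- list(config = config, labels = scen$labels, props = props,
                 scenario = scen, chi_local = chi_local,
                 field_local = field_local, field_total = field_total,
                 r2star = r2star, echoes = echoes, noisy = noisy,
                 recon = list(field = fit, qsm = qsm, r2star = r2fit,
                              weight = weight, signal_scale = scale),
                 report = report)
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- result$config$voxel_size
  vol_paths <- c(
    labels = "labels.nii.gz", chi_local = "chi_local.nii.gz",
    field_local = "field_local_hz.nii.gz", r2star = "r2star_gt.nii.gz",
    qsm_tkd = "qsm_tkd.nii.gz", field_fit = "field_fit_hz.nii.gz",
    r2star_fit = "r2star_fit.nii.gz", fidelity_weight = "weight.nii.gz",
    mask_eval = "mask_eval.nii.gz")
  arrays <- list(
    labels = array(as.integer(result$labels$labels),
                   dim(result$labels$labels)),
    chi_local = result$chi_local,
    field_local = result$field_local$field,
    r2star = result$r2star,
    qsm_tkd = result$recon$qsm,
    field_fit = result$recon$field$field$field,
    r2star_fit = result$recon$r2star$r2star,
    fidelity_weight = result$recon$weight,
    mask_eval = result$scenario$eval_mask * 1)
  files <- character(0)
  for (nm in names(vol_paths)) {
    p <- file.path(output_dir, vol_paths[[nm]])
    write_vol(arrays[[nm]], p, vs)
    files <- c(files, p)
  }
  if (!is.null(result$field_total)) {
    p <- file.path(output_dir, "field_total_hz.nii.gz")
    write_vol(result$field_total$field, p, vs)
    files <- c(files, p)
  }
  files <- c(files, write_echo_series(result$noisy,
                                      file.path(output_dir, "echoes"), vs))
  report_path <- file.path(output_dir, "metrics.json")
  jsonlite::write_json(
    list(metrics = as.data.frame(result$report),
         constants = attr(result$report, "constants")),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, report_path)
  manifest <- list(
    config = unclass(result$config), seed = result$config$seed,
    package_version = as.character(utils::packageVersion("qsmphantom")),
    files = data.frame(
      path = sub(paste0("^", normalizePath(output_dir), "/"), "",
                 normalizePath(files)),
      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(files)
}
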