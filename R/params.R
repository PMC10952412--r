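#' Tissue parameter tables for the scenario presets
#'
#' Loads the per-class susceptibility and R2* model parameters driving the
#' texture synthesis. Three presets ship with the package:
#' \describe{
#'   \item{HS}{healthy subject -- literature/experimental class means with
#'     texture weights; R2* kept as the experimental map everywhere.}
#'   \item{PL}{pathologic lobe -- whole-mask class means (lower inter-class
#'     contrast) plus an extra hepatic-lobe class with mean susceptibility
#'     0.2 ppm and mean R2* 150 1/s.}
#'   \item{IO}{iron overload -- liver, spleen, pancreas and vertebrae get
#'     strongly increased susceptibility and R2* with their own texture
#'     weights; other classes as in HS.}
#' }
#' Air classes and the large intestine carry fixed susceptibilities
#' (9.2 / 4.84 / 4.84 ppm) with no texture modulation, are excluded from
#' boundary smoothing, and are the background-field sources.
#'
#' @param scenario One of `"HS"`, `"PL"`, `"IO"`, or a path to a custom
#'   CSV/YAML file with the same columns.
#' @return Data frame with columns `class_id`, `class`, `chi_mean_ppm`,
#'   `a_ppm`, `b_ppm`, `c_ppm`, `r2_mean_hz`, `a_r2_hz`, `modify_r2`,
#'   `smooth_excluded`, `background_source`, `stats_excluded`.
#' @export
tissue_parameters <- function(scenario = "HS") {
  path <- if (scenario %in% c("HS", "PL", "IO")) {
    system.file("extdata", "params",
                sprintf("tissue_table_%s.csv", scenario),
                package = "qsmphantom", mustWork = TRUE)
  } else scenario
  if (!file.exists(path)) stop_qsm("no tissue table: %s", path)
  tab <- if (grepl("\\.ya?ml$", path)) {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("class_id", "class", "chi_mean_ppm", "a_ppm", "b_ppm", "c_ppm",
            "r2_mean_hz", "a_r2_hz", "modify_r2", "smooth_excluded",
            "background_source", "stats_excluded")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_qsm("tissue table %s lacks columns: %s", path,
             paste(missing, collapse = ", "))
  tab
}
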