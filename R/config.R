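#' Default pipeline configuration
#'
#' Hierarchical list of every tunable used by the CLI and the high-level
#' drivers: Logan fit window and reference washout rate, IDAIF optimizer
#' settings and parent-fraction parameters, PSF width and ROI target
#' volumes, and the forward-model grid step.
#'
#' @return Nested named list.
#' @export
idaif_default_config <- function() {
  list(
    logan = list(window_min = 30, window_max = 60, k2prime = 0.16),
    idaif = list(t_late = 40, n_starts = 5, seed = 1,
                 smooth_derivative = FALSE,
                 parent_fraction = list(form = "exp_plateau", c = 0.05,
                                        lambda = 0.15,
                                        blood_plasma_ratio = 1,
                                        direction = "plasma_to_blood")),
    kinetic = list(n_starts = 3, seed = 1),
    roi = list(fwhm_mm = 8, cc_a = 16, cc_b = 100, percentile = 99,
               components = 1),
    model = list(dt_internal = 1 / 120)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML configuration file over the defaults
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Config list (defaults overridden by the file's keys).
#' @export
load_config <- function(path = NULL) {
  cfg <- idaif_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

pf_from_config <- function(cfg) {
  p <- cfg$idaif$parent_fraction
  parent_fraction_model(form = p$form, c = p$c, lambda = p$lambda,
                        blood_plasma_ratio = p$blood_plasma_ratio,
                        direction = p$direction)
}
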