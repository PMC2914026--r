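#' Run configuration
#'
#' A nested parameter list mirroring every tunable of the toolkit --
#' diffusion, TRON, cartoon, overlay, centre-surround, scotoma, retinal
#' geometry constants, RNG seed and output directory -- with defaults equal
#' to the published operating point (K = 0.1, tau = 0.1/0.4, phi = 3/25,
#' N = 8 bins, retina 42 mm / fovea 1 mm / macula 6 mm). The configuration
#' round-trips losslessly through YAML.
#'
#' @return A nested named list of class `"retinasim_config"`.
#' @export
#' @examples
#' cfg <- default_run_config()
#' cfg$tron$k_threshold
default_run_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = ".",
    diffusion = list(iterations = 15L, dt = 1 / 7, kappa = 0.1,
                     stopping = "exponential"),
    tron = list(k_threshold = 0.1, pyramid_levels = 3L),
    cartoon = list(n_bins = 8L, tau_min = 0.1, tau_max = 0.4,
                   phi_lo = 3, phi_hi = 25),
    overlay = list(base_mode = "original", edge_opacity = 1),
    retina = list(retina_mm = 42, fovea_mm = 1, macula_mm = 6,
                  sigma_h = 1, sigma_c = 1, sigma_ratio = 2,
                  kernel_ratio = 5),
    scotoma = list(size_s = 1, degree_d = 1)),
    class = "retinasim_config")
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @param config A `"retinasim_config"` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]])) {
      for (sub in names(cfg[[nm]])) base[[nm]][[sub]] <- cfg[[nm]][[sub]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

config_params <- function(cfg) {
  dp <- diffusion_params(cfg$diffusion$iterations, cfg$diffusion$dt,
                         cfg$diffusion$kappa, cfg$diffusion$stopping)
  list(
    diffusion = dp,
    tron = tron_params(cfg$tron$k_threshold, dp, cfg$tron$pyramid_levels),
    cartoon = cartoon_params(cfg$cartoon$n_bins, cfg$cartoon$tau_min,
                             cfg$cartoon$tau_max, cfg$cartoon$phi_lo,
                             cfg$cartoon$phi_hi, dp),
    overlay = overlay_params(cfg$overlay$base_mode,
                             edge_opacity = cfg$overlay$edge_opacity),
    dog = dog_params(cfg$retina$sigma_c, cfg$retina$sigma_ratio,
                     cfg$retina$kernel_ratio))
}
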