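#' Read and validate a run configuration
#'
#' Configurations are structured YAML files with sections `rsa_synth`,
#' `soil`, `root_hydraulics`, `transport`, `pipeline`, `inversion` plus the
#' top-level keys `seed` and `output_dir`. Unknown sections or keys are
#' rejected before any computation; missing keys fall back to the package
#' defaults.
#'
#' @param path YAML file path, or `NULL` for the all-defaults configuration.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    output_dir = "rootflux_out",
    rsa_synth = list(),
    soil = list(theta_r = 0.03, theta_s = 0.37, alpha = 0.025, n = 5,
                Ks = 500, l = 0.5, bulk_density = 1.62, theta0 = 0.35),
    root_hydraulics = list(kr_T = 1e-4, kr_Ly = 1e-2, kr_Lo = 1e-3,
                           Kx_T = 1, Kx_Ly = 1e-1, Kx_Lo = 1e-2,
                           age_threshold = 5),
    transport = list(Dm = 0.35, alpha_L = 0.25, alpha_T = 0.025,
                     n_particles = 10000),
    pipeline = list(dx = 0.5, dt_max = 0.05, t_start = 18, t_end = 25,
                    scenario = "full_experiment", transpiration_peak = 60,
                    irrigation_flux = 35, merge_width = 0.5, noise_sd = 0),
    inversion = list(n_kr = 3, n_Kx = 2, t_start = 23, t_end = 25,
                     refine = TRUE)
  )
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) abort("config must be a YAML mapping")
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    abort(paste("unknown config section(s):", paste(bad, collapse = ", ")))
  }
  for (sec in names(user)) {
    if (is.list(defaults[[sec]]) && length(defaults[[sec]]) > 0) {
      badkey <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(badkey) > 0) {
        abort(sprintf("unknown key(s) in [%s]: %s", sec,
                      paste(badkey, collapse = ", ")))
      }
    }
  }
  cfg <- modifyList(defaults, user)
  if (!is.numeric(cfg$seed)) abort("seed must be numeric")
  structure(cfg, class = "run_config")
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration, the MD5 of its canonical form, the
#' derived per-module seeds, package and R versions, and a timestamp -
#' enough to reproduce the run.
#'
#' @param cfg a `run_config`.
#' @param dir output directory.
#' @param extra optional named list of extra entries.
#' @return Manifest file path, invisibly.
#' @export
write_manifest <- function(cfg, dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- c(list(
    config = unclass(cfg),
    config_md5 = hash,
    seeds = as.list(derive_seeds(cfg$seed)),
    package_version = as.character(utils::packageVersion("rootflux")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
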