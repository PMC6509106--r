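#' Assemble a synthetic virtual experiment
#'
#' Convenience constructor bundling everything a forward run needs: a seeded
#' synthetic root architecture series, the experiment timeline, the
#' voxelized column with its initial water content, and the soil/transport
#' parameter sets. This is the synthetic twin used for inversion tests and
#' proxy analyses.
#'
#' @param seed seed controlling the architecture (and, shifted, transport).
#' @param dx voxel edge (cm).
#' @param theta0 initial uniform water content (cm3/cm3).
#' @param n_particles particle budget (set 0/`NULL` to skip transport).
#' @param scenario,transpiration_peak,irrigation_flux passed to
#'   [generate_timeline()].
#' @param t_start,t_end simulated window (DAS).
#' @param rsa_config optional `rsa_gen_config` override (its seed is set
#'   from `seed`).
#' @param soil a `soil_medium`.
#' @return List with `rsa_series`, `timeline`, `grid`, `soil`, `transport`,
#'   `seed`, `t0`, `t1`.
#' @export
virtual_experiment <- function(seed = 1L, dx = 0.5, theta0 = 0.35,
                               n_particles = 20000,
                               scenario = "full_experiment",
                               transpiration_peak = 60,
                               irrigation_flux = 35,
                               t_start = 18, t_end = 25,
                               rsa_config = NULL,
                               soil = soil_medium()) {
  seeds <- derive_seeds(seed)
  cfg <- if (is.null(rsa_config)) rsa_gen_config(seed = seeds["rsa"]) else {
    rsa_config$seed <- seeds["rsa"]
    rsa_config
  }
  snap <- sort(unique(c(floor(t_start):ceiling(t_end), t_start, t_end)))
  snap <- snap[snap >= t_start & snap <= t_end]
  rsa_series <- generate_rsa_series(cfg, snapshot_times = snap)
  timeline <- generate_timeline(scenario,
                                transpiration_peak = transpiration_peak,
                                irrigation_flux = irrigation_flux,
                                t_start = t_start, t_end = t_end)
  grid <- build_column_grid(diameter = 2 * cfg$column_radius,
                            height = cfg$column_height, dx = dx,
                            theta0 = theta0, vg = soil$vg)
  tp <- if (is.null(n_particles) || n_particles < 1) NULL else {
    transport_params(n_particles = n_particles, seed = seeds["transport"])
  }
  list(rsa_series = rsa_series, timeline = timeline, grid = grid,
       soil = soil, transport = tp, seed = seed,
       seeds = seeds, t0 = t_start, t1 = t_end)
}

#' Derive per-module random streams from one global seed
#'
#' Documented splitting rule: `module_seed = (seed * 7919 + offset) mod
#' (2^31 - 1)` with offsets 1 (architecture), 2 (transport), 3 (observation
#' noise).
#'
#' @param seed integer global seed.
#' @export
derive_seeds <- function(seed) {
  base <- (as.numeric(seed) * 7919) %% (2^31 - 1)
  c(rsa = as.integer((base + 1) %% (2^31 - 1)),
    transport = as.integer((base + 2) %% (2^31 - 1)),
    noise = as.integer((base + 3) %% (2^31 - 1)))
}

#' Forward-runner factory for inversion
#'
#' Returns a deterministic closure mapping a `hydraulic_params` to the
#' simulated tracer observation map at the end of the experiment window, as
#' required by [grid_search()] and [sensitivity_cross_sections()]. Each call
#' restarts from the experiment's initial state and a fixed transport seed.
#'
#' @param ex a [virtual_experiment()] list.
#' @param t0,t1 window (DAS), default the experiment's.
#' @param initial_concentration optional initial tracer field.
#' @param merge_width observation merged-voxel width (cm).
#' @param dt_max coupling step (d).
#' @param metric `"tracer"` (concentration map at `t1`) or `"wud"`
#'   (cumulative uptake density map over the window).
#' @return `function(params) -> observation_map`.
#' @export
make_forward_runner <- function(ex, t0 = ex$t0, t1 = ex$t1,
                                initial_concentration = NULL,
                                merge_width = 0.5, dt_max = 0.05,
                                metric = c("tracer", "wud")) {
  metric <- match.arg(metric)
  force(ex)
  function(params) {
    transport <- if (metric == "tracer") ex$transport else NULL
    run <- run_forward(ex$rsa_series, ex$timeline, params,
                       soil = ex$soil, transport = transport,
                       grid = ex$grid, t0 = t0, t1 = t1, dt_max = dt_max,
                       initial_concentration = initial_concentration,
                       seed = ex$seeds["transport"])
    s <- state_at(run, t1)
    fld <- if (metric == "tracer") s$conc else s$cum_wud
    observe(fld, ex$grid, merge_width = merge_width, timestamp = s$t)
  }
}
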