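#' Run the coupled forward virtual experiment
#'
#' Time-marches the coupled system between `t0` and `t1` (DAS): at every
#' step the root architecture is interpolated to the current time, root
#' hydraulic parameters are assigned by order and age, the xylem network is
#' solved under the flux-controlled transpiration demand, the resulting
#' uptake sink enters the Richards step, and the updated water content and
#' Darcy flux fields drive tracer injection and random-walk transport.
#' Boundary water flows are weighted by the grid's `area_ratio` before
#' application. States (theta, h, concentration, cumulative water uptake
#' density) are archived at the end of each nightly scan window and at `t1`.
#'
#' @param rsa_series list of `root_system` snapshots covering `[t0, t1]`.
#' @param timeline a `boundary_timeline`.
#' @param params a `hydraulic_params`.
#' @param soil a `soil_medium` (or `vg_params`).
#' @param transport a `transport_params`, or `NULL` to skip tracer
#'   transport (water and uptake only).
#' @param grid a `soil_grid`; its `theta`/`h` fields give the initial state.
#' @param t0,t1 simulated window (DAS).
#' @param dt_max largest coupling step (d); the Richards solver sub-steps
#'   adaptively below this.
#' @param initial_concentration optional 3-d array (mmol/l) converted into
#'   particles at `t0`.
#' @param seed seed for the transport random stream.
#' @param verbose print progress.
#' @return A `forward_run` object: list with `states` (one entry per archive
#'   time: `t`, `theta`, `h`, `conc`, `cum_wud` in cm3/cm3 since `t0`),
#'   `uptake_by_order` (tibble of cumulative uptake, cm3, per order and
#'   archive time), `uptake_by_segment` (cumulative cm3 keyed by final
#'   segment id), `ledger` (water bookkeeping tibble), `effluent_water`,
#'   `particles`, `grid`, and the call settings.
#' @export
run_forward <- function(rsa_series, timeline, params, soil = soil_medium(),
                        transport = transport_params(), grid,
                        t0 = min(vapply(rsa_series, system_time, numeric(1))),
                        t1 = max(vapply(rsa_series, system_time, numeric(1))),
                        dt_max = 0.025, initial_concentration = NULL,
                        seed = NULL, verbose = FALSE) {
  vg <- if (inherits(soil, "soil_medium")) soil$vg else soil
  if (any(is.na(grid$theta[grid$mask]))) {
    abort("grid has no initial water content; call grid_set_theta() first")
  }
  ar <- grid$area_ratio
  use_particles <- !is.null(transport)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  if (!is.null(seed)) set.seed(seed) else if (use_particles) {
    set.seed(transport$seed)
  }

  # particle mass: expected total injected mass over the window / budget
  particles <- NULL
  if (use_particles) {
    inj <- timeline %>%
      mutate(ts = pmax(.data$t_start, t0), te = pmin(.data$t_end, t1)) %>%
      filter(.data$te > .data$ts)
    expected_mass <- sum(inj$irrigation_flux * ar *
                           inj$irrigation_concentration *
                           (inj$te - inj$ts)) * 1e-3
    init_mass <- if (is.null(initial_concentration)) 0 else {
      sum(initial_concentration[grid$mask] * grid$theta[grid$mask],
          na.rm = TRUE) * voxel_volume(grid) / 1000
    }
    mpp <- max(expected_mass + init_mass, 1e-12) / transport$n_particles
    particles <- particle_ensemble(mpp)
    if (!is.null(initial_concentration)) {
      particles <- particles_from_field(initial_concentration, grid, particles)
    }
  }

  # step edges: timeline event boundaries + archive times, subdivided;
  # states are kept at scan ends, at whole days (daily imaging) and at t1
  archive_times <- sort(unique(c(scan_times(timeline),
                                 ceiling(t0):floor(t1))))
  archive_times <- sort(unique(c(archive_times[archive_times > t0 + 1e-9 &
                                                 archive_times <= t1 + 1e-9], t1)))
  edges <- sort(unique(c(t0, t1, timeline$t_start, timeline$t_end,
                         archive_times)))
  edges <- edges[edges >= t0 - 1e-12 & edges <= t1 + 1e-12]
  steps <- unlist(lapply(seq_len(length(edges) - 1), function(i) {
    nsub <- max(1, ceiling((edges[i + 1] - edges[i]) / dt_max - 1e-9))
    seq(edges[i], edges[i + 1], length.out = nsub + 1)[-1]
  }))

  states <- list()
  cum_wud <- array(0, dim = dim(grid$mask))
  uptake_order <- c(`1` = 0, `2` = 0, `3` = 0)
  uptake_seg <- new.env(parent = emptyenv())
  up_rows <- list()
  ledger_rows <- list()
  effl_rows <- list()
  t_now <- t0
  transp_cum <- 0
  next_arch <- 1

  t_rsa_max <- max(vapply(rsa_series, system_time, numeric(1)))
  for (t_next in steps) {
    t_sub <- t_now
    dt_outer <- t_next - t_now
    vel_acc <- NULL
    bcn_outer <- boundary_at(timeline, t_now + dt_outer / 2)
    # a coupling step may be subdivided when the root sink would locally
    # exhaust the extractable water: the xylem system is re-solved on each
    # subdivision so uptake shifts away from drying voxels (compensation)
    while (t_sub < t_next - 1e-12) {
      dt <- t_next - t_sub
      bcn <- boundary_at(timeline, t_sub + dt / 2)
      irr_sim <- weight_flux(bcn$irrigation_flux, ar)
      transp_sim <- weight_flux(bcn$transpiration_flux, ar)

      sink <- 0
      sol <- NULL
      if (transp_sim > 1e-12) {
        t_mid <- min(t_sub + dt / 2, t_rsa_max)
        rs_t <- interpolate_architecture(rsa_series, t_mid)
        rsp <- assign_segment_params(rs_t, params, t = t_mid)
        soil_H <- soil_potential_at_segments(rsp, grid)
        sol <- solve_xylem(rsp, soil_H, collar_bc = list(flux = transp_sim))
        sink <- sink_to_grid(sol, rsp, grid)
        # limit the step so no voxel loses more than a third of its
        # extractable water before the next xylem solve
        smax <- sink > 0
        if (any(smax)) {
          avail <- (grid$theta - vg$theta_r - 1e-4)[smax]
          dt_sink <- 0.33 * min(pmax(avail, 0) / sink[smax])
          dt <- max(min(dt, dt_sink), dt_max / 64)
        }
      }
      dt <- min(dt, t_next - t_sub)
      rst <- richards_step(grid, vg, sink = sink,
                           bc = list(top_flux = irr_sim,
                                     bottom = bcn$bottom_condition),
                           dt = dt)
      grid <- rst$grid
      if (!is.null(sol)) {
        cum_wud <- cum_wud + sink * dt
        ord_add <- tapply(sol$fluxes$radial_flux * dt, sol$fluxes$order, sum)
        uptake_order[names(ord_add)] <- uptake_order[names(ord_add)] + ord_add
        ids <- as.character(sol$fluxes$id)
        vals <- sol$fluxes$radial_flux * dt
        for (k in seq_along(ids)) {
          prev <- uptake_seg[[ids[k]]]
          uptake_seg[[ids[k]]] <- if (is.null(prev)) vals[k] else prev + vals[k]
        }
        transp_cum <- transp_cum + transp_sim * dt
      }
      if (use_particles) {
        # time-weighted mean Darcy flux over the outer step: particles are
        # advected once per outer step on a scenario-independent schedule,
        # so runs with slightly different parameters consume the same
        # random numbers (common random numbers across scenarios)
        if (is.null(vel_acc)) {
          vel_acc <- lapply(rst$velocity, function(a) a * dt)
        } else {
          vel_acc <- Map(function(acc, a) acc + a * dt, vel_acc,
                         rst$velocity)
        }
      }
      ledger_rows[[length(ledger_rows) + 1]] <- tibble(
        t = t_sub + dt, irrigation = irr_sim * dt,
        transpiration = if (is.null(sol)) 0 else transp_sim * dt,
        effluent = rst$effluent,
        storage_change = rst$balance$storage_change,
        balance_rel_error = rst$balance$rel_error
      )
      if (rst$effluent > 0) {
        effl_rows[[length(effl_rows) + 1]] <- tibble(t = t_sub + dt,
                                                     volume = rst$effluent)
      }
      t_sub <- t_sub + dt
    }
    if (use_particles && !is.null(vel_acc)) {
      vel_mean <- lapply(vel_acc, function(a) a / dt_outer)
      irr_outer <- weight_flux(bcn_outer$irrigation_flux, ar)
      if (irr_outer > 0 && bcn_outer$irrigation_concentration > 0) {
        particles <- inject_particles(particles, grid, irr_outer,
                                      bcn_outer$irrigation_concentration,
                                      dt_outer)
      }
      bottom_open <- bcn_outer$bottom_condition %in%
        c("free_drainage", "seepage")
      vmax <- max(abs(vel_mean$qx), abs(vel_mean$qy), abs(vel_mean$qz)) /
        max(min(grid$theta[grid$mask], na.rm = TRUE), 1e-3)
      # quantized substep count (powers of two) so that near-identical
      # scenarios keep identical random-number schedules
      nsub_p <- 2^ceiling(log2(max(1, 2 * vmax * dt_outer / grid$dx)))
      for (s in seq_len(nsub_p)) {
        particles <- advect_disperse_step(particles, grid, vel_mean,
                                          transport, dt_outer / nsub_p,
                                          t = t_now + dt_outer * s / nsub_p,
                                          bottom_open = bottom_open)
      }
    }
    t_now <- t_next
    if (next_arch <= length(archive_times) &&
        t_now >= archive_times[next_arch] - 1e-9) {
      states[[length(states) + 1]] <- list(
        t = t_now, theta = grid$theta, h = grid$h,
        conc = if (use_particles) bin_concentration(particles, grid) else NULL,
        cum_wud = cum_wud
      )
      up_rows[[length(up_rows) + 1]] <- tibble(
        t = t_now, order = 1:3, cum_uptake_cm3 = unname(uptake_order))
      next_arch <- next_arch + 1
      if (verbose) message(sprintf("archived state at %.2f DAS", t_now))
    }
  }
  seg_ids <- ls(uptake_seg)
  structure(list(
    states = states,
    uptake_by_order = bind_rows(up_rows),
    uptake_by_segment = tibble(
      id = as.integer(seg_ids),
      cum_uptake_cm3 = vapply(seg_ids, function(k) uptake_seg[[k]],
                              numeric(1))),
    ledger = bind_rows(ledger_rows),
    effluent_water = if (length(effl_rows)) bind_rows(effl_rows) else
      tibble(t = numeric(0), volume = numeric(0)),
    particles = particles,
    grid = grid,
    transpiration_total = transp_cum,
    t0 = t0, t1 = t1, params = params
  ), class = "forward_run")
}

#' @export
print.forward_run <- function(x, ...) {
  cat(sprintf("forward run %.2f-%.2f DAS: %d archived states\n",
              x$t0, x$t1, length(x$states)))
  led <- x$ledger
  cat(sprintf("  irrigation %.2f cm3, transpiration %.2f cm3, effluent %.2f cm3\n",
              sum(led$irrigation), sum(led$transpiration), sum(led$effluent)))
  cat(sprintf("  worst per-step mass-balance error %.2e\n",
              max(led$balance_rel_error)))
  invisible(x)
}

#' Archived state closest to a requested time
#' @param run a `forward_run`.
#' @param t requested time (DAS).
#' @export
state_at <- function(run, t) {
  ts <- vapply(run$states, `[[`, numeric(1), "t")
  run$states[[which.min(abs(ts - t))]]
}

#' Build the initial tracer concentration field
#'
#' Distributes a known total tracer mass over the column: within the imaged
#' depth range the concentration is uniform in each horizontal layer and
#' decreases linearly with depth (relative slope `slope`: 0 gives a uniform
#' profile, 1 reaches zero at the bottom of the imaged region), scaled so
#' the imaged region holds `imaged_mass`; the remaining mass is spread
#' uniformly below.
#'
#' @param grid a `soil_grid` with a valid `theta` field.
#' @param total_mass total tracer mass in the column (mmol).
#' @param imaged_mass tracer mass inside the imaged region (mmol);
#'   must not exceed `total_mass`.
#' @param imaged_depth depth (cm) covered by the imaging field of view.
#' @param slope relative linear decrease over the imaged depth (0..1).
#' @return 3-d concentration array (mmol/l) whose mass integral equals
#'   `total_mass`.
#' @export
build_initial_concentration <- function(grid, total_mass, imaged_mass,
                                        imaged_depth = 8, slope = 1) {
  if (imaged_mass > total_mass + 1e-12) {
    abort("imaged mass exceeds total mass")
  }
  depth <- -grid$zc
  imaged_layers <- which(depth <= imaged_depth + 1e-9)
  shape <- pmax(1 - slope * depth / imaged_depth, 0)
  conc <- array(0, dim = dim(grid$mask))
  wat_layer <- vapply(seq_len(grid$nz), function(k) {
    sum(grid$theta[, , k][grid$mask2d]) * voxel_volume(grid)
  }, numeric(1)) # cm3 of water per layer
  denom <- sum(shape[imaged_layers] * wat_layer[imaged_layers]) / 1000
  if (denom <= 0) abort("imaged region holds no water")
  c0 <- imaged_mass / denom
  for (k in imaged_layers) conc[, , k] <- c0 * shape[k]
  rem <- total_mass - imaged_mass
  below <- setdiff(seq_len(grid$nz), imaged_layers)
  if (rem > 1e-15) {
    if (length(below) == 0) abort("mass left over but no unimaged region")
    c_below <- rem / (sum(wat_layer[below]) / 1000)
    for (k in below) conc[, , k] <- c_below
  }
  conc[!grid$mask] <- NA_real_
  conc
}

#' Virtual-MRI observation of a concentration field
#'
#' Block-averages the fine field to merged voxels (default 0.5 cm) and
#' optionally adds Gaussian noise. With `conc_dependent_noise`, the noise
#' standard deviation inflates proportionally above 5 mmol/l, mimicking the
#' larger uncertainty of MRI-derived concentrations at high values.
#' Negative draws are clipped at zero and counted.
#'
#' @param field 3-d array on the fine grid.
#' @param grid the `soil_grid` the field lives on.
#' @param merge_width merged voxel width (cm); integer multiple of the
#'   grid's `dx`.
#' @param noise_sd Gaussian noise level (units of the field; 0 = noiseless).
#' @param conc_dependent_noise inflate noise above 5 mmol/l.
#' @param timestamp observation time (DAS), carried along.
#' @param seed optional seed for the noise stream.
#' @return An `observation_map`: list with the coarse array `c`, logical
#'   `mask`, `width`, `timestamp`, `noise_sd`, `n_clipped`.
#' @export
observe <- function(field, grid, merge_width = 0.5, noise_sd = 0,
                    conc_dependent_noise = FALSE, timestamp = NA_real_,
                    seed = NULL) {
  f <- merge_width / grid$dx
  if (abs(f - round(f)) > 1e-9) {
    abort("merge_width must be an integer multiple of the grid dx")
  }
  f <- as.integer(round(f))
  dims <- dim(field)
  cd <- ceiling(dims / f)
  fld <- field
  fld[!grid$mask] <- NA_real_
  blk <- function(i, k) (i - 1L) %/% k + 1L
  ix <- blk(slice.index(fld, 1), f)
  iy <- blk(slice.index(fld, 2), f)
  iz <- blk(slice.index(fld, 3), f)
  key <- ix + (iy - 1L) * cd[1] + (iz - 1L) * cd[1] * cd[2]
  ok <- !is.na(fld)
  sums <- rowsum(fld[ok], key[ok])
  cnts <- rowsum(rep(1, sum(ok)), key[ok])
  coarse <- array(NA_real_, dim = cd)
  coarse[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  n_fine <- array(0L, dim = cd)
  n_fine[as.integer(rownames(cnts))] <- as.integer(cnts[, 1])
  cmask <- !is.na(coarse)
  n_clipped <- 0L
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    if (!is.null(seed)) set.seed(seed)
    sd_eff <- array(noise_sd, dim = cd)
    if (conc_dependent_noise) {
      hi <- cmask & coarse > 5
      sd_eff[hi] <- noise_sd * coarse[hi] / 5
    }
    noisy <- coarse + array(rnorm(prod(cd), 0, sd_eff), dim = cd)
    n_clipped <- sum(noisy[cmask] < 0)
    noisy[noisy < 0] <- 0
    coarse[cmask] <- noisy[cmask]
    if (!is.null(seed) && !is.null(old_seed)) {
      assign(".Random.seed", old_seed, .GlobalEnv)
    }
  }
  structure(list(c = coarse, mask = cmask, n_fine = n_fine,
                 width = merge_width, timestamp = timestamp,
                 noise_sd = noise_sd, n_clipped = n_clipped),
            class = "observation_map")
}

#' Water-uptake proxy fields over an observation window
#'
#' Computes, per voxel, the water depletion `WD = theta(t1) - theta(t2)`,
#' the tracer accumulation `Acc = c(t2) - c(t1)` and the cumulative water
#' uptake density `cumWUD` over `[t1, t2]` from two archived states of a
#' forward run.
#'
#' @param run a `forward_run`.
#' @param t1,t2 archive times bracketing the window (DAS).
#' @return A `proxy_fields` list with 3-d arrays `WD` (cm3/cm3), `Acc`
#'   (mmol/l), `cumWUD` (cm3/cm3) and the window.
#' @export
proxies <- function(run, t1, t2) {
  s1 <- state_at(run, t1)
  s2 <- state_at(run, t2)
  if (abs(s1$t - s2$t) < 1e-9) abort("proxy window has zero length")
  out <- list(
    WD = s1$theta - s2$theta,
    Acc = if (!is.null(s1$conc)) s2$conc - s1$conc else NULL,
    cumWUD = s2$cum_wud - s1$cum_wud,
    t1 = s1$t, t2 = s2$t
  )
  structure(out, class = "proxy_fields")
}

#' Normalize a field to unit sum
#'
#' `Y_hat_i = Y_i / sum_j Y_j`, the normalization applied to proxy maps
#' before comparison.
#'
#' @param Y numeric array or vector.
#' @return Array of the same shape summing to 1.
#' @export
normalize_field <- function(Y) {
  s <- sum(Y, na.rm = TRUE)
  if (abs(s) < 1e-300) abort("cannot normalize: field sums to zero")
  Y / s
}

#' Proxy-vs-uptake agreement
#'
#' Squared Pearson correlations between the normalized proxies (tracer
#' accumulation, water depletion) and the normalized cumulative uptake
#' density, computed in 3-d at merged-voxel resolution and in 1-d on
#' horizontally averaged depth profiles.
#'
#' @param pf a `proxy_fields`.
#' @param grid the fine `soil_grid`.
#' @param merge_width merged voxel width (cm) for the 3-d comparison.
#' @return Tibble with columns `proxy`, `dimension`, `r2`.
#' @export
proxy_r2 <- function(pf, grid, merge_width = 0.5) {
  cw <- function(fld) observe(fld, grid, merge_width)$c
  w3 <- cw(pf$cumWUD)
  profiles <- function(fld) {
    vapply(seq_len(dim(fld)[3]), function(k) {
      mean(fld[, , k][grid$mask2d], na.rm = TRUE)
    }, numeric(1))
  }
  w1 <- profiles(pf$cumWUD)
  r2 <- function(a, b) {
    ok <- complete.cases(a, b)
    cor(a[ok], b[ok])^2
  }
  rows <- list()
  for (nm in c("Acc", "WD")) {
    if (is.null(pf[[nm]])) next
    rows[[length(rows) + 1]] <- tibble(
      proxy = nm, dimension = "3d",
      r2 = r2(as.vector(cw(pf[[nm]])), as.vector(w3)))
    rows[[length(rows) + 1]] <- tibble(
      proxy = nm, dimension = "1d",
      r2 = r2(profiles(pf[[nm]]), w1))
  }
  bind_rows(rows)
}

#' Cumulative uptake partition by root order
#'
#' @param run a `forward_run`.
#' @param window optional `c(t1, t2)`; default the whole run.
#' @return Tibble with `order`, `cum_uptake_cm3`, `fraction` (summing to 1).
#' @export
uptake_partition <- function(run, window = NULL) {
  ub <- run$uptake_by_order
  if (nrow(ub) == 0) abort("no uptake archived in this run")
  at_time <- function(tt) {
    ts <- unique(ub$t)
    ub %>% filter(.data$t == ts[which.min(abs(ts - tt))])
  }
  last <- at_time(if (is.null(window)) max(ub$t) else window[2])
  first <- if (is.null(window) || window[1] <= run$t0 + 1e-9) {
    last %>% mutate(cum_uptake_cm3 = 0)
  } else at_time(window[1])
  out <- last %>%
    mutate(cum_uptake_cm3 = .data$cum_uptake_cm3 - first$cum_uptake_cm3) %>%
    select("order", "cum_uptake_cm3")
  tot <- sum(out$cum_uptake_cm3)
  if (tot <= 0) abort("empty uptake window")
  out$fraction <- out$cum_uptake_cm3 / tot
  out
}
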