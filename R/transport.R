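#' Solute transport parameters
#'
#' Parameters of the random-walk particle tracking scheme for the
#' convection-dispersion transport of a conservative, root-excluded tracer.
#'
#' @param Dm molecular diffusivity in the liquid phase (cm2/d). The default
#'   is the fixed Gd-DTPA value, 0.35 cm2/d; no extra tortuosity factor is
#'   applied unless `tortuosity` is set.
#' @param alpha_L,alpha_T longitudinal and transverse dispersivities (cm);
#'   defaults 0.25 and 0.025 (the longitudinal value equals the voxel
#'   width, its maximal theoretical value).
#' @param n_particles particle budget for an experiment.
#' @param tortuosity optional multiplier (< 1) applied to `Dm`.
#' @param seed RNG seed for the transport stream.
#' @export
transport_params <- function(Dm = 0.35, alpha_L = 0.25, alpha_T = 0.025,
                             n_particles = 20000, tortuosity = 1,
                             seed = 1L) {
  if (Dm < 0 || alpha_L < 0 || alpha_T < 0) abort("negative transport parameter")
  if (alpha_T > alpha_L) abort("alpha_T must not exceed alpha_L")
  if (n_particles < 1) abort("n_particles must be >= 1")
  structure(list(Dm = Dm * tortuosity, alpha_L = alpha_L, alpha_T = alpha_T,
                 n_particles = as.integer(n_particles), seed = seed),
            class = "transport_params")
}

#' Particle ensembles
#'
#' A particle ensemble carries the tracer mass as `n` equal-mass Lagrangian
#' particles plus bookkeeping ledgers: `pending_mass` (mass awaiting
#' discretisation into whole particles), `injected_mass`, and the effluent
#' ledger (`exited_mass`, with an exit log of times and masses). Total mass
#' (in-domain + pending + exited) is conserved between injections.
#'
#' @param mass_per_particle particle mass (mmol); fix it from the expected
#'   total injected mass divided by the particle budget.
#' @return A `particle_ensemble`.
#' @export
particle_ensemble <- function(mass_per_particle) {
  if (mass_per_particle <= 0) abort("mass_per_particle must be > 0")
  structure(list(
    pos = matrix(numeric(0), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z"))),
    mpp = mass_per_particle,
    pending_mass = 0,
    injected_mass = 0,
    exited_mass = 0,
    exit_log = tibble(t = numeric(0), mass = numeric(0))
  ), class = "particle_ensemble")
}

#' @rdname particle_ensemble
#' @param p a `particle_ensemble`.
#' @export
in_domain_mass <- function(p) nrow(p$pos) * p$mpp + p$pending_mass

#' @rdname particle_ensemble
#' @export
total_mass <- function(p) in_domain_mass(p) + p$exited_mass

#' Inject tracer with the irrigation water
#'
#' Adds `flux * concentration * dt` of tracer mass through the top face,
#' uniformly over the masked surface cells. Whole particles are released as
#' soon as the accumulated mass reaches multiples of the particle mass; the
#' remainder stays in `pending_mass`, so the mass ledger is exact.
#'
#' @param p a `particle_ensemble`.
#' @param grid a `soil_grid`.
#' @param flux irrigation water flux (cm3/d, >= 0, area-weighted).
#' @param concentration tracer concentration of the irrigation water
#'   (mmol/l, >= 0).
#' @param dt time step (d).
#' @return The updated ensemble.
#' @export
inject_particles <- function(p, grid, flux, concentration, dt) {
  if (flux < 0 || concentration < 0) abort("negative flux or concentration")
  mass <- flux * concentration * dt * 1e-3   # cm3 * mmol/l -> mmol
  p$injected_mass <- p$injected_mass + mass
  p$pending_mass <- p$pending_mass + mass
  n_new <- floor(p$pending_mass / p$mpp)
  if (n_new > 0) {
    p$pending_mass <- p$pending_mass - n_new * p$mpp
    topo <- grid_topology(grid)
    tops <- topo$active[topo$top]
    ijk <- arrayInd(tops, dim(grid$mask))
    pick <- sample.int(length(tops), n_new, replace = TRUE)
    dx <- grid$dx
    x <- grid$xc[ijk[pick, 1]] + runif(n_new, -dx / 2, dx / 2)
    y <- grid$yc[ijk[pick, 2]] + runif(n_new, -dx / 2, dx / 2)
    z <- runif(n_new, -dx / 50, 0)   # just below the surface
    p$pos <- rbind(p$pos, cbind(x = x, y = y, z = z))
  }
  p
}

# trilinear interpolation of a cell-centred field at particle positions;
# out-of-mask (or out-of-box) corners take `fill`, or the nearest in-mask
# value when fill = "nearest"
.interp_field <- function(field, grid, x, y, z, fill = 0) {
  dx <- grid$dx
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  # continuous index coordinates of cell centres
  gx <- (x + nx * dx / 2) / dx + 0.5
  gy <- (y + ny * dx / 2) / dx + 0.5
  gz <- -z / dx + 0.5
  i0 <- pmin(pmax(floor(gx), 1), nx); fi <- pmin(pmax(gx - i0, 0), 1)
  j0 <- pmin(pmax(floor(gy), 1), ny); fj <- pmin(pmax(gy - j0, 0), 1)
  k0 <- pmin(pmax(floor(gz), 1), nz); fk <- pmin(pmax(gz - k0, 0), 1)
  out <- numeric(length(x))
  nearest <- identical(fill, "nearest")
  base_val <- if (nearest) {
    idx <- locate_cells(grid, x, y, z)
    miss <- is.na(idx)
    if (any(miss)) {
      # snap positions outside the mask radially toward the axis
      r <- sqrt(x[miss]^2 + y[miss]^2)
      s <- pmin(1, (grid$nx * dx / 2 - dx) / pmax(r, 1e-9))
      idx[miss] <- locate_cells(grid, x[miss] * s, y[miss] * s, z[miss])
    }
    v <- field[idx]
    v[is.na(v)] <- mean(field[grid$mask], na.rm = TRUE)
    v
  } else NULL
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- pmin(i0 + di, nx); jj <- pmin(j0 + dj, ny); kk <- pmin(k0 + dk, nz)
    w <- (if (di == 1) fi else 1 - fi) * (if (dj == 1) fj else 1 - fj) *
      (if (dk == 1) fk else 1 - fk)
    idx <- ii + (jj - 1) * nx + (kk - 1) * nx * ny
    v <- field[idx]
    inmask <- grid$mask[idx]
    v[!inmask] <- if (nearest) base_val[!inmask] else fill
    out <- out + w * v
  }
  out
}

# velocity (pore-water, cm/d) and theta at positions
.pore_velocity <- function(grid, velocity, x, y, z) {
  qx <- .interp_field(velocity$qx, grid, x, y, z, fill = 0)
  qy <- .interp_field(velocity$qy, grid, x, y, z, fill = 0)
  qz <- .interp_field(velocity$qz, grid, x, y, z, fill = 0)
  th <- .interp_field(grid$theta, grid, x, y, z, fill = "nearest")
  th <- pmax(th, 1e-6)
  list(vx = qx / th, vy = qy / th, vz = qz / th, theta = th)
}

#' One random-walk convection-dispersion step
#'
#' Ito scheme: displacement `= (v + drift) dt + B xi sqrt(dt)` with
#' `B B^T = 2 D`, `D = (alpha_L - alpha_T) v v^T / |v| + (alpha_T |v| + Dm) I`
#' evaluated on the trilinearly interpolated pore velocity. The drift term
#' `(1/theta) div(theta D)` (needed so particles do not artificially
#' accumulate where dispersion or water content vary) is estimated by
#' central finite differences of the interpolated fields. Particles reflect
#' at the top and at the lateral mask walls; particles crossing the bottom
#' while drainage is active are removed to the effluent ledger.
#'
#' @param p a `particle_ensemble`.
#' @param grid a `soil_grid` (theta field used for pore velocity).
#' @param velocity cell-centred Darcy flux field from [richards_step()].
#' @param tp a `transport_params`.
#' @param dt time step (d); must respect `dt <= dx / max|v|`.
#' @param t current time (DAS), for the exit log.
#' @param bottom_open whether the bottom boundary absorbs particles
#'   (drainage active).
#' @return The updated ensemble.
#' @export
advect_disperse_step <- function(p, grid, velocity, tp, dt, t = NA_real_,
                                 bottom_open = FALSE) {
  n <- nrow(p$pos)
  if (n == 0) return(p)
  x <- p$pos[, 1]; y <- p$pos[, 2]; z <- p$pos[, 3]
  pv <- .pore_velocity(grid, velocity, x, y, z)
  speed <- sqrt(pv$vx^2 + pv$vy^2 + pv$vz^2)
  if (max(speed) * dt > grid$dx + 1e-12) {
    abort("transport step too large: |v| dt exceeds the voxel width")
  }
  # drift correction (1/theta) d/dx_j (theta D_ij): the divergence of the
  # theta-weighted dispersion tensor is formed once per step on the grid by
  # central differences (zero-gradient at the mask boundary) and then
  # interpolated to the particles
  drift <- matrix(0, n, 3)
  if (tp$alpha_L > 0 || tp$alpha_T > 0 || tp$Dm > 0) {
    df <- .drift_field(grid, velocity, tp)
    drift[, 1] <- .interp_field(df$x, grid, x, y, z, fill = 0) / pv$theta
    drift[, 2] <- .interp_field(df$y, grid, x, y, z, fill = 0) / pv$theta
    drift[, 3] <- .interp_field(df$z, grid, x, y, z, fill = 0) / pv$theta
  }
  # random displacement with the anisotropic dispersion tensor
  DL <- tp$alpha_L * speed + tp$Dm
  DT <- tp$alpha_T * speed + tp$Dm
  xi <- matrix(rnorm(3 * n), n, 3)
  sT <- sqrt(2 * DT * dt)
  sL <- sqrt(2 * DL * dt)
  ev <- cbind(pv$vx, pv$vy, pv$vz) / pmax(speed, 1e-300)
  ev[speed < 1e-300, ] <- 0
  proj <- rowSums(ev * xi)
  rand <- xi * sT + ev * ((sL - sT) * proj)
  newx <- x + (pv$vx + drift[, 1]) * dt + rand[, 1]
  newy <- y + (pv$vy + drift[, 2]) * dt + rand[, 2]
  newz <- z + (pv$vz + drift[, 3]) * dt + rand[, 3]
  # top: specular reflection
  above <- newz > 0
  newz[above] <- -newz[above]
  # bottom
  H <- grid$height
  below <- newz < -H
  if (bottom_open) {
    exited <- below
  } else {
    newz[below] <- -2 * H - newz[below]
    newz <- pmax(newz, -H + 1e-9)
    exited <- rep(FALSE, n)
  }
  # lateral walls: bounce-back to the previous position for particles whose
  # proposed cell falls outside the mask (robust for the stair-step wall)
  k_ok <- pmin(pmax(-newz, 0), H - 1e-9)
  idx <- locate_cells(grid, newx, newy, -k_ok)
  out_lat <- is.na(idx) & !exited
  newx[out_lat] <- x[out_lat]
  newy[out_lat] <- y[out_lat]
  newz[out_lat] <- pmax(pmin(z[out_lat], 0), -H + 1e-9)
  if (any(exited)) {
    m <- sum(exited) * p$mpp
    p$exited_mass <- p$exited_mass + m
    p$exit_log <- bind_rows(p$exit_log, tibble(t = t, mass = m))
  }
  keep <- !exited
  p$pos <- cbind(x = newx[keep], y = newy[keep], z = newz[keep])
  p
}

#' Bin particle mass into a concentration field
#'
#' `c_voxel = mass_in_voxel / (theta_voxel * voxel_volume)`, converted to
#' mmol per litre of soil solution.
#'
#' @param p a `particle_ensemble`.
#' @param grid a `soil_grid` with a valid `theta` field.
#' @return 3-d array of concentrations (mmol/l); 0 in empty masked voxels,
#'   `NA` outside the mask.
#' @export
bin_concentration <- function(p, grid) {
  conc <- array(0, dim = dim(grid$mask))
  conc[!grid$mask] <- NA_real_
  if (nrow(p$pos) > 0) {
    idx <- locate_cells(grid, p$pos[, 1], p$pos[, 2], p$pos[, 3])
    idx[is.na(idx)] <- locate_cells(grid, 0, 0, p$pos[is.na(idx), 3])
    counts <- rowsum(rep(p$mpp, length(idx)), idx)
    at <- as.integer(rownames(counts))
    conc[at] <- counts[, 1] / (grid$theta[at] * voxel_volume(grid)) * 1000
  }
  conc
}

#' Effluent breakthrough curve
#'
#' Aggregates the particle exit ledger and the effluent water volumes into
#' windowed effluent concentrations.
#'
#' @param p a `particle_ensemble` with an exit log.
#' @param effluent_water tibble with columns `t` and `volume` (cm3) of
#'   drained water per recorded interval.
#' @param breaks window edges (DAS).
#' @return Tibble with `t_mid`, `mass_mmol`, `water_cm3`, `conc_mmol_l`
#'   (`NA`, flagged by `undefined`, where no water drained).
#' @export
breakthrough <- function(p, effluent_water, breaks) {
  win <- cut(p$exit_log$t, breaks, include.lowest = TRUE)
  mass <- tapply(p$exit_log$mass, win, sum, default = 0)
  wwin <- cut(effluent_water$t, breaks, include.lowest = TRUE)
  water <- tapply(effluent_water$volume, wwin, sum, default = 0)
  lv <- levels(win)
  m <- ifelse(is.na(mass[lv]), 0, mass[lv])
  w <- ifelse(is.na(water[lv]), 0, water[lv])
  tibble(
    t_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
    mass_mmol = as.numeric(m),
    water_cm3 = as.numeric(w),
    conc_mmol_l = ifelse(w > 0, as.numeric(m) / as.numeric(w) * 1000, NA_real_),
    undefined = w <= 0
  )
}

#' Spawn particles matching a concentration field
#'
#' Used to initialise a run from an observed or constructed concentration
#' map: the expected particle count per voxel is proportional to the voxel
#' tracer mass; positions are uniform within each voxel.
#'
#' @param conc 3-d concentration array (mmol/l).
#' @param grid a `soil_grid` with a valid `theta` field.
#' @param p a `particle_ensemble` (provides the particle mass).
#' @return The ensemble with the added particles; residual sub-particle
#'   mass goes to `pending_mass`.
#' @export
particles_from_field <- function(conc, grid, p) {
  mask_idx <- which(grid$mask)
  mass_v <- conc[mask_idx] * grid$theta[mask_idx] * voxel_volume(grid) / 1000
  mass_v[is.na(mass_v)] <- 0
  n_exact <- mass_v / p$mpp
  n_int <- floor(n_exact)
  frac <- n_exact - n_int
  n_int <- n_int + rbinom(length(frac), 1, frac)
  tot <- sum(n_int)
  if (tot > 0) {
    ijk <- arrayInd(rep(mask_idx, n_int), dim(grid$mask))
    dx <- grid$dx
    x <- grid$xc[ijk[, 1]] + runif(tot, -dx / 2, dx / 2)
    y <- grid$yc[ijk[, 2]] + runif(tot, -dx / 2, dx / 2)
    z <- grid$zc[ijk[, 3]] + runif(tot, -dx / 2, dx / 2)
    p$pos <- rbind(p$pos, cbind(x = x, y = y, z = z))
  }
  p$pending_mass <- p$pending_mass + sum(mass_v) - tot * p$mpp
  p$injected_mass <- p$injected_mass + sum(mass_v)
  p
}

# array shift with edge replication; out-of-mask values take the centre value
.shift_rep <- function(a, mask, d, by) {
  dims <- dim(a)
  idx <- lapply(seq_along(dims), function(k) seq_len(dims[k]))
  idx[[d]] <- pmin(pmax(idx[[d]] + by, 1), dims[d])
  out <- do.call(`[`, c(list(a), idx))
  bad <- !do.call(`[`, c(list(mask), idx))
  out[bad] <- a[bad]
  dim(out) <- dims
  out
}

# cell-centred div(theta * D) for the dispersive drift correction
.drift_field <- function(grid, velocity, tp) {
  mask <- grid$mask
  th <- grid$theta
  th[!mask] <- 0
  vx <- velocity$qx / pmax(th, 1e-9)
  vy <- velocity$qy / pmax(th, 1e-9)
  vz <- velocity$qz / pmax(th, 1e-9)
  vx[!mask] <- 0; vy[!mask] <- 0; vz[!mask] <- 0
  sp <- sqrt(vx^2 + vy^2 + vz^2)
  a <- (tp$alpha_L - tp$alpha_T) / pmax(sp, 1e-300)
  b <- tp$alpha_T * sp + tp$Dm
  comp <- list(
    xx = th * (a * vx^2 + b), yy = th * (a * vy^2 + b),
    zz = th * (a * vz^2 + b), xy = th * a * vx * vy,
    xz = th * a * vx * vz, yz = th * a * vy * vz)
  dx2 <- 2 * grid$dx
  ddx <- function(f) (.shift_rep(f, mask, 1, 1) - .shift_rep(f, mask, 1, -1)) / dx2
  ddy <- function(f) (.shift_rep(f, mask, 2, 1) - .shift_rep(f, mask, 2, -1)) / dx2
  # array index k increases downward, i.e. along -z
  ddz <- function(f) (.shift_rep(f, mask, 3, -1) - .shift_rep(f, mask, 3, 1)) / dx2
  list(x = ddx(comp$xx) + ddy(comp$xy) + ddz(comp$xz),
       y = ddx(comp$xy) + ddy(comp$yy) + ddz(comp$yz),
       z = ddx(comp$xz) + ddy(comp$yz) + ddz(comp$zz))
}
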