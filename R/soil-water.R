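#' van Genuchten-Mualem soil hydraulic functions
#'
#' Closed-form water retention and unsaturated hydraulic conductivity.
#' With `Se = (1 + (alpha*|h|)^n)^(-m)`, `m = 1 - 1/n`:
#' `theta(h) = theta_r + Se * (theta_s - theta_r)` and
#' `K(h) = Ks * Se^l * (1 - (1 - Se^(1/m))^m)^2`.
#'
#' The default parameter set describes a coarse quartz sand similar to the
#' FH31 material used in MRI root experiments; treat it as a configurable
#' placeholder, not a fitted curve.
#'
#' @param theta_r,theta_s residual and saturated water content (cm3/cm3).
#' @param alpha inverse air-entry value (1/cm).
#' @param n pore-size distribution index (> 1).
#' @param Ks saturated conductivity (cm/d).
#' @param l pore-connectivity (tortuosity) exponent.
#' @return `vg_params` returns a parameter list of class `vg_params`.
#' @export
vg_params <- function(theta_r = 0.03, theta_s = 0.37, alpha = 0.025,
                      n = 5, Ks = 500, l = 0.5) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1)) {
    abort("need 0 <= theta_r < theta_s <= 1")
  }
  if (alpha <= 0 || n <= 1 || Ks <= 0) {
    abort("need alpha > 0, n > 1, Ks > 0")
  }
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n = n, m = 1 - 1 / n, Ks = Ks, l = l),
            class = "vg_params")
}

#' @rdname vg_params
#' @param h matric potential (cm of water, <= 0 when unsaturated); vectorised.
#' @param vg a `vg_params` object.
#' @export
vg_saturation <- function(h, vg) {
  ifelse(h >= 0, 1, (1 + (vg$alpha * abs(h))^vg$n)^(-vg$m))
}

#' @rdname vg_params
#' @export
vg_retention <- function(h, vg) {
  vg$theta_r + vg_saturation(h, vg) * (vg$theta_s - vg$theta_r)
}

#' @rdname vg_params
#' @export
vg_conductivity <- function(h, vg) {
  Se <- vg_saturation(h, vg)
  vg$Ks * Se^vg$l * (1 - (1 - Se^(1 / vg$m))^vg$m)^2
}

#' @rdname vg_params
#' @param theta volumetric water content (cm3/cm3); vectorised.
#' @export
vg_head <- function(theta, vg) {
  Se <- pmin(1, pmax(1e-12, (theta - vg$theta_r) / (vg$theta_s - vg$theta_r)))
  ifelse(Se >= 1, 0, -(Se^(-1 / vg$m) - 1)^(1 / vg$n) / vg$alpha)
}

#' @rdname vg_params
#' @export
vg_capacity <- function(h, vg) {
  # dtheta/dh, zero at and above saturation
  ah <- vg$alpha * abs(h)
  C <- (vg$theta_s - vg$theta_r) * vg$alpha * vg$n * vg$m *
    ah^(vg$n - 1) * (1 + ah^vg$n)^(-vg$m - 1)
  ifelse(h >= 0, 0, C)
}

#' Soil medium description
#'
#' @param vg a `vg_params` object.
#' @param bulk_density dry bulk density (g/cm3).
#' @export
soil_medium <- function(vg = vg_params(), bulk_density = 1.62) {
  if (bulk_density <= 0) abort("bulk_density must be > 0")
  structure(list(vg = vg, bulk_density = bulk_density), class = "soil_medium")
}

#' Voxelized cylindrical soil column
#'
#' Builds a regular grid of cubic voxels whose horizontal mask approximates
#' the circular column cross-section: a voxel column is included when its
#' square cross-section intersects the disc. The ratio between the masked
#' area and the true disc area (`area_ratio`) is used to weight all boundary
#' water flows (see [weight_flux()]).
#'
#' The origin sits at the centre of the column top; `z` is positive upwards,
#' so the soil occupies `z` in `[-height, 0]`. Layer 1 is the top layer.
#'
#' @param diameter column inner diameter (cm).
#' @param height column height (cm); must be an integer multiple of `dx`.
#' @param dx voxel edge length (cm).
#' @param theta0 initial uniform water content (cm3/cm3), optional.
#' @param vg `vg_params` used to keep `h` and `theta` consistent.
#' @return A `soil_grid`: list with voxel counts `nx, ny, nz`, edge `dx`,
#'   cell-centre coordinates, logical 3-d `mask`, fields `theta` and `h`
#'   (3-d arrays), and `area_ratio`.
#' @export
build_column_grid <- function(diameter = 5, height = 10, dx = 0.25,
                              theta0 = NULL, vg = vg_params()) {
  if (dx >= diameter) abort("degenerate grid: dx >= diameter")
  if (abs(height / dx - round(height / dx)) > 1e-9) {
    abort("dx must divide the column height")
  }
  nx <- ceiling(diameter / dx - 1e-9)
  nz <- round(height / dx)
  r <- diameter / 2
  xc <- (seq_len(nx) - 0.5) * dx - nx * dx / 2
  # square [x0,x1]x[y0,y1] intersects the disc iff its closest point to the
  # axis is inside the circle
  x0 <- xc - dx / 2; x1 <- xc + dx / 2
  cx <- pmin(pmax(0, x0), x1)
  mask2d <- outer(cx^2, cx^2, "+") < r^2
  area_ratio <- sum(mask2d) * dx^2 / (pi * r^2)
  zc <- -(seq_len(nz) - 0.5) * dx
  mask <- array(mask2d, dim = c(nx, nx, nz))
  grid <- structure(list(
    nx = nx, ny = nx, nz = nz, dx = dx,
    diameter = diameter, height = height,
    xc = xc, yc = xc, zc = zc,
    mask = mask, mask2d = mask2d,
    area_ratio = area_ratio,
    theta = array(NA_real_, dim = c(nx, nx, nz)),
    h = array(NA_real_, dim = c(nx, nx, nz))
  ), class = "soil_grid")
  if (!is.null(theta0)) grid <- grid_set_theta(grid, theta0, vg)
  grid
}

#' @rdname build_column_grid
#' @param grid a `soil_grid`.
#' @param theta water content: scalar or array of the grid dimensions.
#' @export
grid_set_theta <- function(grid, theta, vg = vg_params()) {
  th <- array(theta, dim = dim(grid$mask))
  th[!grid$mask] <- NA_real_
  grid$theta <- th
  grid$h <- array(vg_head(th, vg), dim = dim(th))
  grid
}

#' @rdname build_column_grid
#' @param h matric potential: scalar or array (cm of water).
#' @export
grid_set_head <- function(grid, h, vg = vg_params()) {
  hh <- array(h, dim = dim(grid$mask))
  hh[!grid$mask] <- NA_real_
  grid$h <- hh
  grid$theta <- array(vg_retention(hh, vg), dim = dim(hh))
  grid
}

#' Voxel volume (cm3)
#' @param grid a `soil_grid`.
#' @export
voxel_volume <- function(grid) grid$dx^3

#' Total water volume held in the column (cm3)
#' @param grid a `soil_grid`.
#' @export
water_volume <- function(grid) {
  sum(grid$theta[grid$mask]) * voxel_volume(grid)
}

#' Flux weighting between the true and the voxelized column surface
#'
#' Boundary water flows measured on the real column (irrigation,
#' transpiration, effluent) are rescaled by the ratio of the voxelized to
#' the true cross-section before being applied to the simulated domain:
#' `W_simulation = area_ratio * W_experiment`.
#'
#' @param W_experiment flow magnitude (cm3/d), non-negative.
#' @param area_ratio masked-to-true area ratio (from [build_column_grid()]).
#' @export
weight_flux <- function(W_experiment, area_ratio) {
  if (any(W_experiment < 0)) abort("flux magnitudes must be non-negative")
  if (any(area_ratio <= 0)) abort("area_ratio must be positive")
  area_ratio * W_experiment
}

# -- internal grid topology -------------------------------------------------

# Precomputes, for the masked cells, the linear indices of interior face
# pairs and the boundary face lists used by the Richards solver.
grid_topology <- function(grid) {
  if (!is.null(grid$topology)) return(grid$topology)
  dims <- dim(grid$mask)
  act <- which(grid$mask)
  amap <- array(NA_integer_, dim = dims)
  amap[act] <- seq_along(act)
  ijk <- arrayInd(act, dims)
  pair_dir <- function(dd) {
    shifted <- ijk
    shifted[, dd] <- shifted[, dd] + 1L
    ok <- shifted[, dd] <= dims[dd]
    nb <- rep(NA_integer_, nrow(ijk))
    nb[ok] <- amap[shifted[ok, , drop = FALSE]]
    valid <- !is.na(nb)
    cbind(from = seq_along(act)[valid], to = nb[valid])
  }
  pairs <- list(x = pair_dir(1), y = pair_dir(2), z = pair_dir(3))
  top <- which(ijk[, 3] == 1L)     # z-layer 1 is the surface
  bottom <- which(ijk[, 3] == dims[3])
  grid$topology <- list(active = act, amap = amap, ijk = ijk, pairs = pairs,
                        top = top, bottom = bottom, n = length(act))
  grid$topology
}

# adds `w` into `x` at (possibly repeated) integer positions `idx`
tapply_add <- function(x, idx, w) {
  s <- rowsum(as.numeric(w), idx)
  at <- as.integer(rownames(s))
  x[at] <- x[at] + s[, 1]
  x
}

#' One Richards step with root sink coupling
#'
#' Advances the mixed-form (theta-h) Richards equation by `dt` days with a
#' modified-Picard backward-Euler finite-volume scheme on the masked grid.
#' Boundary conditions: prescribed irrigation flux distributed uniformly over
#' the top layer, free drainage (unit gradient) or no-flux at the bottom,
#' no-flux lateral walls; gravity is included. On Picard non-convergence the
#' step is retried with halved sub-steps. After convergence the water content
#' is updated from the converged face fluxes, so the step conserves mass by
#' construction; the returned balance reports the bookkeeping.
#'
#' @param grid a `soil_grid` with consistent `theta`/`h` fields.
#' @param medium a `soil_medium` (or `vg_params`).
#' @param sink root water extraction per voxel (cm3 water / cm3 soil / d):
#'   scalar or array; positive extracts water.
#' @param bc list with `top_flux` (cm3/d total irrigation into the column,
#'   already area-weighted) and `bottom` (`"free_drainage"` or `"no_flux"`).
#' @param dt time step (d).
#' @param tol Picard tolerance on the water-content increment (cm3/cm3).
#' @param max_iter maximum Picard iterations per (sub)step.
#' @param max_halvings maximum number of dt halvings before giving up.
#' @return List with the updated `grid`, a `balance` list (boundary and sink
#'   volumes, storage change, relative mass-balance error), the Darcy flux
#'   field (`velocity`, cell-centred, cm/d, z positive up), the bottom
#'   outflow volume `effluent` (cm3), and `n_substeps`.
#' @export
richards_step <- function(grid, medium, sink = 0,
                          bc = list(top_flux = 0, bottom = "no_flux"),
                          dt, tol = 1e-6, max_iter = 15, max_halvings = 20) {
  vg <- if (inherits(medium, "soil_medium")) medium$vg else medium
  topo <- grid_topology(grid)
  grid$topology <- topo
  n <- topo$n
  dx <- grid$dx
  sink_v <- array(sink, dim = dim(grid$mask))[topo$active]
  q_top_cell <- bc$top_flux / (length(topo$top) * dx^2)   # cm/d per top cell
  bottom_mode <- bc$bottom %||% "no_flux"
  if (!bottom_mode %in% c("no_flux", "free_drainage", "seepage")) {
    abort(paste("unknown bottom condition:", bottom_mode))
  }

  # fixed sparse pattern (upper triangle: active indices increase along +x,
  # +y and +z-down shifts) + diagonal; the symbolic Cholesky factorisation
  # is cached on the grid topology and reused across steps
  prx <- topo$pairs$x; pry <- topo$pairs$y; prz <- topo$pairs$z
  pat_i <- c(prx[, 1], pry[, 1], prz[, 1], seq_len(n))
  pat_j <- c(prx[, 2], pry[, 2], prz[, 2], seq_len(n))
  if (is.null(topo$solver)) {
    topo$solver <- new.env(parent = emptyenv())
    grid$topology <- topo
  }

  picard <- function(h, theta_n, dt_sub) {
    h_m <- h
    for (iter in seq_len(max_iter)) {
      K <- vg_conductivity(h_m, vg)
      C <- vg_capacity(h_m, vg) + 1e-9
      theta_m <- vg_retention(h_m, vg)
      Kfx <- (K[prx[, 1]] + K[prx[, 2]]) / 2
      Kfy <- (K[pry[, 1]] + K[pry[, 2]]) / 2
      Kfz <- (K[prz[, 1]] + K[prz[, 2]]) / 2
      wx <- Kfx / dx^2; wy <- Kfy / dx^2; wz <- Kfz / dx^2
      diag_v <- C / dt_sub
      diag_v <- tapply_add(diag_v, prx[, 1], wx)
      diag_v <- tapply_add(diag_v, prx[, 2], wx)
      diag_v <- tapply_add(diag_v, pry[, 1], wy)
      diag_v <- tapply_add(diag_v, pry[, 2], wy)
      diag_v <- tapply_add(diag_v, prz[, 1], wz)
      diag_v <- tapply_add(diag_v, prz[, 2], wz)
      rhs <- C / dt_sub * h_m - (theta_m - theta_n) / dt_sub - sink_v
      # gravity on vertical faces: the "to" cell is one layer deeper
      # (z_to - z_from = -dx), contributing  K_f * (z_nb - z_i) / dx^2
      gz <- Kfz / dx
      rhs <- tapply_add(rhs, prz[, 1], -gz)
      rhs <- tapply_add(rhs, prz[, 2], +gz)
      rhs[topo$top] <- rhs[topo$top] + q_top_cell / dx
      if (bottom_mode == "free_drainage") {
        rhs[topo$bottom] <- rhs[topo$bottom] - K[topo$bottom] / dx
      } else if (bottom_mode == "seepage") {
        # saturated bottom face (h = 0), outflow only: cells wetter than
        # hydrostatic equilibrium with the face drain implicitly
        act <- h_m[topo$bottom] > -dx / 2
        Kb <- K[topo$bottom][act]
        bi <- topo$bottom[act]
        diag_v[bi] <- diag_v[bi] + 2 * Kb / dx^2
        rhs[bi] <- rhs[bi] - Kb / dx
      }
      A <- Matrix::sparseMatrix(
        i = pat_i, j = pat_j,
        x = c(-wx, -wy, -wz, diag_v + 1e-12),
        dims = c(n, n), symmetric = TRUE)
      ch <- topo$solver$chol
      ch <- if (is.null(ch)) {
        Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
      } else Matrix::update(ch, A)
      topo$solver$chol <- ch
      h_new <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
      converged <- max(abs(vg_retention(h_new, vg) - theta_m)) < tol
      h_m <- h_new
      if (converged) return(list(h = h_m, ok = TRUE))
    }
    list(ok = FALSE)
  }

  # one attempted substep: converged Picard heads, then a conservative
  # theta update from the converged face fluxes; heads are re-derived from
  # theta so the two fields stay consistent through the retention curve
  try_substep <- function(h, theta_n, dt_sub) {
    res <- picard(h, theta_n, dt_sub)
    if (!res$ok) return(NULL)
    K <- vg_conductivity(res$h, vg)
    fl <- .face_fluxes(res$h, K, topo, dx, q_top_cell, bottom_mode)
    theta_new <- theta_n + dt_sub * (fl$div - sink_v)
    if (any(theta_new < vg$theta_r - 1e-7) ||
        any(theta_new > vg$theta_s + 1e-7)) {
      return(NULL)
    }
    theta_new <- pmin(pmax(theta_new, vg$theta_r + 1e-12), vg$theta_s)
    list(h = vg_head(theta_new, vg), theta = theta_new, fl = fl,
         effluent = sum(fl$q_bottom) * dx^2 * dt_sub)
  }

  theta_n0 <- grid$theta[topo$active]
  h <- grid$h[topo$active]
  theta_n <- theta_n0
  dt_min <- dt / 2^max_halvings
  remaining <- dt
  dt_try <- dt
  effluent <- 0
  nsub <- 0L
  fl <- NULL
  while (remaining > 1e-12 * dt) {
    res <- try_substep(h, theta_n, dt_try)
    if (is.null(res)) {
      dt_try <- dt_try / 2
      if (dt_try < dt_min) {
        abort(sprintf(
          "Richards solver failed to converge (dt floor %.3g d reached)",
          dt_try))
      }
      next
    }
    h <- res$h
    theta_n <- res$theta
    fl <- res$fl
    effluent <- effluent + res$effluent
    remaining <- remaining - dt_try
    nsub <- nsub + 1L
    dt_try <- min(dt_try * 1.5, remaining + 1e-15 * dt)
  }
  out <- list(h = h, theta = theta_n, fl = fl, effluent = effluent,
              nsub = nsub)
  theta_n <- theta_n0
  grid$h[topo$active] <- out$h
  grid$theta[topo$active] <- out$theta

  storage_change <- sum(out$theta - theta_n) * dx^3
  top_in <- bc$top_flux * dt
  sink_total <- sum(sink_v) * dx^3 * dt
  resid <- top_in - out$effluent - sink_total - storage_change
  # scale tiny steps by the column water volume so no-flux steps do not
  # report spurious relative errors
  denom <- max(abs(top_in) + abs(out$effluent) + abs(sink_total),
               abs(storage_change), 1e-6 * sum(theta_n) * dx^3)
  balance <- list(storage_change = storage_change, top_in = top_in,
                  bottom_out = out$effluent, sink = sink_total,
                  residual = resid, rel_error = abs(resid) / denom)
  vel <- .cell_velocity(out$fl, topo, grid, q_top_cell)
  list(grid = grid, balance = balance, velocity = vel,
       effluent = out$effluent, n_substeps = out$nsub)
}

# face fluxes and their divergence (in 1/d units of theta change) from a
# converged head field; q is positive from `from` to `to`
.face_fluxes <- function(h, K, topo, dx, q_top_cell, bottom_mode) {
  n <- topo$n
  div <- numeric(n)
  qp <- list()
  for (d3 in c("x", "y", "z")) {
    pr <- topo$pairs[[d3]]
    Kf <- (K[pr[, 1]] + K[pr[, 2]]) / 2
    dz <- if (d3 == "z") -dx else 0
    q <- -Kf * (h[pr[, 2]] - h[pr[, 1]] + dz) / dx
    div <- tapply_add(div, pr[, 1], -q / dx)
    div <- tapply_add(div, pr[, 2], +q / dx)
    qp[[d3]] <- q
  }
  div[topo$top] <- div[topo$top] + q_top_cell / dx
  q_bot <- if (bottom_mode == "free_drainage") {
    K[topo$bottom]
  } else if (bottom_mode == "seepage") {
    pmax(0, K[topo$bottom] * (2 * h[topo$bottom] / dx + 1))
  } else numeric(0)
  if (length(q_bot) > 0) div[topo$bottom] <- div[topo$bottom] - q_bot / dx
  list(pairs_q = qp, div = div, q_bottom = q_bot)
}

# cell-centred Darcy flux vectors (cm/d) in coordinate convention
# (x, y, z with z positive up); used by the particle tracker
.cell_velocity <- function(fl, topo, grid, q_top_cell) {
  n <- topo$n
  qx <- qy <- qz <- numeric(n)
  prx <- topo$pairs$x; pry <- topo$pairs$y; prz <- topo$pairs$z
  qx <- tapply_add(qx, prx[, 1], fl$pairs_q$x / 2)
  qx <- tapply_add(qx, prx[, 2], fl$pairs_q$x / 2)
  qy <- tapply_add(qy, pry[, 1], fl$pairs_q$y / 2)
  qy <- tapply_add(qy, pry[, 2], fl$pairs_q$y / 2)
  # pair direction "to deeper layer" is -z in space
  qz <- tapply_add(qz, prz[, 1], -fl$pairs_q$z / 2)
  qz <- tapply_add(qz, prz[, 2], -fl$pairs_q$z / 2)
  qz[topo$top] <- qz[topo$top] - q_top_cell / 2
  if (length(fl$q_bottom) > 0) {
    qz[topo$bottom] <- qz[topo$bottom] - fl$q_bottom / 2
  }
  dims <- dim(grid$mask)
  mk <- function(v) {
    a <- array(0, dim = dims)
    a[topo$active] <- v
    a
  }
  list(qx = mk(qx), qy = mk(qy), qz = mk(qz))
}
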