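#' Age- and order-structured root hydraulic parameter sets
#'
#' Six parameters describe the root hydraulic architecture: radial
#' conductivity `kr` (cm hPa^-1 d^-1) and axial conductance `Kx`
#' (cm4 hPa^-1 d^-1) for the taproot (`T`), young laterals (`Ly`, younger
#' than `age_threshold` days) and old laterals (`Lo`). Radial conductivity
#' of old laterals may not exceed that of young ones (casparian-band
#' maturation lowers the radial pathway's conductivity with age).
#'
#' The defaults are the optimal values found by tracer-map inversion for a
#' 25-day lupin: `kr_Ly = 1e-2`, `kr_Lo = 1e-3` cm hPa^-1 d^-1 and
#' `Kx_T = 1` cm4 hPa^-1 d^-1, with lateral axial conductances set
#' non-limiting and a small taproot radial conductivity (the tracer pattern
#' is insensitive to `kr_T`).
#'
#' @param kr_T,kr_Ly,kr_Lo radial conductivities (cm hPa^-1 d^-1).
#' @param Kx_T,Kx_Ly,Kx_Lo axial conductances (cm4 hPa^-1 d^-1).
#' @param age_threshold age separating young from old laterals (d).
#' @return A `hydraulic_params` list.
#' @export
hydraulic_params <- function(kr_T = 1e-4, kr_Ly = 1e-2, kr_Lo = 1e-3,
                             Kx_T = 1, Kx_Ly = 1e-1, Kx_Lo = 1e-2,
                             age_threshold = 5) {
  vals <- c(kr_T = kr_T, kr_Ly = kr_Ly, kr_Lo = kr_Lo,
            Kx_T = Kx_T, Kx_Ly = Kx_Ly, Kx_Lo = Kx_Lo)
  if (any(vals <= 0)) abort("all hydraulic parameters must be > 0")
  if (kr_Lo > kr_Ly + 1e-300) {
    abort("kr_Lo must not exceed kr_Ly (radial conductivity decreases with age)")
  }
  structure(c(as.list(vals), list(age_threshold = age_threshold)),
            class = "hydraulic_params")
}

#' Assign per-segment hydraulic parameters
#'
#' Classifies segments into `T`/`Ly`/`Lo` at time `t` (see
#' [classify_segments()]) and attaches the matching `kr` and `Kx`.
#'
#' @param rs a `root_system`.
#' @param params a `hydraulic_params`.
#' @param t evaluation time (DAS).
#' @return `rs` with added columns `class`, `kr`, `Kx`.
#' @export
assign_segment_params <- function(rs, params, t = system_time(rs)) {
  rc <- classify_segments(rs, t, age_threshold = params$age_threshold)
  kr_map <- c(T = params$kr_T, Ly = params$kr_Ly, Lo = params$kr_Lo)
  kx_map <- c(T = params$Kx_T, Ly = params$Kx_Ly, Lo = params$Kx_Lo)
  out <- as_tibble(rc)
  out$kr <- unname(kr_map[out$class])
  out$Kx <- unname(kx_map[out$class])
  if (anyNA(out$kr)) abort("unclassified segment")
  reclass_rs(out, rs)
}

#' Solve water flow in the root xylem network
#'
#' Doussan-type linear network solver. Each segment exchanges water radially
#' with the soil, `J_r,i = kr_i * (2 pi r_i l_i) * (H_soil,i - H_x,i)`, and
#' conducts water axially, `J_x,i = (Kx_i / l_i) * (H_x,i - H_x,parent)`
#' (positive toward the collar), where `H` are total water potentials (hPa,
#' gravity included). Kirchhoff balance at every distal node plus a collar
#' boundary condition (prescribed transpiration flux, or prescribed collar
#' potential) closes the sparse symmetric system.
#'
#' @param rs a `root_system` carrying `kr` and `Kx` columns (see
#'   [assign_segment_params()]).
#' @param soil_h total soil water potential (hPa) seen by each segment, in
#'   segment row order (bulk potential of the voxel holding the midpoint).
#' @param collar_bc either `list(flux = Q)` (transpiration, cm3/d, positive
#'   out of the soil) or `list(potential = H)` (hPa, total potential at the
#'   collar).
#' @return A `root_flow` list: per-segment tibble `fluxes` (`id`, `order`,
#'   `class`, `H_x` at the distal node, `radial_flux`, `axial_flux`, both
#'   cm3/d), `collar_flux` (cm3/d), `collar_potential` (hPa), and the
#'   maximum relative Kirchhoff residual `kirchhoff_resid`.
#' @export
solve_xylem <- function(rs, soil_h, collar_bc) {
  if (!all(c("kr", "Kx") %in% names(rs))) {
    abort("run assign_segment_params() first: kr/Kx columns missing")
  }
  n <- nrow(rs)
  if (length(soil_h) == 1) soil_h <- rep(soil_h, n)
  if (length(soil_h) != n) abort("soil_h must have one value per segment")
  geom <- segment_geometry(rs)
  len <- geom$length
  c_ax <- rs$Kx / len                       # cm3 hPa^-1 d^-1 between nodes
  c_r <- rs$kr * 2 * pi * rs$radius * len   # cm3 hPa^-1 d^-1 to the soil
  flux_bc <- !is.null(collar_bc$flux)
  if (flux_bc && all(c_r <= 0)) {
    abort("infeasible: flux-controlled collar with no radial conductivity")
  }
  # nodes: 1 = collar, 1 + i = distal node of segment i
  node_i <- seq_len(n) + 1L
  parent_node <- ifelse(rs$parent_id == 0L, 1L,
                        match(rs$parent_id, rs$id) + 1L)
  if (anyNA(parent_node)) abort("disconnected network: unknown parent")
  nn <- n + 1L
  ii <- c(node_i, parent_node, node_i, parent_node)
  jj <- c(parent_node, node_i, node_i, parent_node)
  xx <- c(-c_ax, -c_ax, c_ax, c_ax)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn)) +
    Matrix::Diagonal(nn, x = c(0, c_r))
  b <- c(0, c_r * soil_h)
  if (flux_bc) {
    b[1] <- b[1] - collar_bc$flux
    # regularise the collar row: with no radial term at the collar the
    # system is singular only if all kr are zero (checked above)
    sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                    error = function(e) abort(paste(
                      "singular xylem system:", conditionMessage(e))))
  } else {
    # Dirichlet at the collar
    Hc <- collar_bc$potential
    b2 <- b[-1] + c_ax * Hc * (parent_node == 1L)
    A22 <- A[-1, -1, drop = FALSE]
    sol <- c(Hc, as.numeric(Matrix::solve(A22, b2)))
  }
  H_x <- sol[node_i]
  radial <- c_r * (soil_h - H_x)
  axial <- c_ax * (H_x - sol[parent_node])
  collar_flux <- sum(radial)
  # Kirchhoff residual at distal nodes: inflow radial + from children = axial out
  child_in <- tapply_add(numeric(nn), parent_node, axial)
  resid <- radial + child_in[node_i] - axial
  scale <- max(abs(radial), abs(axial), 1e-12)
  out <- list(
    fluxes = tibble(id = rs$id, order = rs$order,
                    class = if ("class" %in% names(rs)) rs$class else NA,
                    H_x = H_x, radial_flux = radial, axial_flux = axial),
    collar_flux = collar_flux,
    collar_potential = sol[1],
    kirchhoff_resid = max(abs(resid)) / scale
  )
  structure(out, class = "root_flow")
}

#' Whole-root-system conductance
#'
#' `Krs` is the collar flux per unit difference between a uniform soil total
#' potential and the collar potential (cm3 hPa^-1 d^-1). `krs` is `Krs`
#' normalised by the total root surface area and converted to
#' m MPa^-1 s^-1.
#'
#' @param rs a `root_system`.
#' @param params a `hydraulic_params`.
#' @param t evaluation time (DAS).
#' @return Tibble with `Krs_cm3_hPa_d`, `krs_m_MPa_s`, `surface_cm2`, and
#'   the radial-only upper bound `sum_krA_cm3_hPa_d`.
#' @export
compute_Krs <- function(rs, params, t = system_time(rs)) {
  rsp <- assign_segment_params(rs, params, t)
  geom <- segment_geometry(rsp)
  surface <- sum(2 * pi * rsp$radius * geom$length)
  if (surface <= 0) abort("zero root surface area")
  sol <- solve_xylem(rsp, soil_h = 0, collar_bc = list(potential = -1))
  Krs <- sol$collar_flux / 1
  tibble(
    Krs_cm3_hPa_d = Krs,
    krs_m_MPa_s = Krs / surface * KR_CM_HPA_D_TO_M_MPA_S,
    surface_cm2 = surface,
    sum_krA_cm3_hPa_d = sum(rsp$kr * 2 * pi * rsp$radius * geom$length)
  )
}

#' Map per-segment radial uptake onto the soil grid
#'
#' Deposits each segment's radial flux into the voxel containing its
#' midpoint and divides by the voxel volume, yielding the water uptake
#' density (WUD, cm3 of water per day per cm3 of soil). Total uptake is
#' conserved exactly.
#'
#' @param solution a `root_flow` from [solve_xylem()].
#' @param rs the `root_system` the solution was computed on.
#' @param grid a `soil_grid`.
#' @return 3-d array of WUD values (0 outside the mask).
#' @export
sink_to_grid <- function(solution, rs, grid) {
  geom <- segment_geometry(rs)
  idx <- locate_cells(grid, geom$xm, geom$ym, geom$zm)
  if (anyNA(idx)) abort("segment midpoint outside the masked soil domain")
  wud <- array(0, dim = dim(grid$mask))
  add <- rowsum(solution$fluxes$radial_flux, idx)
  wud[as.integer(rownames(add))] <- add[, 1] / voxel_volume(grid)
  wud
}

#' Locate points on the grid
#'
#' @param grid a `soil_grid`.
#' @param x,y,z point coordinates (cm).
#' @return Linear cell indices into the grid arrays; `NA` outside the mask.
#' @export
locate_cells <- function(grid, x, y, z) {
  dx <- grid$dx
  i <- pmin(pmax(1L, as.integer(ceiling((x + grid$nx * dx / 2) / dx))), grid$nx)
  j <- pmin(pmax(1L, as.integer(ceiling((y + grid$ny * dx / 2) / dx))), grid$ny)
  k <- pmin(pmax(1L, as.integer(ceiling(-z / dx))), grid$nz)
  idx <- i + (j - 1L) * grid$nx + (k - 1L) * grid$nx * grid$ny
  ifelse(grid$mask[idx], idx, NA_integer_)
}

#' Total soil water potential (hPa) seen by each segment
#'
#' Bulk matric potential of the voxel containing the segment midpoint,
#' converted from cm of water to hPa, plus the gravitational term.
#'
#' @param rs a `root_system`.
#' @param grid a `soil_grid` with a valid `h` field.
#' @return Numeric vector (hPa), one value per segment.
#' @export
soil_potential_at_segments <- function(rs, grid) {
  geom <- segment_geometry(rs)
  idx <- locate_cells(grid, geom$xm, geom$ym, geom$zm)
  if (anyNA(idx)) abort("segment midpoint outside the masked soil domain")
  (grid$h[idx] + geom$zm) * CM_H2O_TO_HPA
}
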