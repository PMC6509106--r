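test_that("parameter sets enforce positivity and the age ordering of kr", {
  expect_error(hydraulic_params(kr_Lo = 2e-2, kr_Ly = 1e-2), "kr_Lo")
  expect_error(hydraulic_params(Kx_T = 0), "> 0")
  p <- hydraulic_params()
  expect_equal(p$age_threshold, 5)
})

test_that("segment parameters switch class as a lateral crosses the age threshold", {
  rs <- toy_system(timestamp = 10)
  p <- hydraulic_params()
  a9 <- assign_segment_params(rs, p, t = 9)   # id 4 aged 3 d -> Ly
  a12 <- assign_segment_params(rs, p, t = 12) # id 4 aged 6 d -> Lo
  expect_equal(a9$kr[a9$id == 4], p$kr_Ly)
  expect_equal(a12$kr[a12$id == 4], p$kr_Lo)
  expect_true(all(a9$kr[a9$order == 1] == p$kr_T))
  expect_true(all(a9$Kx[a9$order == 1] == p$Kx_T))
})

test_that("a single segment in the high-Kx limit behaves as one radial resistor", {
  rs <- with_hydraulics(one_segment(length = 1, radius = 0.05),
                        kr = 0.01, Kx = 1e6)
  sol <- solve_xylem(rs, soil_h = 0, collar_bc = list(potential = -100))
  A <- 2 * pi * 0.05 * 1
  expect_equal(sol$collar_flux, 0.01 * A * 100, tolerance = 1e-4)
})

test_that("two segments in series match the hand-built resistor network", {
  seg2 <- tibble::tibble(id = 1:2, parent_id = c(0L, 1L), axis_id = 1L,
                         x = 0, y = 0, z = c(-1, -2), radius = 0.05,
                         order = 1L, birth = c(0, 1), origination = c(1, 2))
  rs <- with_hydraulics(root_system(seg2, timestamp = 10),
                        kr = c(0.02, 0.01), Kx = c(0.5, 0.3))
  Hs <- c(-50, -80); Hc <- -500
  sol <- solve_xylem(rs, Hs, collar_bc = list(potential = Hc))
  cr <- c(0.02, 0.01) * 2 * pi * 0.05
  cax <- c(0.5, 0.3)
  Amat <- rbind(c(cax[1] + cax[2] + cr[1], -cax[2]),
                c(-cax[2], cax[2] + cr[2]))
  Hx <- solve(Amat, c(cr[1] * Hs[1] + cax[1] * Hc, cr[2] * Hs[2]))
  expect_equal(sol$collar_flux, cax[1] * (Hx[1] - Hc), tolerance = 1e-10)
  expect_equal(sol$fluxes$H_x, Hx, tolerance = 1e-8)
  expect_lt(sol$kirchhoff_resid, 1e-8)
})

test_that("flux control delivers the prescribed transpiration exactly", {
  for (s in 1:20) {
    rs <- random_tree(s, n = 15)
    set.seed(s)
    rsp <- with_hydraulics(rs, kr = runif(15, 1e-4, 1e-2),
                           Kx = runif(15, 1e-3, 1))
    Hs <- rnorm(15, -100, 20)
    Q <- runif(1, 0.1, 2)
    sol <- solve_xylem(rsp, Hs, collar_bc = list(flux = Q))
    expect_equal(sum(sol$fluxes$radial_flux), Q, tolerance = 1e-8 * Q)
    expect_lt(sol$kirchhoff_resid, 1e-8)
  }
  # all-zero radial conductivity is infeasible under flux control
  rs0 <- with_hydraulics(one_segment(), kr = 0, Kx = 1)
  expect_error(solve_xylem(rs0, 0, collar_bc = list(flux = 1)), "infeasible")
})

test_that("whole-system conductance is bounded by the radial-only sum", {
  rs <- random_tree(42, n = 20)
  for (s in 1:50) {
    set.seed(s + 500)
    p <- hydraulic_params(kr_T = runif(1, 1e-5, 1e-2),
                          kr_Ly = 10^runif(1, -4, -1),
                          kr_Lo = 10^runif(1, -5, -4),
                          Kx_T = 10^runif(1, -3, 1),
                          Kx_Ly = 10^runif(1, -3, 1),
                          Kx_Lo = 10^runif(1, -3, 1))
    kk <- compute_Krs(rs, p)
    expect_lte(kk$Krs_cm3_hPa_d, kk$sum_krA_cm3_hPa_d * (1 + 1e-9))
  }
  # radial-only limit: uniform kr and huge Kx -> krs equals kr (converted)
  p_lim <- hydraulic_params(kr_T = 1e-3, kr_Ly = 1e-3, kr_Lo = 1e-3,
                            Kx_T = 1e7, Kx_Ly = 1e7, Kx_Lo = 1e7)
  kk <- compute_Krs(rs, p_lim)
  expect_equal(kk$krs_m_MPa_s, 1e-3 * 1e2 / 86400, tolerance = 1e-3)
})

test_that("collar flux rises monotonically with every conductivity", {
  rs <- random_tree(9, n = 15)
  base <- hydraulic_params()
  flux_of <- function(p) {
    rsp <- assign_segment_params(rs, p, t = 30)
    solve_xylem(rsp, soil_h = -50,
                collar_bc = list(potential = -5000))$collar_flux
  }
  f0 <- flux_of(base)
  for (nm in c("kr_T", "kr_Ly", "kr_Lo", "Kx_T", "Kx_Ly", "Kx_Lo")) {
    up <- base
    up[[nm]] <- up[[nm]] * 1.5
    expect_gte(flux_of(do.call(hydraulic_params, up[1:7])), f0 - 1e-12)
  }
})

test_that("uptake concentrates near the tips when young laterals conduct more", {
  rs <- small_synth()
  p <- hydraulic_params()
  rsp <- assign_segment_params(rs, p)
  sol <- solve_xylem(rsp, soil_h = -60, collar_bc = list(potential = -3000))
  g <- segment_geometry(rsp)
  g$radial <- sol$fluxes$radial_flux
  per_axis <- g %>%
    dplyr::filter(.data$order > 1) %>%
    dplyr::group_by(.data$axis_id) %>%
    dplyr::mutate(pos = cumsum(.data$length) / sum(.data$length)) %>%
    dplyr::summarise(
      tip_share = sum(.data$radial[.data$pos > 0.5]) / sum(.data$radial),
      n = dplyr::n()) %>%
    dplyr::filter(.data$n >= 2, is.finite(.data$tip_share))
  expect_gt(mean(per_axis$tip_share), 0.5)
})

test_that("the uptake sink is deposited on midpoint voxels and conserved", {
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, 0.5, vg = vg), 0.3, vg)
  # one segment with a midpoint at a known voxel centre
  seg <- tibble::tibble(id = 1L, parent_id = 0L, axis_id = 1L,
                        x = 0.25, y = 0.25, z = -1.5, radius = 0.05,
                        order = 1L, birth = 0, origination = 1)
  rs <- with_hydraulics(root_system(seg, collar = c(0.25, 0.25, -1), timestamp = 10),
                        kr = 0.01, Kx = 10)
  sol <- solve_xylem(rs, -50, collar_bc = list(flux = 0.4))
  wud <- sink_to_grid(sol, rs, g)
  idx <- locate_cells(g, 0.25, 0.25, -1.25)
  expect_equal(wud[idx], 0.4 / voxel_volume(g))
  expect_equal(sum(wud) * voxel_volume(g), 0.4, tolerance = 1e-12)

  # random fixture: totals conserved
  rs2 <- random_tree(5, n = 12)
  rsp2 <- assign_segment_params(rs2, hydraulic_params(), t = 30)
  sol2 <- solve_xylem(rsp2, -60, collar_bc = list(flux = 1.3))
  wud2 <- sink_to_grid(sol2, rsp2, g)
  expect_equal(sum(wud2) * voxel_volume(g), 1.3, tolerance = 1e-9)
})

test_that("midpoint allocation differs boundedly from length-weighted splitting", {
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, 0.5, vg = vg), 0.3, vg)
  # a segment straddling two voxels vertically
  seg <- tibble::tibble(id = 1L, parent_id = 0L, axis_id = 1L,
                        x = 0.25, y = 0.25, z = -1.8, radius = 0.05,
                        order = 1L, birth = 0, origination = 1)
  rs <- with_hydraulics(root_system(seg, collar = c(0.25, 0.25, -1.2), timestamp = 10),
                        kr = 0.01, Kx = 10)
  sol <- solve_xylem(rs, -50, collar_bc = list(flux = 0.3))
  wud <- sink_to_grid(sol, rs, g)
  # length-weighted oracle: split the 0.6 cm segment across the two voxels
  # it crosses (0.3 cm in each of layers 3 and 4)
  lw <- array(0, dim = dim(g$mask))
  i3 <- locate_cells(g, 0.25, 0.25, -1.25)
  i4 <- locate_cells(g, 0.25, 0.25, -1.75)
  lw[i3] <- 0.3 * (0.3 / 0.6) / voxel_volume(g)
  lw[i4] <- 0.3 * (0.3 / 0.6) / voxel_volume(g)
  # same total, difference bounded by the flux of one voxel's worth
  expect_equal(sum(wud), sum(lw), tolerance = 1e-12)
  expect_lte(max(abs(wud - lw)), 0.3 / voxel_volume(g) / 2 + 1e-12)
})
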