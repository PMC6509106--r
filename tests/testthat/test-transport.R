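uniform_flow_grid <- function(theta = 0.3, qz = -0.6, dx = 0.5) {
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, dx, vg = vg), theta, vg)
  dims <- dim(g$mask)
  list(grid = g,
       vel = list(qx = array(0, dims), qy = array(0, dims),
                  qz = array(qz, dims)))
}

test_that("transport parameter invariants are enforced", {
  expect_error(transport_params(alpha_T = 0.3, alpha_L = 0.25), "alpha_T")
  expect_error(transport_params(Dm = -1), "negative")
  expect_error(particle_ensemble(0), "> 0")
})

test_that("injection adds the prescribed tracer mass through the top face", {
  u <- uniform_flow_grid()
  p <- particle_ensemble(1e-5)
  p <- inject_particles(p, u$grid, flux = 10, concentration = 1, dt = 1)
  expect_equal(p$injected_mass, 0.01)          # 10 cm3 at 1 mmol/l
  expect_equal(in_domain_mass(p), 0.01)
  expect_true(all(p$pos[, 3] > -u$grid$dx))
  # zero concentration adds nothing
  p0 <- inject_particles(particle_ensemble(1e-5), u$grid, 10, 0, 1)
  expect_equal(nrow(p0$pos), 0)
  expect_error(inject_particles(p, u$grid, -1, 1, 1), "negative")
})

test_that("the injection ledger matches quadrature over a random schedule", {
  u <- uniform_flow_grid()
  set.seed(99)
  p <- particle_ensemble(1e-6)
  total <- 0
  for (i in 1:40) {
    f <- runif(1, 0, 25); dt <- runif(1, 0.005, 0.02)
    p <- inject_particles(p, u$grid, f, 1, dt)
    total <- total + f * 1 * dt * 1e-3
  }
  expect_equal(in_domain_mass(p), total, tolerance = 1e-12)
  expect_equal(p$injected_mass, total, tolerance = 1e-12)
})

test_that("particles do not move without velocity or dispersion", {
  u <- uniform_flow_grid(qz = 0)
  tp <- transport_params(Dm = 0, alpha_L = 0, alpha_T = 0)
  p <- particle_ensemble(1e-5)
  p$pos <- cbind(x = c(0, 0.7), y = c(0, -0.4), z = c(-3, -6))
  p2 <- advect_disperse_step(p, u$grid, u$vel, tp, 0.1)
  expect_equal(p2$pos, p$pos)
})

test_that("plug flow displaces particles by exactly v dt", {
  u <- uniform_flow_grid(theta = 0.3, qz = -0.6)
  tp <- transport_params(Dm = 0, alpha_L = 0, alpha_T = 0)
  p <- particle_ensemble(1e-5)
  p$pos <- cbind(x = 0, y = 0, z = -3)
  p2 <- advect_disperse_step(p, u$grid, u$vel, tp, 0.1)
  expect_equal(unname(p2$pos[1, 3]), -3 - 0.6 / 0.3 * 0.1, tolerance = 1e-12)
})

test_that("a pulse in uniform flow matches the analytic dispersion Gaussian", {
  set.seed(202)
  u <- uniform_flow_grid(theta = 0.3, qz = -0.6)
  tp <- transport_params(n_particles = 1e5)
  p <- particle_ensemble(1e-5)
  n <- 1e5
  p$pos <- cbind(x = runif(n, -0.5, 0.5), y = runif(n, -0.5, 0.5),
                 z = rep(-3, n))
  v <- -0.6 / 0.3
  t_tot <- 0.5
  for (i in 1:25) {
    p <- advect_disperse_step(p, u$grid, u$vel, tp, t_tot / 25)
  }
  DL <- tp$alpha_L * abs(v) + tp$Dm
  DT <- tp$alpha_T * abs(v) + tp$Dm
  expect_lt(abs(mean(p$pos[, 3]) - (-3 + v * t_tot)) / abs(v * t_tot), 0.01)
  expect_lt(abs(var(p$pos[, 3]) - 2 * DL * t_tot) / (2 * DL * t_tot), 0.03)
  # transverse variance growth on top of the initial uniform spread
  expect_lt(abs((var(p$pos[, 1]) - 1 / 12) - 2 * DT * t_tot) /
              (2 * DT * t_tot), 0.1)
})

test_that("oversized transport steps are rejected", {
  u <- uniform_flow_grid(theta = 0.05, qz = -3)
  p <- particle_ensemble(1e-5)
  p$pos <- cbind(x = 0, y = 0, z = -5)
  expect_error(advect_disperse_step(p, u$grid, u$vel, transport_params(), 1),
               "too large")
})

test_that("binned concentrations conserve mass and match hand arithmetic", {
  u <- uniform_flow_grid(theta = 0.35, dx = 0.25)
  p <- particle_ensemble(2e-6)
  # all mass inside one voxel
  p$pos <- cbind(x = rep(0.06, 50), y = rep(0.06, 50), z = rep(-0.06, 50))
  conc <- bin_concentration(p, u$grid)
  idx <- locate_cells(u$grid, 0.06, 0.06, -0.06)
  expect_equal(conc[idx], 50 * 2e-6 / (0.35 * 0.25^3) * 1000)
  expect_equal(sum(conc[u$grid$mask] == 0), sum(u$grid$mask) - 1)
  # conservation on a scattered cloud
  set.seed(5)
  p$pos <- cbind(x = runif(400, -1, 1), y = runif(400, -1, 1),
                 z = runif(400, -9, -0.1))
  conc2 <- bin_concentration(p, u$grid)
  tot <- sum(conc2[u$grid$mask] * u$grid$theta[u$grid$mask]) *
    voxel_volume(u$grid) / 1000
  expect_equal(tot, 400 * 2e-6, tolerance = 1e-12)
})

test_that("steady feed at constant concentration approaches the inflow level in the effluent", {
  set.seed(31)
  u <- uniform_flow_grid(theta = 0.3, qz = -1.5)
  tp <- transport_params(n_particles = 2e4)
  area <- sum(u$grid$mask2d) * u$grid$dx^2
  flux <- 1.5 * area            # cm3/d through the column
  p <- particle_ensemble(flux * 1 * 8 * 1e-3 / 2e4)
  dt <- 0.02
  effl <- list()
  for (i in seq_len(round(8 / dt))) {
    p <- inject_particles(p, u$grid, flux, 1, dt)
    p <- advect_disperse_step(p, u$grid, u$vel, tp, dt, t = i * dt,
                              bottom_open = TRUE)
  }
  # after ~4 pore volumes the effluent concentration equals the feed
  late <- p$exit_log[p$exit_log$t > 6, ]
  water <- flux * 2 # cm3 drained over the last 2 d
  conc <- sum(late$mass) / water * 1000
  expect_lt(abs(conc - 1), 0.02)
})

test_that("depth profiles are statistically invariant when the particle budget doubles", {
  run_profile <- function(n, seed) {
    set.seed(seed)
    u <- uniform_flow_grid(theta = 0.3, qz = -0.8)
    tp <- transport_params()
    p <- particle_ensemble(1e-5)
    p$pos <- cbind(x = runif(n, -1, 1), y = runif(n, -1, 1), z = rep(-2, n))
    for (i in 1:10) p <- advect_disperse_step(p, u$grid, u$vel, tp, 0.05)
    p$pos[, 3]
  }
  a <- run_profile(4000, 1)
  b <- run_profile(8000, 2)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("tracer is conserved under an active water sink (exclusion)", {
  # water leaves through the root sink; tracer stays behind and its binned
  # concentration rises where the sink dried the soil
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, 0.5, vg = vg), 0.3, vg)
  rs <- small_synth()
  rsp <- assign_segment_params(rs, hydraulic_params())
  set.seed(77)
  p <- particle_ensemble(1e-6)
  p$pos <- cbind(x = runif(3000, -1.5, 1.5), y = runif(3000, -1.5, 1.5),
                 z = runif(3000, -4, -0.1))
  m0 <- total_mass(p)
  c_before <- bin_concentration(p, g)
  sol <- solve_xylem(rsp, soil_potential_at_segments(rsp, g),
                     collar_bc = list(flux = 30))
  sink <- sink_to_grid(sol, rsp, g)
  r <- richards_step(g, vg, sink = sink,
                     bc = list(top_flux = 0, bottom = "no_flux"), dt = 0.1)
  p2 <- advect_disperse_step(p, r$grid, r$velocity, transport_params(), 0.01)
  expect_equal(total_mass(p2), m0, tolerance = 1e-12)
  c_after <- bin_concentration(p2, r$grid)
  hot <- sink > stats::quantile(sink[sink > 0], 0.8)
  expect_gt(mean(c_after[hot] - c_before[hot], na.rm = TRUE), 0)
})
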