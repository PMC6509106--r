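test_that("retention and conductivity honour the closed-form limits", {
  vg <- vg_params()
  expect_equal(vg_retention(0, vg), vg$theta_s)
  expect_equal(vg_conductivity(0, vg), vg$Ks)
  expect_equal(vg_retention(-1e9, vg), vg$theta_r, tolerance = 1e-9)
  expect_lt(vg_conductivity(-1e5, vg), 1e-8)
  # monotone non-decreasing in h
  h <- seq(-200, 0, by = 0.5)
  expect_true(all(diff(vg_retention(h, vg)) >= 0))
  expect_true(all(diff(vg_conductivity(h, vg)) >= 0))
  # head inversion
  th <- vg_retention(h, vg)
  expect_equal(vg_head(th[h < 0], vg), h[h < 0], tolerance = 1e-6)
  expect_error(vg_params(n = 0.9), "n > 1")
})

test_that("the closed forms agree with an independent scalar implementation", {
  vg <- vg_params()
  # independent transliteration of the van Genuchten-Mualem formulas
  ref <- function(h) {
    m <- 1 - 1 / vg$n
    Se <- (1 + (vg$alpha * abs(h))^vg$n)^(-m)
    theta <- vg$theta_r + Se * (vg$theta_s - vg$theta_r)
    K <- vg$Ks * sqrt(Se) * (1 - (1 - Se^(1 / m))^m)^2
    c(theta = theta, K = K)
  }
  for (h in c(-30, -5, -75, -123.4)) {
    r <- ref(h)
    expect_equal(vg_retention(h, vg), unname(r["theta"]), tolerance = 1e-12)
    expect_equal(vg_conductivity(h, vg), unname(r["K"]), tolerance = 1e-12)
  }
})

test_that("voxelizing the 5 cm disc reproduces the experimental area ratio", {
  g <- build_column_grid(diameter = 5, height = 10, dx = 0.25)
  expect_equal(round(g$area_ratio, 1), 1.1)
  # refinement limit
  g_fine <- build_column_grid(diameter = 5, height = 10, dx = 0.025)
  expect_lt(g_fine$area_ratio, 1.02)
  # brute-force rasterizer oracle: a square intersects the disc iff its
  # nearest point to the axis lies inside
  brute <- 0L
  dx <- 0.25
  for (i in 1:20) for (j in 1:20) {
    xs <- c((i - 1) * dx - 2.5, i * dx - 2.5)
    ys <- c((j - 1) * dx - 2.5, j * dx - 2.5)
    cx <- min(max(0, xs[1]), xs[2]); cy <- min(max(0, ys[1]), ys[2])
    if (cx^2 + cy^2 < 2.5^2) brute <- brute + 1L
  }
  expect_equal(sum(g$mask2d), brute)
  expect_error(build_column_grid(diameter = 5, dx = 6), "degenerate")
  expect_error(build_column_grid(diameter = 5, height = 10, dx = 0.3),
               "divide")
})

test_that("boundary flows are weighted by the surface-area ratio", {
  expect_equal(weight_flux(10, 1.1), 11)
  expect_equal(weight_flux(7.3, 1), 7.3)
  w <- weight_flux(3.21, 1.095)
  expect_equal(w / 1.095, 3.21, tolerance = 1e-15)
  expect_error(weight_flux(-1, 1.1), "non-negative")
})

test_that("a hydrostatic column is a steady state of the Richards step", {
  vg <- vg_params()
  g <- build_column_grid(5, 10, 0.5, vg = vg)
  zc <- array(rep(g$zc, each = g$nx * g$ny), dim = dim(g$mask))
  g <- grid_set_head(g, -100 - zc, vg)
  r <- richards_step(g, vg, sink = 0,
                     bc = list(top_flux = 0, bottom = "no_flux"), dt = 1)
  expect_lt(max(abs(r$grid$theta[g$mask] - g$theta[g$mask])), 1e-6)
})

test_that("a uniform sink removes exactly the prescribed water volume", {
  vg <- vg_params()
  g <- build_column_grid(5, 10, 0.5, vg = vg)
  zc <- array(rep(g$zc, each = g$nx * g$ny), dim = dim(g$mask))
  g <- grid_set_head(g, -100 - zc, vg)
  S <- 0.01
  r <- richards_step(g, vg, sink = S,
                     bc = list(top_flux = 0, bottom = "no_flux"), dt = 0.5)
  expect_equal(mean(r$grid$theta[g$mask] - g$theta[g$mask]), -S * 0.5,
               tolerance = 1e-9)
  expect_lt(r$balance$rel_error, 1e-3)
})

test_that("drainage with no sink dries the column monotonically and conserves mass", {
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, 0.5, vg = vg), 0.35, vg)
  w0 <- water_volume(g)
  out <- 0
  for (i in 1:4) {
    r <- richards_step(g, vg, sink = 0,
                       bc = list(top_flux = 0, bottom = "free_drainage"),
                       dt = 0.05)
    expect_true(all(r$grid$theta[g$mask] <= g$theta[g$mask] + 1e-9))
    expect_lt(r$balance$rel_error, 1e-3)
    g <- r$grid
    out <- out + r$effluent
  }
  expect_equal(w0 - water_volume(g), out, tolerance = 1e-6)
})

test_that("an isotropic problem is invariant under swapping the horizontal axes", {
  vg <- vg_params()
  mk <- function(axis) {
    g <- build_column_grid(5, 10, 0.5, vg = vg)
    cc <- if (axis == "x") g$xc else g$yc
    prof <- 0.12 + 0.08 * (cc + 2.5) / 5
    th <- if (axis == "x") {
      array(rep(prof, times = g$ny * g$nz), dim = dim(g$mask))
    } else {
      array(rep(rep(prof, each = g$nx), times = g$nz), dim = dim(g$mask))
    }
    grid_set_theta(g, th, vg)
  }
  gx <- mk("x"); gy <- mk("y")
  rx <- richards_step(gx, vg, bc = list(top_flux = 0, bottom = "no_flux"),
                      dt = 0.02)
  ry <- richards_step(gy, vg, bc = list(top_flux = 0, bottom = "no_flux"),
                      dt = 0.02)
  expect_equal(aperm(rx$grid$theta, c(2, 1, 3)), ry$grid$theta,
               tolerance = 1e-9)
})

test_that("infiltration is consistent under space-time refinement", {
  vg <- vg_params()
  front_depth <- function(dx, dt) {
    g <- grid_set_theta(build_column_grid(2, 10, dx, vg = vg), 0.06, vg)
    flux <- 3 # cm3/d over the small column
    nstep <- round(0.5 / dt)
    for (i in seq_len(nstep)) {
      r <- richards_step(g, vg, bc = list(top_flux = flux,
                                          bottom = "no_flux"), dt = dt)
      g <- r$grid
    }
    prof <- vapply(seq_len(g$nz), function(k) {
      mean(g$theta[, , k][g$mask2d])
    }, numeric(1))
    # wetting front: deepest layer centre with theta above the midpoint
    thr <- 0.06 + (max(prof) - 0.06) / 2
    depths <- (seq_len(g$nz) - 0.5) * dx
    stats::approx(prof, depths, xout = thr)$y
  }
  coarse <- front_depth(0.5, 0.025)
  fine <- front_depth(0.25, 0.00625)
  expect_lt(abs(coarse - fine) / fine, 0.05)
})

test_that("a seepage bottom holds the column near saturation under irrigation", {
  vg <- vg_params()
  g <- grid_set_theta(build_column_grid(5, 10, 0.5, vg = vg), 0.35, vg)
  for (i in 1:6) {
    r <- richards_step(g, vg, bc = list(top_flux = 20, bottom = "seepage"),
                       dt = 0.1)
    g <- r$grid
  }
  expect_gt(mean(g$theta[g$mask]), 0.33)
  expect_gt(r$effluent, 0)
  expect_lt(r$balance$rel_error, 1e-3)
})
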