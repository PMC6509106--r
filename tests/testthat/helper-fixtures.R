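# Shared fixtures built in code. Expensive objects are computed lazily and
# memoised for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a hand-built 4-segment system: taproot of two 1-cm segments with one
# 2-segment lateral off the first node
toy_system <- function(timestamp = 10) {
  seg <- tibble::tibble(
    id = 1:4,
    parent_id = c(0L, 1L, 1L, 3L),
    axis_id = c(1L, 1L, 2L, 2L),
    x = c(0, 0, 0.8, 1.6),
    y = c(0, 0, 0, 0),
    z = c(-1, -2, -1.1, -1.2),
    radius = c(0.055, 0.055, 0.03, 0.03),
    order = c(1L, 1L, 2L, 2L),
    birth = c(0, 1, 2, 4),
    origination = c(1, 2, 4, 6)
  )
  root_system(seg, timestamp = timestamp)
}

# single straight vertical segment
one_segment <- function(length = 1, radius = 0.05, z0 = 0) {
  seg <- tibble::tibble(id = 1L, parent_id = 0L, axis_id = 1L,
                        x = 0, y = 0, z = z0 - length, radius = radius,
                        order = 1L, birth = 0, origination = 1)
  root_system(seg, collar = c(0, 0, z0), timestamp = 10)
}

with_hydraulics <- function(rs, kr, Kx) {
  out <- tibble::as_tibble(rs)
  out$kr <- kr
  out$Kx <- Kx
  structure(out, class = class(rs), collar = attr(rs, "collar"),
            timestamp = attr(rs, "timestamp"))
}

# random small branched architectures for property checks
random_tree <- function(seed, n = 25) {
  set.seed(seed)
  rows <- list(tibble::tibble(id = 1L, parent_id = 0L, axis_id = 1L,
                              x = 0, y = 0, z = -0.4, radius = 0.05,
                              order = 1L, birth = 0, origination = 0.5))
  for (i in 2:n) {
    parent <- rows[[sample.int(i - 1, 1)]]
    ord <- min(parent$order + sample(c(0L, 1L), 1, prob = c(0.6, 0.4)), 3L)
    dirv <- rnorm(3); dirv[3] <- -abs(dirv[3])
    dirv <- dirv / sqrt(sum(dirv^2)) * runif(1, 0.2, 0.5)
    pos <- c(parent$x + dirv[1], parent$y + dirv[2],
             min(parent$z + dirv[3], -0.01))
    rows[[i]] <- tibble::tibble(
      id = i, parent_id = parent$id, axis_id = i,
      x = pos[1], y = pos[2], z = max(pos[3], -9.9),
      radius = runif(1, 0.02, 0.06), order = ord,
      birth = parent$origination, origination = parent$origination + runif(1, 0.2, 2))
  }
  root_system(dplyr::bind_rows(rows), timestamp = 30)
}

small_synth <- function() memo("small_synth", generate_rsa(rsa_gen_config(seed = 1)))

# one full virtual experiment with tracer, shared across pipeline and
# acceptance tests (seed 1, 0.5 cm grid)
shared_run <- function() {
  memo("shared_run", {
    ex <- virtual_experiment(seed = 1, dx = 0.5, n_particles = 12000)
    run <- run_forward(ex$rsa_series, ex$timeline, hydraulic_params(),
                       soil = ex$soil, transport = ex$transport,
                       grid = ex$grid, dt_max = 0.05)
    list(ex = ex, run = run)
  })
}

# short inversion-window experiment (redistribution day only) for the
# recovery and sensitivity checks
shared_twin <- function() {
  memo("shared_twin", {
    ex <- virtual_experiment(seed = 3, dx = 0.5, n_particles = 8000,
                             t_start = 24, t_end = 25)
    conc0 <- build_initial_concentration(ex$grid, total_mass = 0.15,
                                         imaged_mass = 0.13,
                                         imaged_depth = 8, slope = 1)
    runner <- make_forward_runner(ex, initial_concentration = conc0,
                                  dt_max = 0.1, merge_width = 1)
    truth <- hydraulic_params()
    list(ex = ex, runner = runner, truth = truth, observed = runner(truth))
  })
}

# coarse twin recovery of the lateral radial conductivities (shared between
# the inversion tests and the acceptance suite)
shared_recovery <- function() {
  memo("recovery", {
    tw <- shared_twin()
    scen <- build_scenarios(n_kr = 3, n_Kx = 2, kr_range = c(1e-3, 1e-1),
                            fixed = list(kr_T = tw$truth$kr_T,
                                         Kx_T = tw$truth$Kx_T,
                                         Kx_Ly = tw$truth$Kx_Ly,
                                         Kx_Lo = tw$truth$Kx_Lo))
    grid_search(scen, tw$runner, tw$observed)
  })
}
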