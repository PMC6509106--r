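#' Configuration of the synthetic lupin-like architecture generator
#'
#' Defaults reproduce the architecture statistics of the 25-day white lupin
#' grown in a 5 cm x 10 cm sand column: elongation rates of 0.43, 0.16 and
#' 0.17 cm/d for orders 1-3, branching densities of 4.8 order-2 laterals per
#' cm of taproot and 3.3 order-3 laterals per cm of order-2 root, mean
#' diameters 0.11/0.06/0.045 cm, mean root lengths 7.7/2.4/0.8 cm, and 79%
#' of root length in the top 3 cm of soil.
#'
#' Each axis elongates at a lognormally distributed rate (CV
#' `cv`) for a fixed per-order growth duration derived from the printed mean
#' root lengths (`mean_root_length_by_order / elongation rate`), which makes
#' the mean final axis lengths match the printed means. Lateral emergence is
#' acropetal with a stochastic delay (`emergence_lag` plus an exponential
#' extra delay `emergence_delay_mean`); the delay spread is calibrated so
#' that the 5-day age threshold splits lateral root length into comparable
#' young and old pools at 25 DAS, as observed. Order-2 insertion density
#' decays with depth (`branching_depth_scale`), calibrated against the
#' printed top-3-cm length fraction.
#'
#' @param taproot_elongation,lateral_elongation_order2,lateral_elongation_order3
#'   axis elongation rates (cm/d).
#' @param density_2_on_1,density_3_on_2 branching densities (laterals per cm
#'   of parent root).
#' @param mean_diameter_by_order mean root diameters (cm), orders 1-3.
#' @param mean_root_length_by_order mean final axis lengths (cm), orders 1-3.
#' @param target_depth_fraction_top3cm fraction of root length in 0-3 cm.
#' @param column_radius,column_height soil column dimensions (cm).
#' @param sowing_to_end length of the simulated growth period (d).
#' @param cv coefficient of variation of per-axis rates and diameters.
#' @param emergence_lag deterministic lag between the creation of a parent
#'   node and lateral emergence (d).
#' @param emergence_delay_mean mean of the additional exponential emergence
#'   delay, per order (d).
#' @param branching_depth_scale e-folding depth (cm) of the order-2
#'   insertion density.
#' @param duration_censoring_adjust per-order multipliers on the growth
#'   durations compensating horizon censoring (axes still elongating at the
#'   observation time pull the realized mean axis length below the mature
#'   length); calibrated once against the printed 25-DAS means.
#' @param insertion_angle_order2,insertion_angle_order3 mean insertion angle
#'   below the horizontal (degrees).
#' @param step_length polyline discretisation step (cm).
#' @param seed RNG seed.
#' @export
rsa_gen_config <- function(taproot_elongation = 0.43,
                           lateral_elongation_order2 = 0.16,
                           lateral_elongation_order3 = 0.17,
                           density_2_on_1 = 4.8,
                           density_3_on_2 = 3.3,
                           mean_diameter_by_order = c(0.11, 0.06, 0.045),
                           mean_root_length_by_order = c(7.7, 2.4, 0.8),
                           target_depth_fraction_top3cm = 0.79,
                           column_radius = 2.5,
                           column_height = 10,
                           sowing_to_end = 25,
                           cv = 0.3,
                           emergence_lag = 1,
                           emergence_delay_mean = c(0, 2, 5),
                           branching_depth_scale = 1.8,
                           duration_censoring_adjust = c(1.1, 1.15, 1.9),
                           insertion_angle_order2 = 20,
                           insertion_angle_order3 = 35,
                           step_length = 0.25,
                           seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(taproot_elongation, lateral_elongation_order2,
             lateral_elongation_order3)
  if (any(rates <= 0) || any(cfg$mean_diameter_by_order <= 0) ||
      density_2_on_1 <= 0 || density_3_on_2 <= 0) {
    abort("rates, densities and diameters must be > 0")
  }
  if (column_radius <= 0 || column_height <= 0) abort("degenerate column")
  cfg$elongation_by_order <- rates
  # per-axis growth duration: printed mean final length / elongation rate,
  # inflated to offset horizon censoring (axes still growing at the end of
  # the experiment pull the realized mean below the mature axis length)
  cfg$growth_duration_by_order <- cfg$mean_root_length_by_order / rates *
    cfg$duration_censoring_adjust
  structure(cfg, class = "rsa_gen_config")
}

# lognormal with given mean and coefficient of variation
.rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# grows one axis polyline of target length from a start point; direction
# meanders and is deflected at the column wall and bottom
.grow_axis <- function(start, dir0, length_target, cfg, meander, gravitropism) {
  ds <- cfg$step_length
  n_steps <- max(1, ceiling(length_target / ds - 1e-9))
  pts <- matrix(NA_real_, n_steps, 3)
  pos <- start
  dir <- dir0 / sqrt(sum(dir0^2))
  R <- cfg$column_radius
  H <- cfg$column_height
  for (k in seq_len(n_steps)) {
    step_len <- if (k == n_steps) length_target - (n_steps - 1) * ds else ds
    dir <- dir + meander * rnorm(3) + c(0, 0, -gravitropism)
    dir <- dir / sqrt(sum(dir^2))
    cand <- pos + step_len * dir
    # wall deflection: drop the outward radial component
    r2 <- cand[1]^2 + cand[2]^2
    if (r2 > (R - 1e-6)^2) {
      rad <- pos[1:2] / max(sqrt(sum(pos[1:2]^2)), 1e-9)
      out_comp <- sum(dir[1:2] * rad)
      if (out_comp > 0) {
        dir[1:2] <- dir[1:2] - out_comp * rad
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-6) dir <- c(-rad * 0.1, -1) # slide down the wall
        dir <- dir / sqrt(sum(dir^2))
      }
      cand <- pos + step_len * dir
      r2 <- cand[1]^2 + cand[2]^2
      if (r2 > R^2) { # clamp radially as a last resort
        sc <- (R - 1e-6) / sqrt(r2)
        cand[1:2] <- cand[1:2] * sc
      }
    }
    if (cand[3] < -H + 1e-6) { # bottom deflection: grow horizontally
      dir[3] <- abs(dir[3]) * 0.1
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + step_len * dir
      cand[3] <- max(cand[3], -H + 1e-6)
    }
    cand[3] <- min(cand[3], -1e-6)
    pts[k, ] <- cand
    pos <- cand
  }
  pts
}

# random initial direction at a given mean angle below the horizontal (deg)
.lateral_direction <- function(angle_mean) {
  az <- runif(1, 0, 2 * pi)
  ang <- (angle_mean + rnorm(1, 0, 12)) * pi / 180
  c(cos(az) * cos(ang), sin(az) * cos(ang), -sin(ang))
}

#' Generate a synthetic lupin-like root architecture time series
#'
#' Grows a taproot from the collar at sowing, inserts order-2 laterals along
#' it as a depth-biased Poisson process, and order-3 laterals along those,
#' with acropetal stochastic emergence delays. All axes elongate at
#' per-axis lognormal rates for a fixed per-order duration and are deflected
#' at the column wall and bottom. Returns daily snapshots.
#'
#' @param cfg an `rsa_gen_config`.
#' @param snapshot_times observation times (DAS); default daily 18-25.
#' @return List of `root_system` snapshots (one per requested time).
#' @export
generate_rsa_series <- function(cfg = rsa_gen_config(),
                                snapshot_times = 18:25) {
  full <- generate_rsa(cfg)
  lapply(snapshot_times, function(t) truncate_system(full, t))
}

#' @rdname generate_rsa_series
#' @return `generate_rsa` returns the fully grown `root_system` at
#'   `cfg$sowing_to_end` DAS.
#' @export
generate_rsa <- function(cfg = rsa_gen_config()) {
  if (cfg$column_height < cfg$step_length * 2) {
    abort("column too small to host the taproot")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  t_end <- cfg$sowing_to_end
  axes <- list()     # per axis: pts, node_times, order, parent_axis, parent_node
  # ---- taproot -------------------------------------------------------------
  rate1 <- .rlnorm_mean_cv(1, cfg$elongation_by_order[1], cfg$cv)
  len1 <- min(rate1 * cfg$growth_duration_by_order[1],
              rate1 * t_end, cfg$column_height * 0.95)
  pts1 <- .grow_axis(c(0, 0, 0), c(0, 0, -1), len1, cfg,
                     meander = 0.04, gravitropism = 0.5)
  cum1 <- cumsum(sqrt(rowSums((pts1 - rbind(c(0, 0, 0),
                                            pts1[-nrow(pts1), , drop = FALSE]))^2)))
  axes[[1]] <- list(pts = pts1, node_times = cum1 / rate1, order = 1L,
                    parent_axis = 0L, parent_node = 0L, emergence = 0)

  # ---- order-2 laterals: depth-biased Poisson process along the taproot ----
  place_laterals <- function(parent_id, order, density, depth_biased) {
    par <- axes[[parent_id]]
    npts <- nrow(par$pts)
    if (npts < 1) return(invisible(NULL))
    seg_len <- sqrt(rowSums((par$pts - rbind(
      if (par$parent_axis == 0L) c(0, 0, 0) else par$start,
      par$pts[-npts, , drop = FALSE]))^2))
    total_len <- sum(seg_len)
    w <- if (depth_biased) {
      exp(pmin(par$pts[, 3], 0) / cfg$branching_depth_scale) * seg_len *
        total_len / sum(exp(pmin(par$pts[, 3], 0) / cfg$branching_depth_scale) *
                          seg_len)
    } else seg_len
    # the configured density is the density realized at the growth horizon:
    # primordia whose stochastic emergence delay pushes them past the horizon
    # are thinned out, so the placement intensity is inflated by the inverse
    # emergence probability, targeting `density` emerged laterals per cm of
    # parent length realized at the horizon
    tau <- max(cfg$emergence_delay_mean[order], 1e-9)
    p_emerge <- 1 - exp(-pmax(t_end - par$node_times - cfg$emergence_lag, 0) / tau)
    realized_len <- sum(seg_len[par$node_times <= t_end])
    eligible <- p_emerge > 0.02
    if (!any(eligible)) return(invisible(NULL))
    lambda <- numeric(npts)
    lambda[eligible] <- w[eligible] / p_emerge[eligible]
    lambda <- lambda * density * realized_len /
      max(sum(w[eligible]), 1e-12)
    n_lat <- rpois(1, sum(lambda))
    if (n_lat == 0) return(invisible(NULL))
    nodes <- sample.int(npts, n_lat, replace = TRUE, prob = lambda)
    for (nd in nodes) {
      t_node <- par$node_times[nd]
      emergence <- t_node + cfg$emergence_lag +
        rexp(1, 1 / max(cfg$emergence_delay_mean[order], 1e-9))
      if (emergence >= t_end) next
      rate <- .rlnorm_mean_cv(1, cfg$elongation_by_order[order], cfg$cv)
      len <- rate * cfg$growth_duration_by_order[order]
      dir0 <- .lateral_direction(
        if (order == 2L) cfg$insertion_angle_order2 else cfg$insertion_angle_order3)
      start <- par$pts[nd, ]
      pts <- .grow_axis(start, dir0, len, cfg,
                        meander = if (order == 2L) 0.25 else 0.4,
                        gravitropism = 0.03)
      cuml <- cumsum(sqrt(rowSums((pts - rbind(start,
                                               pts[-nrow(pts), , drop = FALSE]))^2)))
      axes[[length(axes) + 1]] <<- list(
        pts = pts, node_times = emergence + cuml / rate, order = order,
        parent_axis = parent_id, parent_node = nd, emergence = emergence,
        start = start)
    }
    invisible(NULL)
  }
  place_laterals(1L, 2L, cfg$density_2_on_1, depth_biased = TRUE)
  n_axes_now <- length(axes)
  if (n_axes_now >= 2) {
    for (a in 2:n_axes_now) place_laterals(a, 3L, cfg$density_3_on_2,
                                           depth_biased = FALSE)
  }

  # ---- assemble the segment table -----------------------------------------
  diam_axis <- vapply(axes, function(a) {
    .rlnorm_mean_cv(1, cfg$mean_diameter_by_order[a$order], cfg$cv)
  }, numeric(1))
  rows <- vector("list", length(axes))
  id0 <- 0L
  first_seg_id <- integer(length(axes))
  for (a in seq_along(axes)) {
    ax <- axes[[a]]
    nseg <- nrow(ax$pts)
    ids <- id0 + seq_len(nseg)
    id0 <- id0 + nseg
    first_seg_id[a] <- ids[1]
    rows[[a]] <- tibble(
      id = ids,
      parent_id = c(NA_integer_, ids[-nseg]),   # axis-internal; head fixed below
      axis_id = a,
      x = ax$pts[, 1], y = ax$pts[, 2], z = ax$pts[, 3],
      radius = diam_axis[a] / 2,
      order = ax$order,
      birth = unname(c(ax$emergence, ax$node_times[-nseg])),
      origination = unname(ax$node_times)
    )
  }
  seg <- bind_rows(rows)
  # attach each axis head to its parent node's segment
  for (a in seq_along(axes)) {
    ax <- axes[[a]]
    head_row <- first_seg_id[a]
    seg$parent_id[seg$id == head_row] <- if (ax$parent_axis == 0L) 0L else {
      first_seg_id[ax$parent_axis] + ax$parent_node - 1L
    }
  }
  # drop sub-resolution fragments that can appear from wall clamping
  geom_len <- {
    rs_tmp <- root_system(seg, timestamp = t_end)
    segment_geometry(rs_tmp)$length
  }
  keep <- geom_len > 1e-4
  idx <- match(seg$parent_id, seg$id)
  repeat {
    dangling <- keep & seg$parent_id != 0L & !keep[idx]
    dangling[is.na(dangling)] <- FALSE
    if (!any(dangling)) break
    keep <- keep & !dangling
  }
  seg <- seg[keep, , drop = FALSE]
  # axes were laid out to their final capped length; cut back to the horizon
  rs <- root_system(seg, collar = c(0, 0, 0),
                    timestamp = max(seg$origination, t_end))
  rs <- truncate_system(rs, t_end)
  validate_root_system(rs, bounds = list(radius = cfg$column_radius,
                                         height = cfg$column_height))
  rs
}
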