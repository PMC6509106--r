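#' Root-system segment networks
#'
#' A root system is stored as a tibble of segments with one row per segment.
#' Each segment is the straight edge from its parent's distal node (or the
#' collar) to its own distal node. Columns:
#'
#' * `id`, `parent_id`: integer segment ids; `parent_id == 0` means the
#'   segment is attached to the collar.
#' * `axis_id`: integer id of the root axis the segment belongs to; segments
#'   of one axis are ordered base to tip.
#' * `x`, `y`, `z`: distal node position (cm). The origin is at the centre of
#'   the column top and `z` is positive upwards, so soil positions have
#'   `z <= 0`.
#' * `radius`: segment radius (cm).
#' * `order`: branching order, 1 (taproot) to 3.
#' * `birth`, `origination`: time (days after sowing, DAS) at which the
#'   proximal and distal node of the segment were created. The tip segment of
#'   a growing axis is the only segment whose geometry changes over time.
#'
#' @param segments data frame with the columns above (`birth` optional: when
#'   missing it is reconstructed as the previous segment's `origination`
#'   within each axis).
#' @param collar numeric length-3 collar position (cm).
#' @param timestamp observation time (DAS).
#' @return A `root_system`: a tibble of segments with attributes `collar` and
#'   `timestamp`.
#' @export
root_system <- function(segments, collar = c(0, 0, 0), timestamp) {
  seg <- as_tibble(segments)
  required <- c("id", "parent_id", "axis_id", "x", "y", "z", "radius",
                "order", "origination")
  missing_cols <- setdiff(required, names(seg))
  if (length(missing_cols) > 0) {
    abort(paste0("missing segment columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"birth" %in% names(seg)) {
    seg <- seg %>%
      group_by(.data$axis_id) %>%
      mutate(birth = dplyr::lag(.data$origination,
                                default = dplyr::first(.data$origination))) %>%
      ungroup()
  }
  seg <- seg[, c("id", "parent_id", "axis_id", "x", "y", "z", "radius",
                 "order", "birth", "origination")]
  structure(seg,
            class = c("root_system", class(tibble())),
            collar = as.numeric(collar),
            timestamp = as.numeric(timestamp))
}

#' @export
#' @rdname root_system
is_root_system <- function(x) inherits(x, "root_system")

#' @export
#' @rdname root_system
#' @param x,rs a `root_system`.
collar_position <- function(rs) attr(rs, "collar")

#' @export
#' @rdname root_system
system_time <- function(rs) attr(rs, "timestamp")

# keep attributes through dplyr-style subsetting used internally
reclass_rs <- function(seg, template) {
  structure(as_tibble(seg),
            class = class(template),
            collar = attr(template, "collar"),
            timestamp = attr(template, "timestamp"))
}

#' Segment endpoint table
#'
#' Joins each segment to its proximal node (the parent's distal node, or the
#' collar) and computes segment lengths and midpoints.
#'
#' @param rs a `root_system`.
#' @return Tibble with the segment columns plus `x0`, `y0`, `z0` (proximal
#'   node), `length` (cm) and `xm`, `ym`, `zm` (midpoint).
#' @export
segment_geometry <- function(rs) {
  collar <- collar_position(rs)
  parents <- tibble(parent_id = rs$id, x0 = rs$x, y0 = rs$y, z0 = rs$z)
  out <- as_tibble(rs) %>%
    left_join(parents, by = "parent_id") %>%
    mutate(
      x0 = if_else(.data$parent_id == 0L, collar[1], .data$x0),
      y0 = if_else(.data$parent_id == 0L, collar[2], .data$y0),
      z0 = if_else(.data$parent_id == 0L, collar[3], .data$z0),
      length = sqrt((.data$x - .data$x0)^2 + (.data$y - .data$y0)^2 +
                      (.data$z - .data$z0)^2),
      xm = (.data$x + .data$x0) / 2,
      ym = (.data$y + .data$y0) / 2,
      zm = (.data$z + .data$z0) / 2
    )
  out
}

#' Validate a root system
#'
#' Checks the structural invariants: positive radii and lengths, orders in
#' 1..3 non-decreasing from parent to child, origination times non-decreasing
#' from parent to child, and a single acyclic component rooted at the collar.
#'
#' @param rs a `root_system`.
#' @param bounds optional list with `radius` and `height` (cm) of the soil
#'   column; when given, all nodes must lie inside the column.
#' @return `rs`, invisibly. Errors on violation.
#' @export
validate_root_system <- function(rs, bounds = NULL) {
  if (nrow(rs) == 0) abort("empty root system")
  if (anyDuplicated(rs$id)) abort("duplicate segment ids")
  if (any(rs$radius <= 0)) abort("non-positive segment radius")
  if (!all(rs$order %in% 1:3)) abort("root order outside 1..3")
  geom <- segment_geometry(rs)
  if (any(geom$length <= 0)) abort("zero-length segment")
  idx <- match(rs$parent_id, rs$id)
  bad_parent <- rs$parent_id != 0L & is.na(idx)
  if (any(bad_parent)) abort("segment with unknown parent id")
  has_parent <- rs$parent_id != 0L
  if (any(rs$order[has_parent] < rs$order[idx[has_parent]])) {
    abort("child order below parent order")
  }
  if (any(rs$origination < rs$birth - 1e-9)) {
    abort("segment distal node created before its proximal node")
  }
  if (any(rs$birth[has_parent] < rs$origination[idx[has_parent]] - 1e-9)) {
    abort("child older than its parent")
  }
  # connectivity / acyclicity: grow the reachable set from the collar
  known <- rs$parent_id == 0L
  if (!any(known)) abort("no segment attached to the collar")
  repeat {
    newly <- !known & known[idx]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    known <- known | newly
  }
  if (!all(known)) abort("cycle or disconnected component in root network")
  if (!is.null(bounds)) {
    r2 <- rs$x^2 + rs$y^2
    if (any(r2 > (bounds$radius + 1e-9)^2) ||
        any(rs$z > 1e-9) || any(rs$z < -bounds$height - 1e-9)) {
      abort("segment outside the soil column")
    }
  }
  invisible(rs)
}

#' Truncate a root system to an earlier time
#'
#' Reconstructs the architecture at time `t` from a later snapshot: segments
#' whose distal node already existed at `t` are kept unchanged, the tip
#' segment of each axis still growing at `t` is shortened proportionally to
#' the elapsed fraction of its growth interval, and younger segments are
#' dropped. Interior segments are all-or-nothing; only tips shrink.
#'
#' @param rs a `root_system` with timestamp `>= t`.
#' @param t target time (DAS).
#' @return A `root_system` at time `t`.
#' @export
truncate_system <- function(rs, t) {
  if (t > system_time(rs) + 1e-9) {
    abort("cannot truncate forwards in time")
  }
  geom <- segment_geometry(rs)
  full <- geom$origination <= t + 1e-12
  partial <- !full & geom$birth < t - 1e-12
  frac <- pmin(1, (t - geom$birth) / pmax(geom$origination - geom$birth, 1e-12))
  seg <- as_tibble(rs)
  seg$x[partial] <- geom$x0[partial] + frac[partial] * (geom$x[partial] - geom$x0[partial])
  seg$y[partial] <- geom$y0[partial] + frac[partial] * (geom$y[partial] - geom$y0[partial])
  seg$z[partial] <- geom$z0[partial] + frac[partial] * (geom$z[partial] - geom$z0[partial])
  seg$origination[partial] <- t
  keep <- full | partial
  # a kept segment must not dangle from a dropped parent
  idx <- match(seg$parent_id, seg$id)
  repeat {
    dangling <- keep & seg$parent_id != 0L & !keep[idx]
    dangling[is.na(dangling)] <- FALSE
    if (!any(dangling)) break
    keep <- keep & !dangling
  }
  out <- root_system(seg[keep, , drop = FALSE],
                     collar = collar_position(rs), timestamp = t)
  out
}

#' Interpolate a root architecture between snapshots
#'
#' Given time-ordered snapshots of one growing root system, returns the
#' architecture at an intermediate time. Segment origination times carried by
#' the snapshots define linear growth along each axis, so the architecture at
#' `t` is obtained by truncating the first snapshot taken at or after `t`
#' (growth is piecewise linear per axis; tip segments shrink, interior
#' segments are included by origination time).
#'
#' @param snapshots list of `root_system` objects sorted by timestamp.
#' @param t target time (DAS) within the snapshot range.
#' @return A `root_system` at time `t`.
#' @export
interpolate_architecture <- function(snapshots, t) {
  times <- vapply(snapshots, system_time, numeric(1))
  if (is.unsorted(times)) abort("snapshots must be sorted by timestamp")
  if (t < times[1] - 1e-9 || t > times[length(times)] + 1e-9) {
    abort("t outside the snapshot range: refusing to extrapolate")
  }
  k <- which(times >= t - 1e-9)[1]
  later <- snapshots[[k]]
  if (k > 1) {
    earlier <- snapshots[[k - 1]]
    if (!all(earlier$id %in% later$id)) {
      abort("inconsistent topology between snapshots: segments disappear")
    }
  }
  if (abs(times[k] - t) <= 1e-9) return(later)
  truncate_system(later, t)
}

#' Classify segments into taproot / young lateral / old lateral
#'
#' Order-1 segments are class `"T"` regardless of age; lateral segments
#' younger than `age_threshold` days are `"Ly"`, older ones `"Lo"`. Segment
#' age at time `t` is `t - origination`.
#'
#' @param rs a `root_system`.
#' @param t evaluation time (DAS); defaults to the system timestamp.
#' @param age_threshold age separating young from old laterals (days).
#' @return `rs` with an added character column `class`.
#' @export
classify_segments <- function(rs, t = system_time(rs), age_threshold = 5) {
  if (any(rs$origination > t + 1e-9)) {
    abort("segment originates after the evaluation time")
  }
  age <- t - rs$origination
  cls <- if_else(rs$order == 1L, "T", if_else(age < age_threshold, "Ly", "Lo"))
  out <- as_tibble(rs)
  out$class <- cls
  reclass_rs(out, rs)
}

#' Architecture statistics
#'
#' Computes the summary statistics used to characterise a root system: total
#' length, per-order lengths and shares, mean diameters, mean root (axis)
#' lengths, branching densities, mean per-axis elongation rates, the fraction
#' of length in the top 3 cm of soil, and total root surface area
#' (`sum(2 * pi * radius * length)`).
#'
#' @param rs a `root_system`.
#' @param top_depth depth (cm) of the surface layer for the depth fraction.
#' @return An object of class `architecture_stats` (a named list).
#' @export
architecture_stats <- function(rs, top_depth = 3) {
  if (nrow(rs) == 0) abort("empty root system")
  geom <- segment_geometry(rs)
  t_obs <- system_time(rs)
  orders <- sort(unique(geom$order))
  by_order <- geom %>%
    group_by(.data$order) %>%
    summarise(length_cm = sum(.data$length),
              mean_diameter = sum(2 * .data$radius * .data$length) /
                sum(.data$length),
              .groups = "drop")
  total_cm <- sum(by_order$length_cm)
  axes <- geom %>%
    group_by(.data$axis_id) %>%
    summarise(order = dplyr::first(.data$order),
              axis_length = sum(.data$length),
              emergence = min(.data$birth),
              .groups = "drop")
  axis_by_order <- axes %>%
    group_by(.data$order) %>%
    summarise(mean_axis_length = mean(.data$axis_length),
              n_axes = dplyr::n(),
              mean_elongation = mean(.data$axis_length /
                                       pmax(t_obs - .data$emergence, 1e-9)),
              .groups = "drop")
  len_of <- function(o) {
    v <- by_order$length_cm[match(o, by_order$order)]
    if_else(is.na(v), 0, v)
  }
  n_axes_of <- function(o) {
    v <- axis_by_order$n_axes[match(o, axis_by_order$order)]
    if_else(is.na(v), 0L, as.integer(v))
  }
  # depth fraction: apportion each segment linearly across the z interval it
  # spans (exact for straight segments)
  zlo <- pmin(geom$z0, geom$z)
  zhi <- pmax(geom$z0, geom$z)
  overlap <- pmax(0, pmin(zhi, 0) - pmax(zlo, -top_depth))
  span <- pmax(zhi - zlo, 1e-12)
  in_top <- sum(geom$length * overlap / span)
  structure(list(
    total_length = total_cm / 100,
    length_by_order = setNames(len_of(orders) / 100, orders),
    length_share_by_order = setNames(len_of(orders) / total_cm, orders),
    mean_diameter_by_order = setNames(
      by_order$mean_diameter[match(orders, by_order$order)], orders),
    mean_root_length_by_order = setNames(
      axis_by_order$mean_axis_length[match(orders, axis_by_order$order)], orders),
    mean_elongation_by_order = setNames(
      axis_by_order$mean_elongation[match(orders, axis_by_order$order)], orders),
    branching_density_2_on_1 =
      if (len_of(1) > 0) n_axes_of(2L) / len_of(1) else NA_real_,
    branching_density_3_on_2 =
      if (len_of(2) > 0) n_axes_of(3L) / len_of(2) else NA_real_,
    depth_fraction_top3cm = in_top / total_cm,
    total_surface_area = sum(2 * pi * geom$radius * geom$length),
    n_segments = nrow(rs),
    timestamp = t_obs
  ), class = "architecture_stats")
}

#' @export
print.architecture_stats <- function(x, ...) {
  cat("Root architecture at", x$timestamp, "DAS:",
      sprintf("%.2f m total length, %d segments\n",
              x$total_length, x$n_segments))
  cat("  length share by order:",
      paste(sprintf("%s: %.1f%%", names(x$length_share_by_order),
                    100 * x$length_share_by_order), collapse = ", "), "\n")
  cat(sprintf("  mean diameters (cm): %s\n",
              paste(sprintf("%.3f", x$mean_diameter_by_order), collapse = ", ")))
  cat(sprintf("  branching: %.1f order-2 per cm taproot, %.1f order-3 per cm order-2\n",
              x$branching_density_2_on_1, x$branching_density_3_on_2))
  cat(sprintf("  %.0f%% of length in the top 3 cm; surface area %.1f cm^2\n",
              100 * x$depth_fraction_top3cm, x$total_surface_area))
  invisible(x)
}

#' @export
#' @method tidy architecture_stats
tidy.architecture_stats <- function(x, ...) {
  tibble(
    order = as.integer(names(x$length_by_order)),
    length_m = unname(x$length_by_order),
    length_share = unname(x$length_share_by_order),
    mean_diameter_cm = unname(x$mean_diameter_by_order),
    mean_root_length_cm = unname(x$mean_root_length_by_order),
    mean_elongation_cm_d = unname(x$mean_elongation_by_order)
  )
}

#' Read/write a root system as a flat CSV node table
#'
#' Columns: `id, parent_id, axis_id, x, y, z, radius_cm, order, birth_das,
#' origination_das`, with the collar position and timestamp stored in header
#' comment lines.
#'
#' @param rs a `root_system`.
#' @param path file path.
#' @return `read_segment_table` returns a `root_system`;
#'   `write_segment_table` returns `path` invisibly.
#' @export
write_segment_table <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# collar_cm: %.9g %.9g %.9g", collar_position(rs)[1],
            collar_position(rs)[2], collar_position(rs)[3]),
    sprintf("# timestamp_das: %.9g", system_time(rs))
  ), con)
  tab <- as_tibble(rs) %>%
    rename(radius_cm = "radius", birth_das = "birth",
           origination_das = "origination")
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname write_segment_table
read_segment_table <- function(path) {
  hdr <- readLines(path, n = 2)
  collar <- as.numeric(strsplit(sub("# collar_cm: ", "", hdr[1]), " ")[[1]])
  ts <- as.numeric(sub("# timestamp_das: ", "", hdr[2]))
  tab <- read.csv(path, comment.char = "#")
  seg <- as_tibble(tab) %>%
    rename(radius = "radius_cm", birth = "birth_das",
           origination = "origination_das")
  rs <- root_system(seg, collar = collar, timestamp = ts)
  validate_root_system(rs)
  rs
}
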