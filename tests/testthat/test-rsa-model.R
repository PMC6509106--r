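test_that("root systems are validated against their structural invariants", {
  rs <- toy_system()
  expect_silent(validate_root_system(rs))
  expect_equal(nrow(rs), 4)

  bad_radius <- tibble::as_tibble(rs)
  bad_radius$radius[2] <- 0
  expect_error(validate_root_system(root_system(bad_radius, timestamp = 10)),
               "radius")

  # cycle between the two lateral segments: unreachable from the collar
  cyc <- tibble::as_tibble(rs)
  cyc$parent_id <- c(0L, 1L, 4L, 3L)
  cyc$birth <- 5; cyc$origination <- 5
  expect_error(validate_root_system(root_system(cyc, timestamp = 10)),
               "collar|cycle")

  ord <- tibble::as_tibble(rs)
  ord$order[3] <- 0L
  expect_error(validate_root_system(root_system(ord, timestamp = 10)),
               "order")

  out_of_bounds <- root_system(tibble::as_tibble(rs), timestamp = 10)
  expect_error(validate_root_system(out_of_bounds,
                                    bounds = list(radius = 0.5, height = 10)),
               "outside")
})

test_that("architecture interpolation is the identity at snapshot knots and linear between them", {
  rs <- toy_system()
  snaps <- lapply(c(3, 6, 10), function(t) truncate_system(rs, t))

  # identity at a knot
  expect_equal(interpolate_architecture(snaps, 6), snaps[[2]])

  # one axis growing 2 cm -> 4 cm: midpoint has 3 cm
  seg <- tibble::tibble(id = 1:2, parent_id = c(0L, 1L), axis_id = 1L,
                        x = 0, y = 0, z = c(-2, -4), radius = 0.05,
                        order = 1L, birth = c(0, 1), origination = c(1, 2))
  ax <- root_system(seg, timestamp = 2)
  two_snaps <- list(truncate_system(ax, 1), ax)
  mid <- interpolate_architecture(two_snaps, 1.5)
  expect_equal(sum(segment_geometry(mid)$length), 3)

  # outside the snapshot range refuses to extrapolate
  expect_error(interpolate_architecture(snaps, 2), "extrapolate")
  expect_error(interpolate_architecture(snaps, 11), "extrapolate")
})

test_that("total root length is monotone non-decreasing along interpolation time", {
  rs <- random_tree(7, n = 30)
  snaps <- lapply(c(1, 2.5, 4), function(t) truncate_system(rs, t))
  ts <- seq(1, 4, length.out = 100)
  lens <- vapply(ts, function(t) {
    sum(segment_geometry(interpolate_architecture(snaps, t))$length)
  }, numeric(1))
  expect_true(all(diff(lens) > -1e-9))
})

test_that("segment classification follows order and the 5-day age threshold", {
  rs <- toy_system(timestamp = 10)
  cls <- classify_segments(rs, t = 10)
  # taproot segments are T regardless of age
  expect_equal(cls$class[cls$order == 1L], c("T", "T"))
  # laterals aged 6 and 4 days straddle the threshold
  expect_equal(cls$class[cls$id == 3], "Lo")
  expect_equal(cls$class[cls$id == 4], "Ly")
  # exactly at the threshold counts as old
  cls2 <- classify_segments(rs, t = 9)
  expect_equal(cls2$class[cls2$id == 3], "Lo")
  # evaluation before a segment exists errors
  expect_error(classify_segments(rs, t = 3), "originates after")
})

test_that("architecture statistics match hand arithmetic on simple fixtures", {
  one <- one_segment(length = 1, radius = 0.1)
  st <- architecture_stats(one)
  expect_equal(st$total_length, 0.01)
  expect_equal(st$total_surface_area, 2 * pi * 0.1, tolerance = 1e-12)

  # the printed-mean fixture: one 7.7 cm taproot, 37 order-2 roots of
  # 2.4 cm, 293 order-3 roots of 0.8 cm -> 3.31 m, order-3 share 0.708
  tap <- tibble::tibble(id = 1L, parent_id = 0L, axis_id = 1L, x = 0, y = 0,
                        z = -7.7, radius = 0.055, order = 1L, birth = 0,
                        origination = 1)
  # order-2 roots of length 2.4 cm off the taproot tip node, order-3 roots
  # of 0.8 cm off the first order-2 segment
  l2 <- tibble::tibble(id = 1L + seq_len(37), parent_id = 1L,
                       axis_id = 1L + seq_len(37), x = 2.4, y = 0, z = -7.7,
                       radius = 0.03, order = 2L, birth = 1, origination = 2)
  l3 <- tibble::tibble(id = 38L + seq_len(293), parent_id = 2L,
                       axis_id = 38L + seq_len(293), x = 3.2, y = 0,
                       z = -7.7, radius = 0.0225, order = 3L, birth = 2,
                       origination = 3)
  fx <- root_system(dplyr::bind_rows(tap, l2, l3), timestamp = 25)
  stf <- architecture_stats(fx)
  expect_equal(stf$total_length, (7.7 + 37 * 2.4 + 293 * 0.8) / 100)
  expect_equal(stf$total_length, 3.31, tolerance = 0.01)
  expect_equal(unname(stf$length_share_by_order["3"]), 0.708, tolerance = 0.01)
  expect_equal(unname(stf$mean_root_length_by_order), c(7.7, 2.4, 0.8))
  expect_equal(stf$branching_density_2_on_1, 37 / 7.7, tolerance = 1e-12)

  expect_error(architecture_stats(fx[0, ]), "empty")
})

test_that("statistics are invariant under re-indexing and segment splitting", {
  rs <- random_tree(3, n = 20)
  st <- architecture_stats(rs)

  # shares sum to 1 over random fixtures
  for (s in 1:10) {
    expect_equal(sum(architecture_stats(random_tree(s))$length_share_by_order),
                 1, tolerance = 1e-9)
  }

  # re-indexing: permute ids
  set.seed(1)
  perm <- sample(1000:2000, nrow(rs))
  re <- tibble::as_tibble(rs)
  re$id <- perm[match(re$id, rs$id)]
  re$parent_id <- ifelse(re$parent_id == 0L, 0L,
                         perm[match(re$parent_id, rs$id)])
  st2 <- architecture_stats(root_system(re, timestamp = 30))
  expect_equal(st2$total_length, st$total_length, tolerance = 1e-9)
  expect_equal(st2$total_surface_area, st$total_surface_area, tolerance = 1e-9)

  # split the first segment into two collinear halves
  geom <- segment_geometry(rs)
  i <- 1
  sp <- tibble::as_tibble(rs)
  mid_row <- sp[i, ]
  mid_row$id <- 9999L
  mid_row$x <- geom$xm[i]; mid_row$y <- geom$ym[i]; mid_row$z <- geom$zm[i]
  mid_row$origination <- (geom$birth[i] + geom$origination[i]) / 2
  sp$parent_id[i] <- 9999L
  sp$birth[i] <- mid_row$origination
  st3 <- architecture_stats(root_system(dplyr::bind_rows(mid_row, sp),
                                        timestamp = 30))
  expect_equal(st3$total_length, st$total_length, tolerance = 1e-9)
  expect_equal(st3$total_surface_area, st$total_surface_area, tolerance = 1e-9)
  expect_equal(st3$length_share_by_order, st$length_share_by_order,
               tolerance = 1e-9)
})

test_that("the flat CSV node table round-trips a root system", {
  rs <- toy_system()
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(rs, path)
  back <- read_segment_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(rs))
  expect_equal(system_time(back), system_time(rs))
  expect_equal(collar_position(back), collar_position(rs))
})
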