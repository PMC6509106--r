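#' RSML input and output
#'
#' Writes and reads Root System Markup Language (RSML 1.0) files. Each root
#' axis becomes a `<root>` element whose polyline starts at the attachment
#' node on the parent axis (or the collar) and continues through the distal
#' nodes of its segments. Per-node diameter and node creation time (DAS) are
#' stored as RSML point-domain functions, so a write/read round trip
#' reproduces topology, geometry, radii and origination times.
#'
#' @param rs a `root_system`.
#' @param path file path.
#' @param digits number of significant digits written for coordinates.
#' @return `read_rsml` returns a `root_system`; `write_rsml` returns `path`
#'   invisibly.
#' @export
write_rsml <- function(rs, path, digits = 10) {
  geom <- segment_geometry(rs)
  fmt <- function(v) sprintf("%.*g", digits, v)
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  prop <- xml2::xml_add_child(meta, "property-definitions")
  for (nm in c("node_creation_das", "diameter")) {
    pd <- xml2::xml_add_child(prop, "property-definition")
    xml2::xml_add_child(pd, "label", nm)
    xml2::xml_add_child(pd, "type", "float")
  }
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1", label = "plant")
  xml2::xml_attr(plant, "observation_das") <- fmt(system_time(rs))
  xml2::xml_attr(plant, "collar") <-
    paste(fmt(collar_position(rs)), collapse = " ")

  axes <- split(seq_len(nrow(geom)), geom$axis_id)
  # parent axis of each axis (0 = collar)
  axis_first <- vapply(axes, function(i) i[which.min(geom$origination[i])],
                       integer(1))
  axis_parent_axis <- vapply(axes, function(i) {
    first <- i[order(geom$origination[i])][1]
    pid <- geom$parent_id[first]
    if (pid == 0L) 0L else as.integer(geom$axis_id[match(pid, geom$id)])
  }, integer(1))
  axis_ids <- as.integer(names(axes))

  add_axis <- function(parent_node, aid) {
    i <- axes[[as.character(aid)]]
    i <- i[order(geom$origination[i], geom$id[i])]
    root <- xml2::xml_add_child(parent_node, "root",
                                id = as.character(aid),
                                label = paste0("axis_", aid))
    xml2::xml_attr(root, "order") <- as.character(geom$order[i[1]])
    g <- xml2::xml_add_child(root, "geometry")
    pl <- xml2::xml_add_child(g, "polyline")
    xml2::xml_add_child(pl, "point",
                        x = fmt(geom$x0[i[1]]), y = fmt(geom$y0[i[1]]),
                        z = fmt(geom$z0[i[1]]))
    for (k in i) {
      xml2::xml_add_child(pl, "point", x = fmt(geom$x[k]),
                          y = fmt(geom$y[k]), z = fmt(geom$z[k]))
    }
    fns <- xml2::xml_add_child(root, "functions")
    add_fn <- function(name, values) {
      fn <- xml2::xml_add_child(fns, "function", name = name, domain = "point")
      for (v in values) xml2::xml_add_child(fn, "sample", value = fmt(v))
    }
    add_fn("node_creation_das", c(geom$birth[i[1]], geom$origination[i]))
    add_fn("diameter", c(2 * geom$radius[i[1]], 2 * geom$radius[i]))
    for (child in axis_ids[axis_parent_axis == aid]) add_axis(root, child)
  }
  for (aid in axis_ids[axis_parent_axis == 0L]) add_axis(plant, aid)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @export
#' @rdname write_rsml
read_rsml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste("RSML parse error:",
                                                  conditionMessage(e))))
  plant <- xml2::xml_find_first(doc, ".//plant")
  if (inherits(plant, "xml_missing")) abort("RSML file has no <plant>")
  ts <- as.numeric(xml2::xml_attr(plant, "observation_das"))
  if (is.na(ts)) ts <- 0
  collar <- xml2::xml_attr(plant, "collar")
  collar <- if (is.na(collar)) c(0, 0, 0) else
    as.numeric(strsplit(trimws(collar), "\\s+")[[1]])

  rows <- list()
  next_id <- 0L
  read_axis <- function(root_node, parent_axis_rows) {
    aid <- suppressWarnings(as.integer(xml2::xml_attr(root_node, "id")))
    pts <- xml2::xml_find_all(root_node, "./geometry/polyline/point")
    if (length(pts) < 2) abort("RSML root with missing or degenerate geometry")
    px <- as.numeric(xml2::xml_attr(pts, "x"))
    py <- as.numeric(xml2::xml_attr(pts, "y"))
    pz <- as.numeric(xml2::xml_attr(pts, "z"))
    get_fn <- function(name, default) {
      fn <- xml2::xml_find_first(root_node, sprintf(
        "./functions/function[@name='%s']", name))
      if (inherits(fn, "xml_missing")) return(rep(default, length(pts)))
      as.numeric(xml2::xml_attr(xml2::xml_find_all(fn, "./sample"), "value"))
    }
    times <- get_fn("node_creation_das", 0)
    diam <- get_fn("diameter", 0.05)
    ord <- suppressWarnings(as.integer(xml2::xml_attr(root_node, "order")))
    if (is.na(ord)) {
      ord <- if (is.null(parent_axis_rows)) 1L else
        parent_axis_rows$order[1] + 1L
    }
    n_seg <- length(pts) - 1
    # attachment: nearest node of the parent axis to the first point
    if (is.null(parent_axis_rows)) {
      parent_first <- 0L
    } else {
      d2 <- (parent_axis_rows$x - px[1])^2 + (parent_axis_rows$y - py[1])^2 +
        (parent_axis_rows$z - pz[1])^2
      parent_first <- parent_axis_rows$id[which.min(d2)]
    }
    ids <- next_id + seq_len(n_seg)
    next_id <<- next_id + n_seg
    ax_rows <- tibble(
      id = ids,
      parent_id = c(parent_first, ids[-n_seg]),
      axis_id = if (is.na(aid)) ids[1] else aid,
      x = px[-1], y = py[-1], z = pz[-1],
      radius = diam[-1] / 2,
      order = ord,
      birth = times[-length(times)],
      origination = times[-1]
    )
    rows[[length(rows) + 1]] <<- ax_rows
    for (child in xml2::xml_find_all(root_node, "./root")) {
      read_axis(child, ax_rows)
    }
  }
  for (top in xml2::xml_find_all(plant, "./root")) read_axis(top, NULL)
  if (length(rows) == 0) abort("RSML file contains no roots")
  rs <- root_system(bind_rows(rows), collar = collar, timestamp = ts)
  validate_root_system(rs)
  rs
}

#' Write a series of daily snapshots as numbered RSML files
#'
#' @param series list of `root_system` snapshots.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_rsml_series <- function(series, dir, prefix = "rsa") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(series, function(rs) {
    p <- file.path(dir, sprintf("%s_%05.1f_das.rsml", prefix, system_time(rs)))
    write_rsml(rs, p)
    p
  }, character(1))
  invisible(paths)
}
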