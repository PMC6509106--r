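#' Plot a root system (vertical projection)
#'
#' @param rs a `root_system`.
#' @param plane `"xz"` or `"yz"` projection.
#' @return A ggplot.
#' @export
plot_root_system <- function(rs, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  geom <- segment_geometry(rs)
  hx <- if (plane == "xz") "x" else "y"
  hx0 <- paste0(hx, "0")
  ggplot2::ggplot(geom) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data[[hx0]], y = .data$z0,
      xend = .data[[hx]], yend = .data$z,
      colour = factor(.data$order),
      linewidth = .data$radius)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(hx, "(cm)"), y = "z (cm)", colour = "order",
                  title = sprintf("root system at %.1f DAS", system_time(rs))) +
    ggplot2::theme_minimal()
}

#' Depth profiles of archived state fields
#'
#' Horizontally averaged profiles of water content and tracer concentration
#' for every archived state of a forward run.
#'
#' @param object a `forward_run`.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot forward_run
autoplot.forward_run <- function(object, ...) {
  grid <- object$grid
  rows <- lapply(object$states, function(s) {
    prof <- function(f) vapply(seq_len(grid$nz), function(k) {
      mean(f[, , k][grid$mask2d], na.rm = TRUE)
    }, numeric(1))
    out <- tibble(depth = -grid$zc, t = s$t, theta = prof(s$theta))
    if (!is.null(s$conc)) out$conc = prof(s$conc)
    out
  })
  df <- bind_rows(rows) %>%
    tidyr::pivot_longer(-c("depth", "t"), names_to = "field")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$depth,
                                   colour = factor(round(.data$t, 2)))) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~field, scales = "free_x") +
    ggplot2::labs(y = "depth (cm)", colour = "DAS") +
    ggplot2::theme_minimal()
}

#' RMSE response surfaces of a sensitivity map
#'
#' @param object a `sensitivity_map`.
#' @param ... unused.
#' @return A ggplot of log-RMSE rasters per parameter pair.
#' @export
#' @method autoplot sensitivity_map
autoplot.sensitivity_map <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(pair = paste(.data$par1, "vs", .data$par2))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$f1), y = log2(.data$f2),
                                   fill = log10(.data$rmse))) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_fill_viridis_c(name = "log10 RMSE") +
    ggplot2::labs(x = "log2 factor (parameter 1)",
                  y = "log2 factor (parameter 2)") +
    ggplot2::theme_minimal()
}

#' Breakthrough-curve plot
#'
#' @param bt tibble from [breakthrough()].
#' @return A ggplot of effluent concentration against time.
#' @export
plot_breakthrough <- function(bt) {
  ggplot2::ggplot(bt %>% filter(!.data$undefined),
                  ggplot2::aes(x = .data$t_mid, y = .data$conc_mmol_l)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (DAS)", y = "effluent concentration (mmol/l)") +
    ggplot2::theme_minimal()
}

#' Cumulative uptake by root order
#'
#' @param run a `forward_run`.
#' @return A ggplot of cumulative uptake volume per order over time.
#' @export
plot_uptake_partition <- function(run) {
  ggplot2::ggplot(run$uptake_by_order,
                  ggplot2::aes(x = .data$t, y = .data$cum_uptake_cm3,
                               colour = factor(.data$order))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (DAS)", y = "cumulative uptake (cm3)",
                  colour = "root order") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
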