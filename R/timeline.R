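#' Transpiration demand envelope
#'
#' The daytime transpiration demand ramps linearly from half the peak at the
#' start of the tracer experiment (18 DAS) to the peak at its end (25 DAS) -
#' i.e. the transpiration rate doubles over the experiment - and is switched
#' on/off by the 12 h / 12 h day/night cycle.
#'
#' @param t time (DAS); vectorised.
#' @param peak peak daytime transpiration (cm3/d).
#' @param t0,t1 start and end of the ramp (DAS).
#' @return Envelope value (cm3/d) at `t`.
#' @export
transpiration_ramp <- function(t, peak = 60, t0 = 18, t1 = 25) {
  frac <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  peak * (0.5 + 0.5 * frac)
}

#' Generate the experiment boundary-flux timeline
#'
#' Emulates the 7-day tracer protocol: during the leaching phase (18-24
#' DAS) the column is irrigated continuously with tracer solution except
#' during the nightly ~6 h MRI scan windows, when irrigation and
#' transpiration are both zero; during the final non-leaching day (24-25
#' DAS) irrigation is stopped and plant transpiration is the only driver of
#' water movement. The plant transpires during the 12 h light period at the
#' linearly ramping demand (see [transpiration_ramp()]). While irrigation is
#' on, the bottom boundary is a seepage face (effluent drips from the
#' saturated bottom plate, keeping the fine sand column near saturation, as
#' observed); it is closed during scans and the redistribution day.
#'
#' Each day is split into light (`[d, d+0.5)`), scan (`[d+0.5, d+0.75)`) and
#' night (`[d+0.75, d+1)`) windows. Transpiration within an event ramps
#' linearly between `transpiration_start` and `transpiration_end`.
#'
#' @param scenario `"full_experiment"` (default) or `"non_leaching_only"`
#'   (a single interval, the redistribution day, with zero irrigation).
#' @param transpiration_peak peak daytime transpiration (cm3/d).
#' @param irrigation_flux irrigation rate while irrigating (cm3/d).
#' @param irrigation_concentration tracer concentration of the irrigation
#'   solution (mmol/l).
#' @param t_start,t_end simulated window (DAS); the non-leaching day is the
#'   final day `[t_end - 1, t_end]`.
#' @return A `boundary_timeline` tibble with columns `t_start`, `t_end`,
#'   `irrigation_flux` (cm3/d), `irrigation_concentration` (mmol/l),
#'   `transpiration_start`, `transpiration_end`, `transpiration_flux` (the
#'   interval mean, cm3/d), `bottom_condition`, `phase`.
#' @export
generate_timeline <- function(scenario = c("full_experiment",
                                           "non_leaching_only"),
                              transpiration_peak = 60,
                              irrigation_flux = 35,
                              irrigation_concentration = 1,
                              t_start = 18, t_end = 25) {
  scenario <- match.arg(scenario)
  if (transpiration_peak <= 0) abort("transpiration_peak must be > 0")
  ramp <- function(t) transpiration_ramp(t, transpiration_peak)
  if (scenario == "non_leaching_only") {
    t0 <- t_end - 1
    # single interval carrying the day's transpired volume (12 h of light
    # at the ramping demand) spread over the day
    mean_t <- (ramp(t0) + ramp(t0 + 0.5)) / 2 * 0.5
    tl <- tibble(
      t_start = t0, t_end = t_end,
      irrigation_flux = 0, irrigation_concentration = 0,
      transpiration_start = mean_t, transpiration_end = mean_t,
      bottom_condition = "no_flux", phase = "non_leaching"
    )
  } else {
    days <- seq(floor(t_start), t_end - 1)
    rows <- lapply(days, function(d) {
      leaching <- d < t_end - 1
      irr <- if (leaching) irrigation_flux else 0
      conc <- if (leaching) irrigation_concentration else 0
      tibble(
        t_start = d + c(0, 0.5, 0.75),
        t_end = d + c(0.5, 0.75, 1),
        irrigation_flux = c(irr, 0, irr),
        irrigation_concentration = c(conc, 0, conc),
        transpiration_start = c(ramp(d), 0, 0),
        transpiration_end = c(ramp(d + 0.5), 0, 0),
        bottom_condition = if (leaching) {
          c("seepage", "no_flux", "seepage")
        } else rep("no_flux", 3),
        phase = if (leaching) {
          c("leaching", "scan", "leaching")
        } else c("non_leaching", "scan", "non_leaching")
      )
    })
    tl <- bind_rows(rows) %>% filter(.data$t_end > t_start + 1e-12)
    tl$t_start <- pmax(tl$t_start, t_start)
  }
  tl$transpiration_flux <- (tl$transpiration_start + tl$transpiration_end) / 2
  if (any(tl$irrigation_flux < 0) || any(tl$transpiration_flux < 0)) {
    abort("negative boundary flux")
  }
  structure(tl, class = c("boundary_timeline", class(tl)))
}

#' Instantaneous boundary conditions at a time point
#'
#' @param timeline a `boundary_timeline`.
#' @param t time (DAS).
#' @return List with `irrigation_flux`, `irrigation_concentration`,
#'   `transpiration_flux` (linearly interpolated within the event),
#'   `bottom_condition`, `phase`.
#' @export
boundary_at <- function(timeline, t) {
  i <- which(timeline$t_start <= t + 1e-12 & t < timeline$t_end - 1e-12)
  if (length(i) == 0) {
    if (abs(t - max(timeline$t_end)) < 1e-9) i <- nrow(timeline) else {
      abort("t outside the timeline")
    }
  }
  i <- i[1]
  frac <- (t - timeline$t_start[i]) /
    (timeline$t_end[i] - timeline$t_start[i])
  frac <- min(max(frac, 0), 1)
  list(
    irrigation_flux = timeline$irrigation_flux[i],
    irrigation_concentration = timeline$irrigation_concentration[i],
    transpiration_flux = timeline$transpiration_start[i] +
      frac * (timeline$transpiration_end[i] - timeline$transpiration_start[i]),
    bottom_condition = timeline$bottom_condition[i],
    phase = timeline$phase[i]
  )
}

#' Scan-end archive times of a timeline
#'
#' States are archived at the end of each nightly MRI scan window (and at
#' the end of the simulated period).
#'
#' @param timeline a `boundary_timeline`.
#' @return Numeric vector of times (DAS).
#' @export
scan_times <- function(timeline) {
  s <- timeline$t_end[timeline$phase == "scan"]
  sort(unique(c(s, max(timeline$t_end))))
}

#' Write a timeline as CSV (with unit-annotated headers)
#' @param timeline a `boundary_timeline`.
#' @param path output file.
#' @export
write_timeline_csv <- function(timeline, path) {
  out <- as_tibble(timeline)
  names(out) <- c("t_start_das", "t_end_das", "irrigation_cm3_d",
                  "irrigation_mmol_l", "transpiration_start_cm3_d",
                  "transpiration_end_cm3_d", "bottom_condition", "phase",
                  "transpiration_mean_cm3_d")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
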