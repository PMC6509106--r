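#' RMSE between two observation maps
#'
#' Root mean square of the voxelwise differences over the jointly observed
#' merged voxels.
#'
#' @param observed,simulated `observation_map`s on identical coarse grids
#'   (the simulated field must already be averaged to the observation
#'   resolution).
#' @return RMSE (units of the maps, e.g. mmol/l).
#' @export
rmse_maps <- function(observed, simulated) {
  if (!identical(dim(observed$c), dim(simulated$c)) ||
      abs(observed$width - simulated$width) > 1e-9) {
    abort("observation maps live on different grids")
  }
  ok <- observed$mask & simulated$mask
  if (!any(ok)) abort("no jointly observed voxels")
  sqrt(mean((observed$c[ok] - simulated$c[ok])^2))
}

#' Build a scenario grid over root hydraulic parameters
#'
#' Radial conductivities are drawn from a geometric sequence in
#' `kr_range` (cm hPa^-1 d^-1) and axial conductances from one in
#' `Kx_range` (cm4 hPa^-1 d^-1). The Cartesian product over the six
#' parameters is filtered by the admissibility constraint
#' `kr_Lo <= kr_Ly`. Any parameter can be pinned with `fixed`, removing it
#' from the product.
#'
#' @param n_kr,n_Kx number of grid values per radial / axial axis (>= 2 for
#'   free axes).
#' @param kr_range,Kx_range value intervals.
#' @param fixed named list of pinned parameter values (e.g.
#'   `list(kr_T = 1e-4)`).
#' @param age_threshold age threshold carried into every scenario (d).
#' @return A `scenario_grid`: tibble with one row per admissible scenario
#'   (columns the six parameters and `scenario`), with attributes `kr_values`
#'   and `Kx_values`.
#' @export
build_scenarios <- function(n_kr = 4, n_Kx = 3,
                            kr_range = c(1e-5, 1e2),
                            Kx_range = c(1e-4, 1e2),
                            fixed = list(), age_threshold = 5) {
  geom_seq <- function(r, n) {
    v <- exp(seq(log(r[1]), log(r[2]), length.out = n))
    v[1] <- r[1]
    v[n] <- r[2]   # guard against round-off beyond the stated interval
    v
  }
  kr_vals <- geom_seq(kr_range, n_kr)
  kx_vals <- geom_seq(Kx_range, n_Kx)
  par_names <- c("kr_T", "kr_Ly", "kr_Lo", "Kx_T", "Kx_Ly", "Kx_Lo")
  axes <- lapply(par_names, function(p) {
    if (p %in% names(fixed)) fixed[[p]] else {
      if (startsWith(p, "kr")) kr_vals else kx_vals
    }
  })
  names(axes) <- par_names
  free <- par_names[!(par_names %in% names(fixed))]
  if (any(vapply(axes[free], length, integer(1)) < 2)) {
    abort("need >= 2 grid values per free axis")
  }
  grid <- do.call(tidyr::expand_grid, axes)
  grid <- grid %>% filter(.data$kr_Lo <= .data$kr_Ly * (1 + 1e-12))
  if (nrow(grid) == 0) abort("empty admissible scenario set")
  grid$scenario <- seq_len(nrow(grid))
  grid$age_threshold <- age_threshold
  structure(grid, class = c("scenario_grid", class(grid)),
            kr_values = kr_vals, Kx_values = kx_vals)
}

# one scenario row -> hydraulic_params
.row_to_params <- function(row) {
  hydraulic_params(kr_T = row$kr_T, kr_Ly = row$kr_Ly, kr_Lo = row$kr_Lo,
                   Kx_T = row$Kx_T, Kx_Ly = row$Kx_Ly, Kx_Lo = row$Kx_Lo,
                   age_threshold = row$age_threshold)
}

#' Grid-search inversion of root hydraulic properties
#'
#' Evaluates the forward model for every admissible scenario and scores it
#' against the observed tracer map with [rmse_maps()]. Results are
#' independent of evaluation order; ties are broken by the lowest scenario
#' index. A failing forward run flags the scenario (`NA` score) without
#' aborting the search.
#'
#' @param scenarios a `scenario_grid`.
#' @param runner function taking a `hydraulic_params` and returning an
#'   `observation_map` of the simulated tracer field at the observation
#'   time (deterministic given its internal seed).
#' @param observed the observed `observation_map`.
#' @return An `inversion_result`: list with `table` (scenarios + `rmse`),
#'   `best` (one-row tibble), `best_params`, `trace` (best-so-far RMSE per
#'   refinement stage), `converged`.
#' @export
grid_search <- function(scenarios, runner, observed) {
  tab <- as_tibble(scenarios)
  tab$rmse <- vapply(seq_len(nrow(tab)), function(i) {
    p <- .row_to_params(tab[i, ])
    sim <- tryCatch(runner(p), error = function(e) NULL)
    if (is.null(sim)) return(NA_real_)
    rmse_maps(observed, sim)
  }, numeric(1))
  if (all(is.na(tab$rmse))) abort("all forward runs failed")
  best_i <- which(tab$rmse == min(tab$rmse, na.rm = TRUE))[1]
  structure(list(
    table = tab,
    best = tab[best_i, ],
    best_params = .row_to_params(tab[best_i, ]),
    trace = tibble(stage = 0L, best_rmse = tab$rmse[best_i],
                   n_evaluated = sum(!is.na(tab$rmse))),
    converged = FALSE
  ), class = "inversion_result")
}

#' Local refinement around the incumbent optimum
#'
#' Repeatedly re-grids the free parameters on shrinking geometric intervals
#' around the incumbent (one former grid step wide, then halving in log
#' space) until the relative RMSE improvement drops below `tol`.
#'
#' @param result an `inversion_result` from [grid_search()].
#' @param runner,observed as in [grid_search()].
#' @param n_per_axis refinement grid values per free axis.
#' @param tol relative improvement threshold for convergence.
#' @param max_stages hard stage cap.
#' @return The updated `inversion_result` (trace extended, `converged` set).
#' @export
local_refine <- function(result, runner, observed, n_per_axis = 3,
                         tol = 1e-3, max_stages = 8) {
  tab <- result$table
  par_names <- c("kr_T", "kr_Ly", "kr_Lo", "Kx_T", "Kx_Ly", "Kx_Lo")
  free <- par_names[vapply(par_names, function(p)
    length(unique(tab[[p]])) > 1, logical(1))]
  best <- result$best
  best_rmse <- best$rmse
  trace <- result$trace
  # initial half-width: half a grid step of the original sequences, so the
  # first refinement stage samples new midpoints instead of re-evaluating
  # the original lattice
  widths <- vapply(par_names, function(p) {
    u <- sort(unique(tab[[p]]))
    if (length(u) > 1) mean(diff(log(u))) / 2 else 0
  }, numeric(1))
  width0 <- widths
  for (stage in seq_len(max_stages)) {
    axes <- lapply(par_names, function(p) {
      if (!(p %in% free)) return(best[[p]])
      exp(seq(log(best[[p]]) - widths[p], log(best[[p]]) + widths[p],
              length.out = n_per_axis))
    })
    names(axes) <- par_names
    cand <- do.call(tidyr::expand_grid, axes) %>%
      filter(.data$kr_Lo <= .data$kr_Ly * (1 + 1e-12))
    cand$age_threshold <- best$age_threshold
    cand$rmse <- vapply(seq_len(nrow(cand)), function(i) {
      sim <- tryCatch(runner(.row_to_params(cand[i, ])),
                      error = function(e) NULL)
      if (is.null(sim)) return(NA_real_)
      rmse_maps(observed, sim)
    }, numeric(1))
    i <- which(cand$rmse == min(cand$rmse, na.rm = TRUE))[1]
    improved <- (best_rmse - cand$rmse[i]) / max(best_rmse, 1e-300)
    if (!is.na(improved) && cand$rmse[i] <= best_rmse) {
      best[, c(par_names, "rmse")] <- cand[i, c(par_names, "rmse")]
      best_rmse <- cand$rmse[i]
    }
    trace <- bind_rows(trace, tibble(stage = stage, best_rmse = best_rmse,
                                     n_evaluated = sum(!is.na(cand$rmse))))
    widths <- widths / 2
    if (is.na(improved) || improved < tol ||
        max(widths) < 0.01 * max(width0)) {
      result$converged <- TRUE
      break
    }
  }
  result$best <- best
  result$best_params <- .row_to_params(best)
  result$trace <- trace
  result
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion over %d scenarios: best RMSE %.4g\n",
              nrow(x$table), x$best$rmse))
  p <- x$best_params
  cat(sprintf("  kr (T, Ly, Lo): %.3g %.3g %.3g cm/hPa/d\n",
              p$kr_T, p$kr_Ly, p$kr_Lo))
  cat(sprintf("  Kx (T, Ly, Lo): %.3g %.3g %.3g cm4/hPa/d\n",
              p$Kx_T, p$Kx_Ly, p$Kx_Lo))
  cat(if (x$converged) "  refinement converged\n" else "  not refined\n")
  invisible(x)
}

#' @export
#' @method tidy inversion_result
tidy.inversion_result <- function(x, ...) x$table

#' @export
#' @method glance inversion_result
glance.inversion_result <- function(x, ...) {
  tibble(n_scenarios = nrow(x$table),
         n_failed = sum(is.na(x$table$rmse)),
         best_rmse = x$best$rmse,
         n_stages = max(x$trace$stage),
         converged = x$converged)
}

#' 2-d sensitivity cross-sections around an optimum
#'
#' For each requested parameter pair, multiplies the two parameters by
#' factors on a geometric lattice (others held at the optimum), re-runs the
#' forward model and records the RMSE against the observation. The surface
#' value at factors (1, 1) is the optimum's score. Lattice points violating
#' `kr_Lo <= kr_Ly` are skipped (`NA`).
#'
#' @param optimum a `hydraulic_params` at the optimum.
#' @param runner,observed as in [grid_search()].
#' @param pairs list of 2-character vectors of parameter names; default all
#'   15 pairs.
#' @param factors multiplicative factors; default a 5-point geometric
#'   ladder on 1/8..8.
#' @return A `sensitivity_map`: tibble with `par1`, `par2`, `f1`, `f2`,
#'   `rmse`; attributes `optimum`, `optimum_rmse`, `factors`.
#' @export
sensitivity_cross_sections <- function(optimum, runner, observed,
                                       pairs = NULL,
                                       factors = 8^seq(-1, 1, length.out = 5)) {
  par_names <- c("kr_T", "kr_Ly", "kr_Lo", "Kx_T", "Kx_Ly", "Kx_Lo")
  if (is.null(pairs)) {
    pairs <- utils::combn(par_names, 2, simplify = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p1, f1, p2, f2) {
    vals <- unlist(optimum[par_names])
    vals[p1] <- vals[p1] * f1
    vals[p2] <- vals[p2] * f2
    if (vals["kr_Lo"] > vals["kr_Ly"] * (1 + 1e-12)) return(NA_real_)
    key <- paste(signif(vals, 10), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- hydraulic_params(vals["kr_T"], vals["kr_Ly"], vals["kr_Lo"],
                           vals["Kx_T"], vals["Kx_Ly"], vals["Kx_Lo"],
                           age_threshold = optimum$age_threshold)
    sim <- tryCatch(runner(hp), error = function(e) NULL)
    val <- if (is.null(sim)) NA_real_ else rmse_maps(observed, sim)
    cache[[key]] <- val
    val
  }
  rows <- list()
  for (pr in pairs) {
    for (f1 in factors) for (f2 in factors) {
      rows[[length(rows) + 1]] <- tibble(
        par1 = pr[1], par2 = pr[2], f1 = f1, f2 = f2,
        rmse = eval_at(pr[1], f1, pr[2], f2))
    }
  }
  out <- bind_rows(rows)
  structure(out, class = c("sensitivity_map", class(out)),
            optimum = optimum,
            optimum_rmse = eval_at("kr_T", 1, "kr_Ly", 1),
            factors = factors)
}

#' Per-parameter sensitivity profiles and flat-direction detection
#'
#' Collapses a sensitivity map to single-parameter RMSE profiles (the other
#' factor held at 1) and flags parameters whose whole-axis RMSE range is
#' below `tol` times the largest range over all parameters (insensitive,
#' "flat" directions). The default threshold, a tenth of the dynamic range,
#' sits above the Monte-Carlo noise floor of desk-scale particle budgets
#' and below any physically meaningful response. One-sidedness is summarised by the RMSE rise below
#' versus above the optimum.
#'
#' @param sm a `sensitivity_map`.
#' @param tol relative flatness threshold.
#' @return Tibble with `parameter`, `range`, `rise_below` (RMSE at the
#'   smallest factor minus at 1), `rise_above`, `flat`.
#' @export
flat_directions <- function(sm, tol = 0.1) {
  profs <- list()
  one <- function(f) abs(f - 1) < 1e-9
  for (p in unique(c(sm$par1, sm$par2))) {
    a <- sm %>% filter(.data$par1 == p, one(.data$f2)) %>%
      select(f = "f1", rmse = "rmse")
    b <- sm %>% filter(.data$par2 == p, one(.data$f1)) %>%
      select(f = "f2", rmse = "rmse")
    prof <- bind_rows(a, b) %>%
      group_by(.data$f) %>%
      summarise(rmse = mean(.data$rmse, na.rm = TRUE), .groups = "drop") %>%
      arrange(.data$f)
    prof <- prof %>% filter(is.finite(.data$rmse))
    if (nrow(prof) < 2) next
    at1 <- prof$rmse[which.min(abs(prof$f - 1))]
    profs[[length(profs) + 1]] <- tibble(
      parameter = p,
      range = max(prof$rmse) - min(prof$rmse),
      rise_below = prof$rmse[1] - at1,
      rise_above = prof$rmse[nrow(prof)] - at1
    )
  }
  out <- bind_rows(profs)
  out$flat <- out$range < tol * max(out$range)
  out
}
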