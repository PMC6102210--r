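#' @title Quasi-steady-state dynamic flux variability analysis
#' @description
#' The quantitative pipeline advances a hybrid state (Petri-net marking +
#' constrained metabolic model) in time. Each step: (1) integrate the
#' continuous signalling layer by one explicit-Euler step; (2) translate
#' the marking into flux bounds via the coupling map; (3) solve the FBA
#' problem for the protocol's objective reaction with the biomass demand
#' fixed; (4) book the solved fluxes back into medium and product places.
#' Dynamic FVA (dFVA) runs this whole simulation twice — once maximising
#' and once minimising the objective — so the two trajectories bound the
#' feasible envelope. Model parameters are never fitted to data.
#' @name dfva
NULL

#' Define a dFVA simulation protocol
#'
#' @param model a [metabolic_model()] (biomass demand is fixed on it)
#' @param coupling a [coupling_map()] wiring markings to bounds and fluxes
#'   back to markings
#' @param initial_marking named numeric vector; must cover every place the
#'   coupling map references (medium sugars in mM, signalling species, the
#'   product accumulator)
#' @param objective reaction id to optimise (e.g. the TAG synthesis
#'   reaction, or a monosaccharide exchange)
#' @param directions which directions to simulate (default both, the dFVA
#'   envelope)
#' @param dt step, hours (default 0.1)
#' @param horizon simulated time, hours (default 48); a non-multiple of
#'   `dt` truncates the last step
#' @param biomass_demand biomass flux fixed throughout (NULL = leave model
#'   as is)
#' @param net optional kinetic [petri_net()] for the signalling layer
#' @return a `dfva_protocol`
#' @export
dfva_protocol <- function(model, coupling, initial_marking, objective,
                          directions = c("max", "min"), dt = 0.1,
                          horizon = 48, biomass_demand = NULL, net = NULL) {
  stopifnot(horizon > 0, dt > 0, all(directions %in% c("max", "min")))
  rxn_index(model, objective)
  if (!is.null(biomass_demand)) model <- apply_biomass(model, biomass_demand)
  structure(list(model = model, coupling = coupling,
                 initial_marking = initial_marking, objective = objective,
                 directions = directions, dt = dt, horizon = horizon, net = net),
            class = "dfva_protocol")
}

#' One quasi-steady-state step
#'
#' @param state list with `marking` and `t`
#' @param protocol a [dfva_protocol()]
#' @param direction "max" or "min"
#' @param dt step override (defaults to the protocol's)
#' @return updated state, with `flux` (objective flux over the step; NA if
#'   the constrained model was infeasible) and `status`
#' @export
qss_step <- function(state, protocol, direction = "max", dt = protocol$dt) {
  marking <- state$marking
  if (!is.null(protocol$net)) {
    marking <- kinetic_step(protocol$net, marking, dt)
  }
  b <- bounds_from_marking(protocol$coupling, marking, protocol$model)
  model <- set_bounds(protocol$model, b)
  sol <- solve_fba(model, protocol$objective, direction)
  if (sol$status == "optimal") {
    marking <- apply_flux_to_marking(protocol$coupling, sol, marking, dt)
    flux <- sol$objective
  } else {
    flux <- NA_real_
  }
  list(marking = marking, t = state$t + dt, flux = flux, status = sol$status)
}

#' Run a dFVA simulation
#'
#' Two independent time-stepped simulations (one per direction) whose
#' objective-flux and concentration trajectories form the envelope. An
#' infeasible step is recorded (status column) and the simulation
#' continues with the marking unchanged — transient infeasibility at
#' substrate exhaustion terminates flux, not the run.
#'
#' @param protocol a [dfva_protocol()]
#' @return a `dfva_result`; `$trajectory` is a tibble with columns `time`
#'   (h), `direction`, `flux` (objective flux applied over the step
#'   starting at `time`; NA on the final row and on infeasible steps),
#'   `status`, and one column per tracked place (medium concentrations,
#'   product accumulator)
#' @export
run_dfva <- function(protocol) {
  tracked <- unique(c(
    vapply(protocol$coupling$activities, `[[`, "", "place"),
    if (!is.null(protocol$coupling$objectives)) protocol$coupling$objectives$place))
  n_steps <- ceiling(protocol$horizon / protocol$dt - 1e-9)
  rows <- list()
  for (dir in protocol$directions) {
    state <- list(marking = protocol$initial_marking, t = 0)
    for (k in seq_len(n_steps + 1L)) {
      dt_k <- min(protocol$dt, protocol$horizon - state$t)
      rec <- c(list(time = state$t, direction = dir),
               as.list(state$marking[tracked]))
      if (k <= n_steps) {
        state2 <- qss_step(state, protocol, direction = dir, dt = dt_k)
        ## exact grid time (avoids floating-point drift of accumulated dt)
        state2$t <- min(k * protocol$dt, protocol$horizon)
        rec$flux <- state2$flux
        rec$status <- state2$status
        state <- state2
      } else {
        rec$flux <- NA_real_
        rec$status <- "end"
      }
      rows[[length(rows) + 1L]] <- tibble::as_tibble(rec)
    }
  }
  traj <- dplyr::bind_rows(rows)
  traj <- dplyr::relocate(traj, "time", "direction", "flux", "status")
  structure(list(trajectory = traj, objective = protocol$objective,
                 dt = protocol$dt, horizon = protocol$horizon,
                 tracked = tracked),
            class = "dfva_result")
}

#' @export
print.dfva_result <- function(x, ...) {
  cat("<dfva_result> objective ", x$objective, ", horizon ", x$horizon,
      " h, dt ", x$dt, " h\n", sep = "")
  print(x$trajectory, n = 6)
  invisible(x)
}

#' Area under a trajectory curve
#'
#' Trapezoidal rule on the stored grid; `t0`/`t1` falling between grid
#' points are handled by linear interpolation of the bounding segment.
#'
#' @param time increasing time grid
#' @param values values on the grid (same length)
#' @param t0,t1 integration limits within the grid span
#' @return the area (e.g. mM.h/g DW for a flux trajectory)
#' @export
auc <- function(time, values, t0 = min(time), t1 = max(time)) {
  stopifnot(length(time) == length(values))
  keep <- !is.na(values)
  time <- time[keep]; values <- values[keep]
  if (is.unsorted(time, strictly = TRUE)) stop("time grid must be strictly increasing")
  if (t0 >= t1) stop("t0 must be < t1")
  if (t0 < min(time) - 1e-9 || t1 > max(time) + 1e-9) {
    stop("[t0, t1] outside the grid span")
  }
  grid <- sort(unique(c(t0, t1, time[time > t0 & time < t1])))
  vals <- stats::approx(time, values, xout = grid)$y
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}
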