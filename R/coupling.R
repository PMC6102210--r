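#' @title Coupling regulatory markings to metabolic flux bounds
#' @description
#' The contract between the Petri-net layer and the metabolic layer has
#' three parts. Constraint places carry an *activity list* translating
#' their marking into flux bounds of target reactions — either through a
#' kinetic law (medium sugar concentration -> transporter bound magnitude)
#' or through explicit marking intervals. Objective places are written
#' back from solved fluxes, converting specific flux to a medium
#' concentration change through the unit context. Gene places modulate the
#' upper bounds of their target reactions according to their expression
#' level.
#' @name coupling
NULL

#' Create an activity list for a constraint place
#'
#' Two entry styles:
#' * kinetic: `law` is a [kinetic_law()] evaluated at the place's marking;
#'   the resulting magnitude `m` becomes the bound. With `symmetric = TRUE`
#'   the bounds are `(-m, +m)`: uptake up to the kinetically possible rate,
#'   and release (export back into the medium) capped at the same
#'   magnitude. With `symmetric = FALSE` the bounds are `(-m, 0)`.
#' * intervals: a data frame with columns `lower`, `upper`, `lb`, `ub`;
#'   the first row whose (non-overlapping, inclusive-lower) interval
#'   contains the marking supplies the bounds; an unmatched marking leaves
#'   the baseline bounds untouched.
#'
#' @param place constraint place id whose marking is read
#' @param reactions target reaction id(s)
#' @param law optional [kinetic_law()]
#' @param intervals optional interval table (used when `law` is NULL)
#' @param symmetric logical, see above
#' @return an `activity_list`
#' @export
activity_list <- function(place, reactions, law = NULL, intervals = NULL,
                          symmetric = TRUE) {
  if (is.null(law) && is.null(intervals)) {
    stop("activity list needs a kinetic law or an interval table")
  }
  if (!is.null(intervals)) {
    stopifnot(all(c("lower", "upper", "lb", "ub") %in% names(intervals)),
              all(intervals$lb <= intervals$ub))
    iv <- intervals[order(intervals$lower), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$lower[-1] < iv$upper[-nrow(iv)])) {
      stop("activity-list intervals overlap for place '", place, "'")
    }
  }
  structure(list(place = place, reactions = reactions, law = law,
                 intervals = intervals, symmetric = isTRUE(symmetric)),
            class = "activity_list")
}

#' Assemble a coupling map
#'
#' @param activities list of [activity_list()] objects (constraint places)
#' @param objectives data frame with columns `place`, `reaction`: each
#'   objective place is incremented by `phi * v[reaction] * dt` per step
#' @param genes data frame with columns `gene`, `reaction`, `effect`
#'   ("activates" or "represses"): gene-level gating of reaction upper
#'   bounds
#' @param units a [make_unit_context()] result
#' @param induction_factor upper-bound scaling applied by an induced
#'   (level 2) activating gene; a repressing edge inverts the mapping
#' @return a `coupling_map`; a reaction bound controlled by more than one
#'   activity list is a structural error
#' @export
coupling_map <- function(activities = list(), objectives = NULL, genes = NULL,
                         units = make_unit_context(), induction_factor = 2) {
  if (inherits(activities, "activity_list")) activities <- list(activities)
  targets <- unlist(lapply(activities, `[[`, "reactions"))
  if (anyDuplicated(targets)) {
    dup <- unique(targets[duplicated(targets)])
    owners <- vapply(activities, function(a) {
      if (any(dup %in% a$reactions)) a$place else NA_character_
    }, "")
    stop("reaction(s) controlled by more than one constraint source: ",
         paste(dup, collapse = ", "), " (places: ",
         paste(stats::na.omit(owners), collapse = ", "), ")")
  }
  if (!is.null(genes)) {
    stopifnot(all(c("gene", "reaction", "effect") %in% names(genes)),
              all(genes$effect %in% c("activates", "represses")))
    both <- intersect(genes$reaction, targets)
    if (length(both)) {
      stop("reaction(s) controlled by both an activity list and a gene: ",
           paste(both, collapse = ", "))
    }
  }
  structure(list(activities = activities, objectives = objectives,
                 genes = genes, units = units,
                 induction_factor = induction_factor),
            class = "coupling_map")
}

#' Unit context: converting specific flux to medium concentration change
#'
#' The conversion factor is
#' `phi = (dry mass per cell * cells) / medium volume`, so that a flux in
#' mmol/g DW/h sustained for `dt` hours changes the medium concentration by
#' `phi * v * dt` mM. Defaults: 0.58 mL medium per 10^6 cells (consistent
#' with 9.3 mM of glucose being 0.97 mg per million cells) and 300 pg dry
#' mass per cell, a typical cultured-hepatocyte figure.
#'
#' @param volume_mL_per_Mcells medium volume per 10^6 cells, mL
#' @param gDW_per_cell dry mass per cell, g
#' @param n_cells cell count
#' @return a `unit_context` with the derived factor `phi`
#'   (mM per (mmol/g DW/h * h))
#' @export
make_unit_context <- function(volume_mL_per_Mcells = 0.58,
                              gDW_per_cell = 300e-12,
                              n_cells = 1e6) {
  if (any(c(volume_mL_per_Mcells, gDW_per_cell, n_cells) <= 0)) {
    stop("all unit-context inputs must be > 0")
  }
  volume_L <- volume_mL_per_Mcells * (n_cells / 1e6) / 1000
  gDW <- gDW_per_cell * n_cells
  structure(list(volume_mL_per_Mcells = volume_mL_per_Mcells,
                 gDW_per_cell = gDW_per_cell, n_cells = n_cells,
                 phi = gDW / volume_L),
            class = "unit_context")
}

#' Translate a marking into flux bounds
#'
#' Evaluates every activity list at the current marking and every gene
#' place's level against the gene-gating table. Gene semantics (activating
#' edge): level 0 scales the target's upper bound to 0, level 1 leaves the
#' baseline, level 2 multiplies it by the induction factor; a repressing
#' edge swaps the roles of levels 0 and 2.
#'
#' @param coupling a [coupling_map()]
#' @param marking named numeric marking
#' @param model the [metabolic_model()] supplying baseline bounds
#' @return data frame with columns `reaction`, `lb`, `ub`
#' @export
bounds_from_marking <- function(coupling, marking, model) {
  out <- NULL
  for (al in coupling$activities) {
    m_val <- marking[[al$place]]
    if (is.null(m_val)) stop("constraint place '", al$place, "' not in marking")
    if (!is.null(al$law)) {
      mag <- switch(al$law$form,
        michaelis_menten = mm_rate(m_val, al$law, marking = marking),
        mass_action = al$law$k * m_val,
        constant = al$law$rate)
      lbub <- if (al$symmetric) c(-mag, mag) else c(-mag, 0)
      out <- rbind(out, data.frame(reaction = al$reactions,
                                   lb = lbub[1], ub = lbub[2]))
    } else {
      iv <- al$intervals
      hit <- which(m_val >= iv$lower & m_val <= iv$upper)
      if (length(hit)) {
        out <- rbind(out, data.frame(reaction = al$reactions,
                                     lb = iv$lb[hit[1]], ub = iv$ub[hit[1]]))
      }
    }
  }
  if (!is.null(coupling$genes)) {
    g <- coupling$genes
    for (k in seq_len(nrow(g))) {
      lev <- marking[[g$gene[k]]]
      if (is.null(lev)) stop("gene place '", g$gene[k], "' not in marking")
      eff_lev <- if (g$effect[k] == "represses") 2 - lev else lev
      i <- rxn_index(model, g$reaction[k])
      base_ub <- model$ub[i]
      new_ub <- switch(as.character(eff_lev),
                       "0" = 0,
                       "1" = base_ub,
                       "2" = base_ub * coupling$induction_factor)
      out <- rbind(out, data.frame(reaction = g$reaction[k],
                                   lb = min(model$lb[i], new_ub),
                                   ub = new_ub))
    }
  }
  if (is.null(out)) out <- data.frame(reaction = character(0),
                                      lb = numeric(0), ub = numeric(0))
  if (any(out$lb > out$ub)) stop("computed lb > ub — activity list misconfigured")
  out
}

#' Write solved fluxes back into the marking
#'
#' For each objective place, the marking is incremented by
#' `phi * v[reaction] * dt`: under the sign convention an uptake flux
#' (v < 0) decreases the medium concentration. Concentrations are clipped
#' at zero with a warning.
#'
#' @param coupling a [coupling_map()] with an `objectives` table
#' @param flux_solution an optimal [solve_fba()] result
#' @param marking named numeric marking
#' @param dt step length, hours
#' @param units a unit context (defaults to the coupling map's)
#' @return the updated marking
#' @export
apply_flux_to_marking <- function(coupling, flux_solution, marking, dt,
                                  units = coupling$units) {
  if (!identical(flux_solution$status, "optimal")) {
    stop("cannot apply a non-optimal flux solution (status: ",
         flux_solution$status, ")")
  }
  if (dt <= 0) stop("dt must be > 0")
  obj <- coupling$objectives
  if (is.null(obj)) return(marking)
  for (k in seq_len(nrow(obj))) {
    v <- flux_solution$flux[[obj$reaction[k]]]
    if (is.null(v) || is.na(v)) stop("objective reaction '", obj$reaction[k],
                                     "' absent from flux solution")
    sc <- if ("scale" %in% names(obj)) obj$scale[k] else 1
    marking[[obj$place[k]]] <- marking[[obj$place[k]]] + sc * units$phi * v * dt
  }
  neg <- names(marking)[marking < 0]
  if (length(neg)) {
    warning("clipped negative concentration(s) at 0: ", paste(neg, collapse = ", "))
    marking[marking < 0] <- 0
  }
  marking
}
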