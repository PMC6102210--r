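#' @title Constraint-based metabolic models
#' @description
#' A `metabolic_model` holds a (sparse) stoichiometric matrix over declared
#' metabolite and reaction ids, per-reaction flux bounds in mmol/g DW/h, the
#' set of exchange reactions crossing the system boundary, and an optional
#' biomass demand. Flux balance analysis (FBA) and flux variability analysis
#' (FVA) are linear programmes over the steady-state polytope
#' `{v : N v = 0, lb <= v <= ub}`.
#'
#' Sign convention for exchange fluxes: positive = release/export into the
#' medium, negative = consumption/uptake from the medium.
#' @name gsmn
NULL

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' @param stoichiometry metabolites x reactions matrix (dense or
#'   [Matrix::Matrix()]), with dimnames giving metabolite and reaction ids
#' @param lb,ub named or positional flux bounds, mmol/g DW/h; `lb <= ub`
#' @param exchange character vector of exchange reaction ids
#' @param biomass optional list with `reaction` and `demand` (flux value)
#' @param compartments optional named character vector, metabolite -> tag
#' @return a `metabolic_model`
#' @export
metabolic_model <- function(stoichiometry, lb, ub, exchange = character(0),
                            biomass = NULL, compartments = NULL) {
  S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("stoichiometry needs metabolite rownames and reaction colnames")
  }
  n <- ncol(S)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) {
    stop("lb > ub for reaction(s): ",
         paste(colnames(S)[lb > ub], collapse = ", "))
  }
  bad <- setdiff(exchange, colnames(S))
  if (length(bad)) stop("unknown exchange reaction(s): ", paste(bad, collapse = ", "))
  if (!is.null(biomass)) {
    stopifnot(biomass$reaction %in% colnames(S), is.numeric(biomass$demand))
  }
  structure(list(S = S,
                 metabolites = rownames(S), reactions = colnames(S),
                 lb = setNames(lb, colnames(S)), ub = setNames(ub, colnames(S)),
                 exchange = exchange, biomass = biomass,
                 compartments = compartments),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ", length(x$exchange),
      " exchanges\n", sep = "")
  invisible(x)
}

rxn_index <- function(model, reaction) {
  i <- match(reaction, model$reactions)
  if (is.na(i)) stop("unknown reaction '", reaction, "'")
  i
}

#' Flux balance analysis
#'
#' Maximises or minimises the flux through one reaction over the
#' steady-state polytope. The objective value is the contract; when
#' alternative optima exist the returned flux vector is one arbitrary
#' optimal vertex and `alt_optima` is set (detected, when requested, by
#' re-optimising a probe functional with the objective pinned at its
#' optimum — a sufficient, not exhaustive, test of degeneracy).
#'
#' @param model a [metabolic_model()]
#' @param objective reaction id to optimise
#' @param direction "max" or "min"
#' @param detect_alt also probe for alternative optima (2 extra LP solves)
#' @return a `flux_solution`: list with `status` ("optimal", "infeasible",
#'   "unbounded"), `objective` (mmol/g DW/h), named flux vector `flux`, and
#'   `alt_optima` (logical, NA when not probed)
#' @export
solve_fba <- function(model, objective, direction = c("max", "min"),
                      detect_alt = FALSE) {
  direction <- match.arg(direction)
  i <- rxn_index(model, objective)
  n <- length(model$reactions)
  cc <- numeric(n); cc[i] <- 1
  r <- lp_solve(cc, model$S, rep(0, nrow(model$S)), model$lb, model$ub,
                maximize = direction == "max")
  if (r$status == "maxit") stop("LP solver failed to converge")
  if (r$status != "optimal") {
    return(structure(list(status = r$status, objective = NA_real_,
                          flux = NULL, alt_optima = NA),
                     class = "flux_solution"))
  }
  alt <- NA
  if (detect_alt) {
    m2 <- model
    m2$lb[i] <- m2$ub[i] <- r$x[i]
    ## asymmetric fixed weights so symmetric alternative routes differ
    probe <- sin(seq_len(n))
    lo <- lp_solve(probe, m2$S, rep(0, nrow(m2$S)), m2$lb, m2$ub, maximize = FALSE)
    hi <- lp_solve(probe, m2$S, rep(0, nrow(m2$S)), m2$lb, m2$ub, maximize = TRUE)
    alt <- lo$status == "optimal" && hi$status == "optimal" &&
      (hi$objective - lo$objective) > 1e-6
  }
  structure(list(status = "optimal", objective = r$objective,
                 flux = setNames(r$x, model$reactions), alt_optima = alt),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      if (x$status == "optimal") paste0(", objective: ", signif(x$objective, 6)),
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis for one reaction
#'
#' Minimum and maximum feasible flux through `reaction` under the model's
#' constraints, optionally after fixing additional constraints (e.g. a
#' biomass demand) first.
#'
#' @param model a [metabolic_model()]
#' @param reaction reaction id
#' @param fixed_constraints optional data frame with columns `reaction`,
#'   `lb`, `ub` applied before solving
#' @return named numeric `c(vmin, vmax)`
#' @export
flux_variability <- function(model, reaction, fixed_constraints = NULL) {
  if (!is.null(fixed_constraints)) {
    model <- set_bounds(model, fixed_constraints)
  }
  i <- rxn_index(model, reaction)
  n <- length(model$reactions)
  cc <- numeric(n); cc[i] <- 1
  b0 <- rep(0, nrow(model$S))
  lo <- lp_solve(cc, model$S, b0, model$lb, model$ub, maximize = FALSE)
  hi <- lp_solve(cc, model$S, b0, model$lb, model$ub, maximize = TRUE)
  if (lo$status == "infeasible" || hi$status == "infeasible") {
    fixed <- if (is.null(fixed_constraints)) "none" else
      paste(fixed_constraints$reaction, collapse = ", ")
    stop("constrained model infeasible (fixed constraints: ", fixed, ")")
  }
  if (lo$status == "maxit" || hi$status == "maxit") stop("LP solver failed")
  c(vmin = if (lo$status == "unbounded") -Inf else lo$objective,
    vmax = if (hi$status == "unbounded") Inf else hi$objective)
}

#' Override reaction bounds
#'
#' @param model a [metabolic_model()]
#' @param bounds data frame with columns `reaction`, `lb`, `ub`
#' @return the modified model
#' @export
set_bounds <- function(model, bounds) {
  stopifnot(all(c("reaction", "lb", "ub") %in% names(bounds)))
  for (k in seq_len(nrow(bounds))) {
    i <- rxn_index(model, bounds$reaction[k])
    model$lb[i] <- bounds$lb[k]
    model$ub[i] <- bounds$ub[k]
    if (model$lb[i] > model$ub[i]) {
      stop("lb > ub for reaction '", bounds$reaction[k], "'")
    }
  }
  model
}

#' Read a TSV bounds-override table
#'
#' Plain container for reaction-level constraint adjustments (e.g. capping
#' the committed glycolytic step at its physiological kinetic activity).
#' Columns: reaction, lb, ub; tab-separated with a header.
#'
#' @param path file path
#' @return data frame usable with [set_bounds()]
#' @export
read_bounds_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction", "lb", "ub") %in% names(d))) {
    stop("bounds file needs columns reaction, lb, ub: ", path)
  }
  d
}

#' Apply a medium composition and consumption/release limits
#'
#' Exchange reactions whose metabolite is absent from the medium get their
#' uptake closed (lb = 0); metabolites present in the medium are bounded by
#' the (max consumption, max release) pair from the NCI-60-style exchange
#' limits table, under the sign convention uptake < 0 < release. Bounds of
#' non-exchange reactions are untouched. Applying the same medium twice is
#' idempotent.
#'
#' @param model a [metabolic_model()]
#' @param medium named numeric vector, metabolite id -> concentration (mM)
#' @param limits data frame with columns `metabolite`, `consumption`,
#'   `release` (both >= 0, mmol/g DW/h); metabolites without a row fall back
#'   to `default_limits`
#' @param mapping named character vector metabolite id -> exchange reaction
#'   id; defaults to [guess_exchange_mapping()]
#' @param default_limits fallback `c(consumption, release)`
#' @return the constrained model
#' @export
apply_medium <- function(model, medium, limits = NULL, mapping = NULL,
                         default_limits = c(DEFAULT_BOUND, DEFAULT_BOUND)) {
  if (any(medium < 0)) stop("medium concentrations must be >= 0")
  if (is.null(mapping)) mapping <- guess_exchange_mapping(model)
  unmapped <- setdiff(names(medium), names(mapping))
  if (length(unmapped)) {
    stop("medium metabolite(s) with no exchange reaction: ",
         paste(unmapped, collapse = ", "))
  }
  lim_for <- function(met) {
    if (!is.null(limits) && met %in% limits$metabolite) {
      r <- limits[match(met, limits$metabolite), ]
      c(r$consumption, r$release)
    } else default_limits
  }
  for (met in names(mapping)) {
    i <- rxn_index(model, mapping[[met]])
    lm <- lim_for(met)
    if (lm[1] < 0 || lm[2] < 0) stop("exchange limits must be >= 0: ", met)
    present <- met %in% names(medium) && medium[[met]] > 0
    model$lb[i] <- if (present) -lm[1] else 0
    model$ub[i] <- lm[2]
  }
  model
}

#' Map external metabolites to their exchange reactions
#'
#' An exchange reaction touches exactly one declared metabolite (its other
#' side is the system boundary); the mapping pairs that metabolite with the
#' reaction.
#'
#' @param model a [metabolic_model()]
#' @return named character vector metabolite -> exchange reaction id
#' @export
guess_exchange_mapping <- function(model) {
  out <- character(0)
  for (rx in model$exchange) {
    i <- rxn_index(model, rx)
    mets <- model$metabolites[Matrix::which(model$S[, i] != 0)]
    if (length(mets) == 1L) out[mets] <- rx
  }
  out
}

#' Fix the biomass demand
#'
#' The biomass function represents the basic metabolic requirements of the
#' cell (glucose, ATP, ...) and is applied as a hard constraint — both
#' bounds of the biomass reaction set to the demand flux — never as the LP
#' objective. Infeasibility of the demand only surfaces at solve time.
#'
#' @param model a [metabolic_model()] with a biomass reaction declared
#' @param demand_flux required biomass flux (mmol/g DW/h)
#' @return the constrained model
#' @export
apply_biomass <- function(model, demand_flux = model$biomass$demand) {
  if (is.null(model$biomass)) stop("model declares no biomass reaction")
  i <- rxn_index(model, model$biomass$reaction)
  model$lb[i] <- model$ub[i] <- demand_flux
  model$biomass$demand <- demand_flux
  model
}
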