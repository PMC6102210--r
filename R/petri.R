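#' @title Multi-formalism Petri nets for regulatory and signalling dynamics
#' @description
#' The regulatory layer of the simulator is a Petri net mixing two
#' formalisms: continuous places carrying concentrations (signalling
#' species, medium sugars) updated by kinetic transitions, and discrete
#' places carrying small integer levels (gene expression states, treatment
#' token pools) updated by guarded rule transitions. A net is a plain list
#' of places and transitions; the marking travels separately as a named
#' numeric vector so that simulation code never mutates the net.
#' @name petri
NULL

#' Create a place
#'
#' @param id unique place identifier
#' @param kind one of "species", "gene", "constraint", "objective", "treatment"
#' @param marking initial marking: non-negative real (continuous) or integer
#'   level (discrete)
#' @param discrete logical; discrete places carry integer levels
#' @param level_range inclusive integer interval for discrete levels
#' @param units free-text unit label (e.g. "mM", "nM", "level")
#' @return a `pn_place` list
#' @export
pn_place <- function(id, kind = c("species", "gene", "constraint", "objective",
                                  "treatment"),
                     marking = 0, discrete = FALSE,
                     level_range = c(0L, 2L), units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (discrete) {
    stopifnot(marking == round(marking),
              marking >= level_range[1], marking <= level_range[2])
  } else if (marking < 0) {
    stop("continuous marking must be non-negative for place '", id, "'")
  }
  structure(list(id = id, kind = kind, marking = as.numeric(marking),
                 discrete = isTRUE(discrete),
                 level_range = as.integer(level_range), units = units),
            class = "pn_place")
}

#' Create a guard condition
#'
#' Guards are declarative so nets can round-trip through JSON. A guard is a
#' conjunction of atomic tests on place markings. The test "present" follows
#' the convention: a continuous place is present when its marking exceeds 0;
#' a discrete gene-level place is present (active as a regulator) only at its
#' induced level 2. "absent" is the negation.
#'
#' @param place place id the condition reads
#' @param test one of "present", "absent", "ge", "le", "eq"
#' @param value threshold for ge/le/eq
#' @return a `pn_guard` condition (combine in a list for conjunction)
#' @export
pn_guard <- function(place, test = c("present", "absent", "ge", "le", "eq"),
                     value = NA_real_) {
  test <- match.arg(test)
  structure(list(place = place, test = test, value = value), class = "pn_guard")
}

#' Create a transition
#'
#' @param id unique transition id
#' @param mode "kinetic" (continuous-rate, integrated by [kinetic_step()]) or
#'   "rule" (guarded discrete firing, enumerated by [enabled_transitions()])
#' @param arcs data frame with columns `place`, `weight` (> 0), `kind`
#'   ("consume", "produce", "test", "inhibit")
#' @param rate_law a [kinetic_law()] (kinetic mode only)
#' @param guard list of [pn_guard()] conditions, all of which must hold
#'   (rule mode only)
#' @return a `pn_transition` list
#' @export
pn_transition <- function(id, mode = c("rule", "kinetic"), arcs,
                          rate_law = NULL, guard = list()) {
  mode <- match.arg(mode)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  stopifnot(all(c("place", "weight", "kind") %in% names(arcs)),
            all(arcs$weight > 0),
            all(arcs$kind %in% c("consume", "produce", "test", "inhibit")))
  if (mode == "kinetic" && is.null(rate_law)) {
    stop("kinetic transition '", id, "' needs a rate_law")
  }
  if (inherits(guard, "pn_guard")) guard <- list(guard)
  structure(list(id = id, mode = mode, arcs = arcs,
                 rate_law = rate_law, guard = guard),
            class = "pn_transition")
}

#' Helper to build an arc table
#' @param place,weight,kind vectors recycled to a data frame
#' @export
pn_arcs <- function(place, weight = 1, kind = "consume") {
  data.frame(place = place, weight = weight, kind = kind,
             stringsAsFactors = FALSE)
}

#' Assemble a Petri net
#'
#' Validates structural closure (every arc and guard references a declared
#' place, ids unique) and that the initial marking satisfies the place
#' invariants.
#'
#' @param places list of [pn_place()]
#' @param transitions list of [pn_transition()]
#' @return a `petri_net` object; the initial marking is in `$marking`
#' @export
petri_net <- function(places, transitions = list()) {
  ids <- vapply(places, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate place ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tids <- vapply(transitions, `[[`, "", "id")
  if (anyDuplicated(tids)) stop("duplicate transition ids")
  for (tr in transitions) {
    bad <- setdiff(tr$arcs$place, ids)
    gplaces <- vapply(tr$guard, `[[`, "", "place")
    bad <- c(bad, setdiff(gplaces, ids))
    if (length(bad)) {
      stop("transition '", tr$id, "' references unknown place(s): ",
           paste(unique(bad), collapse = ", "))
    }
    if (tr$mode == "kinetic") {
      touched <- tr$arcs$place
      disc <- ids[vapply(places, `[[`, TRUE, "discrete")]
      if (length(intersect(touched, disc))) {
        stop("kinetic transition '", tr$id, "' touches discrete place(s)")
      }
    }
  }
  names(places) <- ids
  names(transitions) <- tids
  marking <- vapply(places, `[[`, 0, "marking")
  net <- structure(list(places = places, transitions = transitions,
                        marking = marking),
                   class = "petri_net")
  validate_marking(net, marking)
  net
}

#' @export
print.petri_net <- function(x, ...) {
  nd <- sum(vapply(x$places, `[[`, TRUE, "discrete"))
  cat("<petri_net> ", length(x$places), " places (", nd, " discrete), ",
      length(x$transitions), " transitions\n", sep = "")
  invisible(x)
}

#' Validate a marking against a net's place invariants
#' @param net a [petri_net()]
#' @param marking named numeric vector
#' @return the marking, invisibly; errors on violation
#' @export
validate_marking <- function(net, marking) {
  if (!all(names(net$places) %in% names(marking))) {
    stop("marking is missing places: ",
         paste(setdiff(names(net$places), names(marking)), collapse = ", "))
  }
  for (p in net$places) {
    v <- marking[[p$id]]
    if (p$discrete) {
      if (v != round(v) || v < p$level_range[1] || v > p$level_range[2]) {
        stop("discrete place '", p$id, "' out of level range: ", v)
      }
    } else if (v < 0) {
      stop("negative marking on continuous place '", p$id, "': ", v)
    }
  }
  invisible(marking)
}

place_present <- function(net, marking, id) {
  p <- net$places[[id]]
  if (is.null(p)) stop("guard references unknown place '", id, "'")
  if (p$discrete && p$kind == "gene") marking[[id]] == 2 else marking[[id]] > 0
}

guard_holds <- function(net, marking, guard) {
  for (g in guard) {
    ok <- switch(g$test,
      present = place_present(net, marking, g$place),
      absent  = !place_present(net, marking, g$place),
      ge = marking[[g$place]] >= g$value,
      le = marking[[g$place]] <= g$value,
      eq = marking[[g$place]] == g$value)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

arc_feasible <- function(net, marking, tr) {
  for (i in seq_len(nrow(tr$arcs))) {
    a <- tr$arcs[i, ]
    v <- marking[[a$place]]
    p <- net$places[[a$place]]
    ok <- switch(a$kind,
      consume = v >= a$weight,
      produce = !p$discrete || (v + a$weight) <= p$level_range[2],
      test    = v >= a$weight,
      inhibit = v < a$weight)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Enumerate enabled rule transitions
#'
#' A rule transition is enabled when all its guard conditions hold, all
#' consume/test arcs are covered by the marking, inhibit arcs are below
#' threshold, and every produce arc on a discrete place stays within the
#' place's level range (so firing can never break an invariant). The result
#' is sorted lexicographically by transition id.
#'
#' @param net a [petri_net()]
#' @param marking named numeric marking (defaults to the net's initial one)
#' @return character vector of enabled transition ids
#' @export
enabled_transitions <- function(net, marking = net$marking) {
  validate_marking(net, marking)
  en <- character(0)
  for (tr in net$transitions) {
    if (tr$mode != "rule") next
    if (guard_holds(net, marking, tr$guard) && arc_feasible(net, marking, tr)) {
      en <- c(en, tr$id)
    }
  }
  sort(en)
}

#' Fire a rule transition
#'
#' Applies consume/produce arc weights; test and inhibit arcs read but do
#' not change the marking. Firing a disabled transition is an error.
#'
#' @inheritParams enabled_transitions
#' @param transition_id id of an enabled rule transition
#' @return the successor marking
#' @export
fire <- function(net, marking, transition_id) {
  tr <- net$transitions[[transition_id]]
  if (is.null(tr)) stop("unknown transition '", transition_id, "'")
  if (!(transition_id %in% enabled_transitions(net, marking))) {
    stop("transition '", transition_id, "' is not enabled at this marking")
  }
  for (i in seq_len(nrow(tr$arcs))) {
    a <- tr$arcs[i, ]
    if (a$kind == "consume") marking[[a$place]] <- marking[[a$place]] - a$weight
    if (a$kind == "produce") marking[[a$place]] <- marking[[a$place]] + a$weight
  }
  validate_marking(net, marking)
  marking
}

#' Explicit-Euler step for the continuous (kinetic) layer
#'
#' Evaluates all kinetic transition rates at the current marking and applies
#' one forward-Euler update `m' = m + dt * S %*% rates`. Continuous markings
#' are clipped at zero with a warning, since concentrations are physical
#' quantities. Discrete places are never touched.
#'
#' @inheritParams enabled_transitions
#' @param dt step size in hours (> 0)
#' @return the updated marking
#' @export
kinetic_step <- function(net, marking = net$marking, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  validate_marking(net, marking)
  dm <- setNames(numeric(length(marking)), names(marking))
  for (tr in net$transitions) {
    if (tr$mode != "kinetic") next
    rate <- transition_rate(net, marking, tr)
    for (i in seq_len(nrow(tr$arcs))) {
      a <- tr$arcs[i, ]
      if (a$kind == "consume") dm[[a$place]] <- dm[[a$place]] - a$weight * rate
      if (a$kind == "produce") dm[[a$place]] <- dm[[a$place]] + a$weight * rate
    }
  }
  out <- marking + dt * dm
  neg <- names(out)[out < 0]
  if (length(neg)) {
    warning("clipped negative marking(s) at 0: ", paste(neg, collapse = ", "))
    out[out < 0] <- 0
  }
  validate_marking(net, out)
  out
}

transition_rate <- function(net, marking, tr) {
  law <- tr$rate_law
  base <- switch(law$form,
    michaelis_menten = {
      s_id <- law$substrate
      if (is.null(s_id)) {
        cons <- tr$arcs$place[tr$arcs$kind == "consume"]
        if (!length(cons)) stop("MM transition '", tr$id, "' has no substrate")
        s_id <- cons[[1]]
      }
      mm_rate(marking[[s_id]], law, marking = marking, apply_modifiers = FALSE)
    },
    mass_action = {
      cons <- tr$arcs[tr$arcs$kind == "consume", , drop = FALSE]
      law$k * prod(marking[cons$place]^cons$weight)
    },
    constant = law$rate)
  base * modifier_scale(law, marking)
}

#' Build a three-level gene-expression motif
#'
#' A gene place has levels 0 (inhibited), 1 (basal), 2 (induced). The motif
#' contributes rule transitions: `induce` steps the level up while an
#' activator is present, `repress` steps it down while an inhibitor is
#' present, and `relax` transitions restore level 1 from either extreme once
#' the corresponding regulator is absent — so basal expression is always
#' reachable again when regulation is withdrawn.
#'
#' @param gene_id id for the gene place
#' @param activator,inhibitor place ids of regulators (either may be NULL)
#' @param level initial level (default 1, basal)
#' @return list with `$place` and `$transitions`, ready for [petri_net()]
#' @export
gene_motif <- function(gene_id, activator = NULL, inhibitor = NULL, level = 1L) {
  place <- pn_place(gene_id, kind = "gene", marking = level, discrete = TRUE,
                    level_range = c(0L, 2L), units = "level")
  trs <- list()
  if (!is.null(activator)) {
    trs <- c(trs, list(
      pn_transition(paste0(gene_id, "_induce"), "rule",
                    pn_arcs(gene_id, 1, "produce"),
                    guard = list(pn_guard(activator, "present"),
                                 pn_guard(gene_id, "ge", 1))),
      pn_transition(paste0(gene_id, "_relax_down"), "rule",
                    pn_arcs(gene_id, 1, "consume"),
                    guard = list(pn_guard(activator, "absent"),
                                 pn_guard(gene_id, "eq", 2)))))
  }
  if (!is.null(inhibitor)) {
    trs <- c(trs, list(
      pn_transition(paste0(gene_id, "_repress"), "rule",
                    pn_arcs(gene_id, 1, "consume"),
                    guard = list(pn_guard(inhibitor, "present"),
                                 pn_guard(gene_id, "ge", 1))),
      pn_transition(paste0(gene_id, "_relax_up"), "rule",
                    pn_arcs(gene_id, 1, "produce"),
                    guard = list(pn_guard(inhibitor, "absent"),
                                 pn_guard(gene_id, "eq", 0)))))
  }
  list(place = place, transitions = trs)
}
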