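#' @title Monte Carlo simulation of regulated metabolism
#' @description
#' The qualitative pipeline samples trajectories of the rule-based
#' regulatory net coupled to the metabolic model. Time is in arbitrary
#' units and reflects exclusively the order of events: at each step the
#' enabled rule transitions are enumerated, one is drawn uniformly at
#' random (seeded), fired, and the gene-gated flux capability of the
#' monitored reactions is recorded as the FVA maximum under the current
#' bounds with the biomass demand fixed — a capability statement robust
#' to LP degeneracy where a single FBA vector is not. Ensembles of
#' independent trajectories yield fraction-of-trajectories statistics
#' with Clopper-Pearson binomial confidence intervals.
#' @name qualitative
NULL

## enabled rule transitions without re-validating the marking (hot loop)
enabled_rule_ids <- function(net, marking) {
  en <- character(0)
  for (tr in net$transitions) {
    if (tr$mode != "rule") next
    if (guard_holds(net, marking, tr$guard) && arc_feasible(net, marking, tr)) {
      en <- c(en, tr$id)
    }
  }
  sort(en)
}

## Precompile a net's rule transitions into index/weight vectors so the
## Monte Carlo loop avoids data-frame access. Semantics identical to
## enabled_transitions()/fire(); transitions kept in lexicographic order.
compile_rule_net <- function(net) {
  pn <- names(net$places)
  gene_present <- vapply(net$places, function(p) p$discrete && p$kind == "gene",
                         TRUE)
  disc_max <- vapply(net$places, function(p)
    if (p$discrete) p$level_range[2] else Inf, 0)
  rules <- Filter(function(tr) tr$mode == "rule", net$transitions)
  rules <- rules[order(names(rules))]
  compiled <- lapply(rules, function(tr) {
    a <- tr$arcs
    pick <- function(kind) {
      k <- a$kind == kind
      list(i = match(a$place[k], pn), w = a$weight[k])
    }
    g <- if (length(tr$guard)) {
      data.frame(i = match(vapply(tr$guard, `[[`, "", "place"), pn),
                 code = match(vapply(tr$guard, `[[`, "", "test"),
                              c("present", "absent", "ge", "le", "eq")),
                 value = vapply(tr$guard, `[[`, 0, "value"))
    } else NULL
    list(id = tr$id, cons = pick("consume"), prod = pick("produce"),
         test = pick("test"), inh = pick("inhibit"), guard = g)
  })
  list(transitions = compiled, gene_present = unname(gene_present),
       disc_max = unname(disc_max))
}

compiled_enabled <- function(cn, m) {
  ok <- vapply(cn$transitions, function(tr) {
    g <- tr$guard
    if (!is.null(g)) {
      for (r in seq_len(nrow(g))) {
        v <- m[g$i[r]]
        pres <- if (cn$gene_present[g$i[r]]) v == 2 else v > 0
        hold <- switch(g$code[r], pres, !pres,
                       v >= g$value[r], v <= g$value[r], v == g$value[r])
        if (!hold) return(FALSE)
      }
    }
    all(m[tr$cons$i] >= tr$cons$w) &&
      all(m[tr$test$i] >= tr$test$w) &&
      all(m[tr$inh$i] < tr$inh$w) &&
      all(m[tr$prod$i] + tr$prod$w <= cn$disc_max[tr$prod$i])
  }, TRUE)
  which(ok)
}

compiled_fire <- function(cn, m, k) {
  tr <- cn$transitions[[k]]
  m[tr$cons$i] <- m[tr$cons$i] - tr$cons$w
  m[tr$prod$i] <- m[tr$prod$i] + tr$prod$w
  m
}

gene_places <- function(regulome) {
  ids <- names(regulome$net$places)
  ids[vapply(regulome$net$places, function(p) p$kind == "gene", TRUE)]
}

baseline_marking <- function(regulome) {
  m <- regulome$net$marking
  m[regulome$treatment_place] <- 0
  m[gene_places(regulome)] <- 1
  m
}

## FVA max of each monitored reaction under the gene-gated bounds implied
## by `marking`; memoised in `cache` keyed by the gene-level signature
monitored_capability <- function(model, coupling, regulome, marking,
                                 monitored, cache = NULL) {
  key <- paste0("s:", paste(marking[gene_places(regulome)], collapse = "|"))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  b <- bounds_from_marking(coupling, marking, model)
  m2 <- set_bounds(model, b)
  v <- vapply(monitored, function(rx) flux_variability(m2, rx)[["vmax"]], 0)
  if (!is.null(cache)) cache[[key]] <- v
  v
}

#' Sample one regulatory trajectory
#'
#' @param model the gene-gated [metabolic_model()] (biomass already fixed)
#' @param coupling a [coupling_map()] whose `genes` table wires the
#'   regulome's gene places to reaction bounds
#' @param regulome a `regulome_model` (see [make_toy_regulome()]); its net
#'   supplies the rule transitions and initial marking
#' @param treatment number of agonist tokens placed on the treatment place
#'   at step 0 (the treatment onset); NULL keeps the net's own marking
#' @param monitored reaction ids whose flux capability is recorded at
#'   every step (default: the regulome's gated reactions)
#' @param max_steps hard cap on the number of events
#' @param seed RNG seed (trajectories are bit-reproducible given it)
#' @param cache optional environment for memoising capability solves
#' @return a `trajectory`: list with `events` (tibble: step, transition),
#'   `markings` ((steps+1) x places matrix, row 1 = initial), `fluxes`
#'   ((steps+1) x monitored matrix), `seed`, `baseline` (marking + fluxes
#'   at basal expression, treatment cleared)
#' @export
run_trajectory <- function(model, coupling, regulome, treatment = NULL,
                           monitored = NULL, max_steps = 200, seed = 1,
                           cache = NULL) {
  if (max_steps <= 0) stop("max_steps must be > 0")
  if (is.null(monitored)) monitored <- unique(regulome$map$reaction)
  net <- regulome$net
  marking <- net$marking
  if (!is.null(treatment)) {
    p <- net$places[[regulome$treatment_place]]
    if (treatment > p$level_range[2]) {
      stop("treatment exceeds the treatment place's level range")
    }
    marking[regulome$treatment_place] <- treatment
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  base_m <- baseline_marking(regulome)
  base_f <- monitored_capability(model, coupling, regulome, base_m,
                                 monitored, cache)
  cn <- cache[["__compiled__"]]
  if (is.null(cn)) cn <- cache[["__compiled__"]] <- compile_rule_net(net)
  gp_idx <- match(gene_places(regulome), names(marking))
  n_pl <- length(marking)
  markings <- matrix(NA_real_, max_steps + 1L, n_pl,
                     dimnames = list(NULL, names(marking)))
  fluxes <- matrix(NA_real_, max_steps + 1L, length(monitored),
                   dimnames = list(NULL, monitored))
  capability <- function(m) {
    key <- paste0("s:", paste(m[gp_idx], collapse = "|"))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- cache[[key]] <- monitored_capability(model, coupling, regulome,
                                                m, monitored)
    }
    v
  }
  markings[1L, ] <- marking
  fluxes[1L, ] <- capability(marking)
  events <- character(max_steps)
  k <- 0L
  withr::with_seed(seed, {
    while (k < max_steps) {
      en <- compiled_enabled(cn, marking)
      if (!length(en)) break
      pick <- if (length(en) == 1L) en else en[sample.int(length(en), 1L)]
      marking <- compiled_fire(cn, marking, pick)
      k <- k + 1L
      events[k] <- cn$transitions[[pick]]$id
      markings[k + 1L, ] <- marking
      fluxes[k + 1L, ] <- capability(marking)
    }
  })
  structure(list(
    events = tibble::tibble(step = seq_len(k), transition = events[seq_len(k)]),
    markings = markings[seq_len(k + 1L), , drop = FALSE],
    fluxes = fluxes[seq_len(k + 1L), , drop = FALSE],
    monitored = monitored, seed = seed,
    treatment_place = regulome$treatment_place,
    baseline = list(marking = base_m, fluxes = base_f)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$events), " events, monitoring ",
      paste(x$monitored, collapse = ", "), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Sample an ensemble of independent trajectories
#'
#' Child seeds are derived reproducibly from the master seed, so the same
#' master seed gives an identical ensemble.
#'
#' @inheritParams run_trajectory
#' @param n number of trajectories (default 100, the study's sampling)
#' @param master_seed master RNG seed
#' @return a `trajectory_ensemble`: list of trajectories plus seeds
#' @export
run_ensemble <- function(model, coupling, regulome, treatment = NULL,
                         n = 100, master_seed = 1, monitored = NULL,
                         max_steps = 200) {
  if (n < 1) stop("n must be >= 1")
  child_seeds <- withr::with_seed(master_seed,
    sample.int(.Machine$integer.max - 1L, n))
  cache <- new.env(parent = emptyenv())
  trajectories <- lapply(child_seeds, function(s) {
    run_trajectory(model, coupling, regulome, treatment = treatment,
                   monitored = monitored, max_steps = max_steps, seed = s,
                   cache = cache)
  })
  structure(list(trajectories = trajectories, n = n,
                 master_seed = master_seed, child_seeds = child_seeds,
                 monitored = trajectories[[1]]$monitored),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> ", x$n, " trajectories (master seed ",
      x$master_seed, ")\n", sep = "")
  invisible(x)
}

#' Fraction of trajectories with increased flux capability
#'
#' A trajectory counts as increased when its maximal post-onset flux
#' capability toward `reaction` exceeds the baseline by more than `tol`.
#' The 95% confidence interval is Clopper-Pearson (exact binomial).
#'
#' @param ensemble a [run_ensemble()] result
#' @param reaction monitored reaction id
#' @param baseline baseline flux capability (default: taken from the
#'   trajectories' stored baseline)
#' @param tol increase tolerance
#' @return a `fraction_statistic`: list with `fraction`, `n`, `conf_low`,
#'   `conf_high`
#' @export
fraction_increased_flux <- function(ensemble, reaction, baseline = NULL,
                                    tol = 1e-6) {
  if (!reaction %in% ensemble$monitored) {
    stop("reaction '", reaction, "' was not monitored in this ensemble")
  }
  if (is.null(baseline)) {
    baseline <- ensemble$trajectories[[1]]$baseline$fluxes[[reaction]]
  }
  inc <- vapply(ensemble$trajectories, function(tr) {
    max(tr$fluxes[, reaction]) > baseline + tol
  }, TRUE)
  k <- sum(inc); n <- length(inc)
  ci <- stats::binom.test(k, n)$conf.int
  structure(list(fraction = k / n, n = n,
                 conf_low = ci[1], conf_high = ci[2],
                 reaction = reaction, baseline = baseline),
            class = "fraction_statistic")
}

#' @export
print.fraction_statistic <- function(x, ...) {
  cat("<fraction_statistic> ", x$reaction, ": ", signif(x$fraction, 4),
      " (n = ", x$n, ", 95% CI ", signif(x$conf_low, 3), "-",
      signif(x$conf_high, 3), ")\n", sep = "")
  invisible(x)
}

#' Freeze a regulome at basal expression (regulatory-naive control)
#'
#' All gene places are pinned at level 1, every rule transition touching a
#' gene place (by arc or guard) is removed, and the gene-gated bounds
#' therefore stay at baseline in every reachable state. Treatment
#' clearance transitions are kept, so the agonist is still consumed —
#' without any regulatory response.
#'
#' @param regulome a `regulome_model`
#' @return the frozen regulome (`frozen = TRUE`)
#' @export
make_regulatory_naive <- function(regulome) {
  gp <- gene_places(regulome)
  keep <- Filter(function(tr) {
    arcs_touch <- any(tr$arcs$place %in% gp)
    guard_touch <- any(vapply(tr$guard, `[[`, "", "place") %in% gp)
    !(arcs_touch || guard_touch)
  }, regulome$net$transitions)
  places <- lapply(regulome$net$places, function(p) {
    if (p$kind == "gene") p$marking <- 1
    p
  })
  regulome$net <- petri_net(places, keep)
  regulome$frozen <- TRUE
  regulome
}

#' Detect acute and reconstitutive phases of a trajectory
#'
#' The acute phase spans treatment onset (step 0, tokens placed) to the
#' step at which the treatment place first empties. The reconstitutive
#' phase extends from clearance to the first step at which the marking
#' and all monitored flux capabilities equal baseline and stay there for
#' `window` consecutive recorded steps (a trajectory that ends in the
#' baseline state counts as persisting). `returned_to_baseline` reports
#' whether that happened within the trajectory.
#'
#' @param trajectory a [run_trajectory()] result
#' @param window stability window, steps (default 10)
#' @param tol flux comparison tolerance
#' @return a `phase_annotation`: list with `acute` (c(start, end) step
#'   indices or NULL), `reconstitutive`, `returned_to_baseline`
#' @export
detect_phases <- function(trajectory, window = 10, tol = 1e-6) {
  tp <- trajectory$treatment_place
  tok <- trajectory$markings[, tp]
  n <- nrow(trajectory$markings)  # states 0..n-1
  if (tok[1] <= 0) {
    return(structure(list(acute = NULL, reconstitutive = NULL,
                          returned_to_baseline = TRUE),
                     class = "phase_annotation"))
  }
  cleared <- which(tok == 0)[1]
  if (is.na(cleared)) {
    return(structure(list(acute = c(0L, n - 1L), reconstitutive = NULL,
                          returned_to_baseline = FALSE),
                     class = "phase_annotation"))
  }
  base <- trajectory$baseline
  at_base <- vapply(seq_len(n), function(i) {
    all(abs(trajectory$markings[i, names(base$marking)] - base$marking) < 1e-9) &&
      all(abs(trajectory$fluxes[i, ] - base$fluxes[trajectory$monitored]) < tol)
  }, TRUE)
  ## first index >= cleared from which baseline persists to the end or for
  ## `window` steps
  ret <- NA_integer_
  for (i in seq.int(cleared, n)) {
    stretch <- seq.int(i, min(i + window - 1L, n))
    if (all(at_base[stretch]) && (max(stretch) == n || length(stretch) >= window)) {
      ret <- i; break
    }
  }
  acute <- c(0L, cleared - 1L)
  if (is.na(ret)) {
    rec <- c(cleared - 1L, n - 1L)
    returned <- FALSE
  } else if (ret == cleared) {
    rec <- NULL     # baseline immediately on clearance: no reconstitutive phase
    returned <- TRUE
  } else {
    rec <- c(cleared - 1L, ret - 1L)
    returned <- TRUE
  }
  structure(list(acute = acute, reconstitutive = rec,
                 returned_to_baseline = returned),
            class = "phase_annotation")
}

#' Flux matrix of a trajectory (reactions x steps)
#'
#' Signed flux capabilities in event order, the data behind the trajectory
#' heatmap (positive flux rendered green, negative red).
#'
#' @param trajectory a [run_trajectory()] result
#' @param reactions monitored reaction ids (default: all monitored)
#' @return numeric matrix, reactions in rows, one column per event (the
#'   pre-treatment state is not a column; it is the baseline)
#' @export
flux_heatmap_matrix <- function(trajectory, reactions = trajectory$monitored) {
  if (!length(reactions)) stop("empty reaction list")
  missing <- setdiff(reactions, trajectory$monitored)
  if (length(missing)) {
    stop("reaction(s) not monitored: ", paste(missing, collapse = ", "))
  }
  t(trajectory$fluxes[-1, reactions, drop = FALSE])
}

#' Exact success probability of the toy regulome by enumeration
#'
#' Exhaustively enumerates the uniform-random firing process of a rule
#' net (memoised on markings) and returns the probability that `place`
#' ever reaches a marking `>= level`. Tractable for the toy regulome's
#' handful of transitions; used as ground truth for ensemble calibration.
#'
#' @param regulome a `regulome_model`
#' @param place place id to watch (default: the first target gene)
#' @param level success threshold (default 2, induced)
#' @param treatment tokens placed at onset (NULL keeps the net's marking)
#' @return exact probability in [0, 1]
#' @export
enumerate_success_probability <- function(regulome, place = NULL, level = 2,
                                          treatment = NULL) {
  net <- regulome$net
  if (is.null(place)) place <- regulome$map$gene[1]
  marking <- net$marking
  if (!is.null(treatment)) marking[regulome$treatment_place] <- treatment
  memo <- new.env(parent = emptyenv())
  recurse <- function(m) {
    if (m[[place]] >= level) return(1)
    key <- paste(m, collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    en <- enabled_rule_ids(net, m)
    if (!length(en)) return(memo[[key]] <- 0)
    p <- mean(vapply(en, function(tr) recurse(fire(net, m, tr)), 0))
    memo[[key]] <- p
  }
  recurse(marking)
}
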