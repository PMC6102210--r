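#' @title Desk-scale synthetic models and data
#' @description
#' Generators for every fixture the pipeline needs: a ~20-reaction
#' hepatocyte-like stoichiometric network whose optima are auditable by
#' hand, a small transcription-factor regulome whose trajectory statistics
#' are exactly enumerable, and Michaelis-Menten depletion observations
#' with additive truncated-Gaussian noise. These are first-class, tested
#' components: the toy network carries the biology the full model has at
#' scale (glucose and fructose uptake, a capped committed glycolytic step
#' that fructolysis bypasses, de novo lipogenesis, cytosolic TAG
#' synthesis, a biomass demand), shrunk until a hand calculation fits on
#' one page.
#' @name synthetic
NULL

#' Generate the toy hepatocyte metabolic network
#'
#' Reactions (mmol/g DW/h throughout):
#' * `EX_glc`, `EX_fru`, `EX_o2`, `EX_co2`: boundary exchanges (positive =
#'   release into medium, negative = uptake).
#' * `GLCt`, `FRUt`: reversible monosaccharide transport.
#' * `GK`: committed glycolytic step, `glc_c -> 2 tp_c`, capped at
#'   `gk_cap` — the rate-limiting step.
#' * `KHK`: fructolysis, `fru_c -> 2 tp_c`, capped at `khk_cap`; this
#'   route bypasses the GK cap, mirroring hepatic fructose metabolism.
#' * `GNG`: gluconeogenesis `2 tp_c -> glc_c`, giving the network a
#'   glucose-export route.
#' * `GLY`: `tp_c -> pyr_c + 2 atp_c`; `PDH`: `pyr_c -> accoa_c + co2_c`;
#'   `RESP`: `pyr_c + 3 o2_c -> 3 co2_c + 15 atp_c`.
#' * `DNL`: de novo lipogenesis, `4 accoa_c + atp_c -> fa_c`.
#' * `TAGS`: TAG synthesis `3 fa_c + tp_c -> tag_c` — the toy analogue of
#'   the full model's TAG production objective.
#' * `SINK_tag`, `ATPM`, `BIOMASS` (`tp_c + 10 atp_c ->`): sinks/demands.
#'
#' Analytic optimum (documented for audit): with glucose the only carbon
#' source and uptake magnitude `u`, committed-step flux is
#' `vGK = min(u, gk_cap)`, and maximal TAG synthesis under biomass demand
#' `b` is `T = (2 vGK - b) / 13` (13 = 12 triose-equivalents through
#' lipogenesis + 1 glycerol backbone per TAG; ATP is then in surplus).
#' The same formula holds for fructose with `vKHK = min(u, khk_cap)`.
#'
#' @param include_fructose_bypass include the KHK route (default TRUE)
#' @param gk_cap,khk_cap capacity caps of the committed steps
#' @param biomass_demand default biomass demand registered on the model
#' @param tag_cap optional finite upper bound on `TAGS` (used by the toy
#'   regulome so gene induction is necessary for increased TAG capability)
#' @return a [metabolic_model()]
#' @export
make_toy_hepatocyte_gsmn <- function(include_fructose_bypass = TRUE,
                                     gk_cap = 5, khk_cap = 10,
                                     biomass_demand = 0.1, tag_cap = Inf) {
  if (gk_cap <= 0 || khk_cap <= 0) stop("capacity caps must be > 0")
  mets <- c("glc_e", "fru_e", "o2_e", "co2_e",
            "glc_c", "fru_c", "tp_c", "pyr_c", "accoa_c", "fa_c", "tag_c",
            "atp_c", "o2_c", "co2_c")
  rx <- list(
    EX_glc  = c(glc_e = -1),
    EX_fru  = c(fru_e = -1),
    EX_o2   = c(o2_e = -1),
    EX_co2  = c(co2_e = -1),
    GLCt    = c(glc_e = -1, glc_c = 1),
    FRUt    = c(fru_e = -1, fru_c = 1),
    GK      = c(glc_c = -1, tp_c = 2),
    KHK     = c(fru_c = -1, tp_c = 2),
    GNG     = c(tp_c = -2, glc_c = 1),
    GLY     = c(tp_c = -1, pyr_c = 1, atp_c = 2),
    PDH     = c(pyr_c = -1, accoa_c = 1, co2_c = 1),
    RESP    = c(pyr_c = -1, o2_c = -3, co2_c = 3, atp_c = 15),
    O2t     = c(o2_e = -1, o2_c = 1),
    CO2t    = c(co2_c = -1, co2_e = 1),
    DNL     = c(accoa_c = -4, atp_c = -1, fa_c = 1),
    TAGS    = c(fa_c = -3, tp_c = -1, tag_c = 1),
    SINK_tag = c(tag_c = -1),
    ATPM    = c(atp_c = -1),
    BIOMASS = c(tp_c = -1, atp_c = -10))
  if (!include_fructose_bypass) rx$KHK <- NULL
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, names(rx)))
  for (r in names(rx)) S[names(rx[[r]]), r] <- rx[[r]]
  B <- DEFAULT_BOUND
  lb <- setNames(rep(0, length(rx)), names(rx))
  ub <- setNames(rep(B, length(rx)), names(rx))
  rev <- intersect(c("EX_glc", "EX_fru", "EX_o2", "EX_co2", "GLCt", "FRUt"),
                   names(rx))
  lb[rev] <- -B
  ub["GK"] <- gk_cap
  if (include_fructose_bypass) ub["KHK"] <- khk_cap
  ub["TAGS"] <- min(tag_cap, B)
  model <- metabolic_model(
    S, lb, ub,
    exchange = intersect(c("EX_glc", "EX_fru", "EX_o2", "EX_co2"), names(rx)),
    biomass = list(reaction = "BIOMASS", demand = biomass_demand),
    compartments = setNames(ifelse(grepl("_e$", mets), "e", "c"), mets))
  ## sanity: the biomass demand must be attainable with both sugars open
  chk <- apply_biomass(model, biomass_demand)
  sol <- solve_fba(chk, "BIOMASS", "max")
  if (sol$status != "optimal") {
    stop("generator error: biomass demand ", biomass_demand,
         " unreachable under the given caps")
  }
  model
}

#' Analytic maximal TAG flux of the toy network
#'
#' The one-page hand calculation as a function: `(2 min(u, cap) - b) / 13`,
#' clipped below at 0 (and NA when the biomass demand itself is
#' unreachable). Used in tests as the closed-form cross-check of the LP.
#'
#' @param uptake available monosaccharide uptake magnitude (mmol/g DW/h)
#' @param cap committed-step cap (GK or KHK)
#' @param biomass_demand biomass flux
#' @param tag_cap upper bound on the TAG synthesis reaction
#' @return maximal TAG synthesis flux
#' @export
toy_tag_optimum <- function(uptake, cap, biomass_demand = 0.1, tag_cap = Inf) {
  vcommit <- pmin(uptake, cap)
  t_raw <- (2 * vcommit - biomass_demand) / 13
  if (2 * vcommit < biomass_demand) return(NA_real_)
  min(max(t_raw, 0), tag_cap)
}

#' Default monosaccharide transport kinetics for the toy model
#'
#' Vmax 5 (glucose) / 3.5 (fructose) mmol/g DW/h, Km 5 mM, and an
#' insulin modifier scaling Vmax by 1.25 while insulin is present —
#' magnitudes chosen so a 25 mM glucose medium is depleted on the ~20 h
#' timescale and fructose clears more slowly.
#'
#' @param sugar "glucose" or "fructose"
#' @param insulin_factor Vmax scaling while the insulin place is marked
#' @return a [kinetic_law()]
#' @export
toy_transport_law <- function(sugar = c("glucose", "fructose"),
                              insulin_factor = 1.25) {
  sugar <- match.arg(sugar)
  kinetic_law("michaelis_menten",
              Vmax = if (sugar == "glucose") 5 else 3.5, Km = 5,
              modifiers = list(list(place = "insulin",
                                    type = "scale_if_present",
                                    factor = insulin_factor)))
}

#' Assemble the toy dFVA protocol
#'
#' Wires the toy network to medium places via symmetric Michaelis-Menten
#' activity lists, adds the TAG accumulator, and fixes the biomass demand.
#'
#' @param sugar which monosaccharide the medium contains
#' @param conc initial medium concentration, mM (default 25)
#' @param insulin_nM insulin dose, nM (0 or 100 in the study design)
#' @param objective reaction to optimise (default "TAGS"; use "EX_glc" /
#'   "EX_fru" with `directions = "min"` for maximal uptake)
#' @param directions LP directions to simulate
#' @param dt,horizon stepping parameters (h)
#' @param biomass_demand biomass flux
#' @param units a [make_unit_context()]
#' @param model optionally a pre-built toy model (e.g. with a TAG cap)
#' @return a [dfva_protocol()]
#' @export
toy_dfva_protocol <- function(sugar = c("glucose", "fructose"), conc = 25,
                              insulin_nM = 0, objective = "TAGS",
                              directions = c("max", "min"),
                              dt = 0.1, horizon = 48, biomass_demand = 0.1,
                              units = make_unit_context(),
                              model = NULL) {
  sugar <- match.arg(sugar)
  if (is.null(model)) {
    model <- make_toy_hepatocyte_gsmn(biomass_demand = biomass_demand)
  }
  med_place <- if (sugar == "glucose") "glc_medium" else "fru_medium"
  ex <- if (sugar == "glucose") "EX_glc" else "EX_fru"
  other_ex <- if (sugar == "glucose") "EX_fru" else "EX_glc"
  acts <- list(
    activity_list(med_place, ex, law = toy_transport_law(sugar),
                  symmetric = TRUE),
    ## the absent sugar: no uptake, no release
    activity_list("zero", other_ex,
                  intervals = data.frame(lower = 0, upper = 0, lb = 0, ub = 0),
                  symmetric = FALSE))
  objectives <- data.frame(place = c(med_place, "tag_cell"),
                           reaction = c(ex, "TAGS"))
  coupling <- coupling_map(acts, objectives = objectives, units = units)
  marking <- c(conc, 0, 0, insulin_nM)
  names(marking) <- c(med_place, "zero", "tag_cell", "insulin")
  dfva_protocol(model, coupling, marking, objective,
                directions = directions, dt = dt, horizon = horizon,
                biomass_demand = biomass_demand)
}

#' Generate the toy regulome
#'
#' One agonist-activated transcription factor whose target genes gate the
#' TAG synthesis route: the returned metabolic model carries a basal cap
#' on `TAGS` below its unconstrained optimum, so increased TAG capability
#' strictly requires gene induction (level 2 doubles the cap, releasing
#' the full optimum). The Petri net holds a `treatment` token pool, the
#' TF gene motif activated by the treatment, target-gene motifs activated
#' by the TF, and a clearance transition consuming one token at a time;
#' with a handful of rule transitions, every trajectory statistic is
#' exactly enumerable.
#'
#' @param n_genes number of target genes (>= 1; gene 1 gates `TAGS`,
#'   further genes gate `DNL`, `GLY`, `PDH` with slack caps)
#' @param treatment_tokens size of the agonist token pool (default 8)
#' @param tag_cap_basal basal `TAGS` cap, below the unconstrained optimum
#' @param biomass_demand passed to the toy network
#' @return list with `net` (a [petri_net()]), `map` (gene/reaction/effect
#'   tibble), `model` (the capped toy [metabolic_model()]), `tf`,
#'   `treatment_place`, and `frozen = FALSE`
#' @export
make_toy_regulome <- function(n_genes = 1, treatment_tokens = 8,
                              tag_cap_basal = 0.4, biomass_demand = 0.1) {
  gateable <- c("TAGS", "DNL", "GLY", "PDH")
  if (n_genes < 1 || n_genes > length(gateable)) {
    stop("n_genes must be between 1 and ", length(gateable))
  }
  model <- make_toy_hepatocyte_gsmn(biomass_demand = biomass_demand,
                                    tag_cap = tag_cap_basal)
  ## slack caps on further gated routes (never binding at the toy optimum)
  if (n_genes >= 2) model <- set_bounds(model, data.frame(
    reaction = gateable[2:n_genes], lb = 0, ub = 25))
  treatment <- pn_place("treatment", kind = "treatment",
                        marking = treatment_tokens, discrete = TRUE,
                        level_range = c(0L, as.integer(treatment_tokens)),
                        units = "tokens")
  tf <- gene_motif("TF", activator = "treatment")
  genes <- paste0("g", seq_len(n_genes))
  motifs <- lapply(genes, gene_motif, activator = "TF")
  clear <- pn_transition("treatment_clear", "rule",
                         pn_arcs("treatment", 1, "consume"))
  net <- petri_net(
    c(list(treatment, tf$place), lapply(motifs, `[[`, "place")),
    c(tf$transitions, unlist(lapply(motifs, `[[`, "transitions"),
                             recursive = FALSE), list(clear)))
  map <- tibble::tibble(gene = genes, reaction = gateable[seq_len(n_genes)],
                        effect = "activates")
  structure(list(net = net, map = map, model = model, tf = "TF",
                 treatment_place = "treatment", frozen = FALSE),
            class = "regulome_model")
}

#' @export
print.regulome_model <- function(x, ...) {
  cat("<regulome_model> ", nrow(x$map), " gene(s) gating ",
      length(unique(x$map$reaction)), " reaction(s)",
      if (x$frozen) " [regulatory-naive: frozen at basal]", "\n", sep = "")
  invisible(x)
}

#' Parse a regulome table
#'
#' CSV or TSV (sniffed from the first line) with columns `gene_id`,
#' `reaction_id`, `effect` ("activates"/"represses"). Duplicated
#' (gene, reaction) pairs collapse to one entry with a warning; unknown
#' effect keywords or missing columns raise an error naming the line.
#'
#' @param path table file
#' @return tibble with columns `gene`, `reaction`, `effect`; the counts of
#'   distinct genes and reactions are reported via `message()`
#' @export
parse_regulome <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "reaction_id", "effect")
  if (!all(need %in% names(d))) {
    stop("regulome table missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), " in ", path)
  }
  bad <- which(!d$effect %in% c("activates", "represses"))
  if (length(bad)) {
    stop("unknown effect keyword '", d$effect[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  }
  key <- paste(d$gene_id, d$reaction_id)
  if (anyDuplicated(key)) {
    warning("dropped ", sum(duplicated(key)), " duplicate (gene, reaction) pair(s)")
    d <- d[!duplicated(key), ]
  }
  out <- tibble::tibble(gene = d$gene_id, reaction = d$reaction_id,
                        effect = d$effect)
  message(length(unique(out$gene)), " genes regulating ",
          length(unique(out$reaction)), " reactions")
  out
}

#' Simulate noisy monosaccharide depletion observations
#'
#' Integrates the Michaelis-Menten depletion model (closed form), scales
#' Vmax by `insulin_scale`, and adds independent Gaussian observation
#' noise truncated at zero — emulating assay error on medium
#' concentrations.
#'
#' @param Vmax maximal depletion rate, mM/h
#' @param Km half-saturation, mM
#' @param S0 initial concentration, mM
#' @param insulin_scale multiplicative Vmax factor (1 = no insulin)
#' @param noise_sd observation noise SD; interpreted as a fraction of the
#'   current signal when `relative = TRUE`
#' @param times increasing sampling times, hours
#' @param replicates number of replicate series
#' @param seed RNG seed
#' @param relative noise proportional to signal (default) or absolute (mM)
#' @return tibble with columns `time`, `replicate`, `concentration`
#' @export
simulate_uptake_observations <- function(Vmax, Km, S0 = 25, insulin_scale = 1,
                                         noise_sd = 0, times = seq(0, 48, by = 2),
                                         replicates = 1, seed = 1,
                                         relative = TRUE) {
  if (any(c(Vmax, Km, S0) < 0) || noise_sd < 0 || insulin_scale < 0) {
    stop("parameters must be non-negative")
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  truth <- mm_depletion(times, S0, Vmax * insulin_scale, Km)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(replicates), function(r) {
      sd_vec <- if (relative) noise_sd * truth else rep(noise_sd, length(truth))
      obs <- pmax(truth + stats::rnorm(length(truth), 0, sd_vec), 0)
      tibble::tibble(time = times, replicate = r, concentration = obs)
    })
  })
}
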