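# Shared fixtures built in code.

# Three-transition rule net: a token buffer, a gate, and an inhibitor-guarded
# drain — small enough that enabledness can be recomputed by hand per state.
toy_rule_net <- function() {
  petri_net(
    list(pn_place("buf", "treatment", marking = 2, discrete = TRUE,
                  level_range = c(0L, 5L)),
         pn_place("out", "treatment", marking = 0, discrete = TRUE,
                  level_range = c(0L, 5L)),
         pn_place("sig", "species", marking = 0)),
    list(pn_transition("move", "rule",
                       rbind(pn_arcs("buf", 1, "consume"),
                             pn_arcs("out", 1, "produce"))),
         pn_transition("drain", "rule", pn_arcs("out", 1, "consume"),
                       guard = pn_guard("sig", "absent")),
         pn_transition("gated", "rule", pn_arcs("buf", 1, "consume"),
                       guard = pn_guard("sig", "present"))))
}

# independent guard/arc oracle: re-evaluates enabledness from first principles
brute_force_enabled <- function(net, marking) {
  ok <- character(0)
  for (tr in net$transitions) {
    if (tr$mode != "rule") next
    holds <- TRUE
    for (g in tr$guard) {
      p <- net$places[[g$place]]
      pres <- if (p$discrete && p$kind == "gene") marking[[g$place]] == 2
              else marking[[g$place]] > 0
      v <- switch(g$test, present = pres, absent = !pres,
                  ge = marking[[g$place]] >= g$value,
                  le = marking[[g$place]] <= g$value,
                  eq = marking[[g$place]] == g$value)
      if (!v) holds <- FALSE
    }
    if (holds) {
      for (i in seq_len(nrow(tr$arcs))) {
        a <- tr$arcs[i, ]
        p <- net$places[[a$place]]
        v <- switch(a$kind,
                    consume = marking[[a$place]] >= a$weight,
                    test = marking[[a$place]] >= a$weight,
                    inhibit = marking[[a$place]] < a$weight,
                    produce = !p$discrete ||
                      marking[[a$place]] + a$weight <= p$level_range[2])
        if (!v) holds <- FALSE
      }
    }
    if (holds) ok <- c(ok, tr$id)
  }
  sort(ok)
}

glucose_only_toy <- function(conc = 25, biomass = 0.1, Vmax = 5, Km = 5) {
  m <- apply_biomass(make_toy_hepatocyte_gsmn(biomass_demand = biomass), biomass)
  u <- Vmax * conc / (Km + conc)
  set_bounds(m, data.frame(reaction = c("EX_glc", "EX_fru"),
                           lb = c(-u, 0), ub = c(u, 0)))
}

write_regulome_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
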