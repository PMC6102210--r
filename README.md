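# hepaflux

Hybrid Petri-net / flux-balance simulation of hepatocyte sugar and lipid
metabolism.

## The problem

Fatty liver begins as an imbalance between what hepatocytes take up
(glucose, fructose, fatty acids) and what they store as triacylglycerol
(TAG). Mechanistically this spans three layers: membrane transport with
Michaelis–Menten kinetics, the stoichiometry of central carbon and lipid
metabolism, and transcription-factor regulation (a PPARα-style regulome)
that rewires enzyme capacities in response to lipid loading. No single
formalism covers all three: the kinetics are quantitative, the
stoichiometry is a linear-programming problem, and the regulation is known
mostly as signed gene→reaction links with no rate constants.

`hepaflux` is for modellers who want to couple those layers without
inventing parameters they do not have. It implements a quasi-steady-state
Petri-net scheme: a Petri net carries continuous concentrations and
discrete three-level gene states (0 inhibited / 1 basal / 2 induced), and
the metabolic layer is re-solved per step as an LP whose flux bounds are
functions of the current marking.

Two pipelines:

* **Dynamic flux variability analysis (dFVA).** Per time step `dt`:
  transporter bounds from medium concentration via
  `v = Vmax·S/(Km+S)` (optionally insulin-scaled); FBA with the biomass
  demand fixed (`N·v = 0`, `lb ≤ v ≤ ub`); solved exchange fluxes
  integrated back into the medium (`ΔS = φ·v·Δt`). Run once maximising
  and once minimising the objective, the two trajectories bound the
  feasible envelope of, e.g., TAG production or sugar uptake.
* **Qualitative Monte Carlo.** Arbitrary-unit time; enabled regulatory
  transitions fire uniformly at random (seeded); gene levels gate
  reaction bounds (level 0 → closed, 2 → induced capacity); flux
  *capability* (FVA maximum) of monitored reactions is recorded per
  event. Ensembles give fraction-of-trajectories statistics with exact
  binomial confidence intervals, acute/reconstitutive phase detection,
  and a regulatory-naive control (all genes frozen basal).

Everything is testable offline: the package generates a ~20-reaction
hepatocyte-like toy network (glucose/fructose uptake, a capped committed
glycolytic step that fructolysis bypasses, lipogenesis, TAG synthesis,
biomass) whose optima are derived by hand — maximal TAG flux is
`(2·min(uptake, cap) − biomass)/13` — plus a toy regulome whose trajectory
statistics are exactly enumerable, and synthetic noisy uptake curves for
parameter-recovery studies. FBA runs on a bounded-variable simplex written
for the package and cross-checked against a brute-force vertex-enumeration
oracle; SBML (Level 3 + FBC) and a JSON Petri-net schema cover model I/O.

## Worked example

```r
library(hepaflux)

# 25 mM glucose, no insulin: TAG production envelope over 48 h
pr  <- toy_dfva_protocol("glucose", conc = 25, objective = "TAGS",
                         dt = 0.1, horizon = 48)
res <- run_dfva(pr)
glance(res)
#> # A tibble: 2 × 5
#>   direction flux_initial flux_final flux_auc n_infeasible
#>   <chr>            <dbl>      <dbl>    <dbl>        <int>
#> 1 max           6.33e- 1   1.83e- 4 7.21e+ 0          274
#> 2 min           2.31e-18   2.31e-18 3.47e-18            0
```

Maximal TAG synthesis starts at 0.633 mmol/g DW/h — exactly the hand
value `(2·(5·25/30) − 0.1)/13` for the toy's transport kinetics, committed
step and biomass demand — and decays as the medium is depleted (the 274
`infeasible` steps are the post-exhaustion tail, where the biomass demand
can no longer be met and flux is simply absent). The minimisation
direction produces no TAG at all: the lower envelope is identically zero.
`tidy(res)` returns the full trajectory (time, direction, flux, medium
glucose, accumulated TAG) and `autoplot(res)` draws the envelope.

```r
# regulatory response to an agonist pulse, competent vs naive
reg <- make_toy_regulome()            # TF + target gene gating TAG synthesis
mod <- apply_biomass(reg$model)
cpl <- coupling_map(genes = as.data.frame(reg$map))
ens <- run_ensemble(mod, cpl, reg, n = 100, master_seed = 1)
fraction_increased_flux(ens, "TAGS")
#> <fraction_statistic> TAGS: 0.99 (n = 100, 95% CI 0.946-1)

naive <- make_regulatory_naive(reg)
fraction_increased_flux(run_ensemble(mod, cpl, naive, n = 100,
                                     master_seed = 1), "TAGS")
#> <fraction_statistic> TAGS: 0 (n = 100, 95% CI 0-0.0362)

enumerate_success_probability(reg)    # exact value the 0.99 estimates
#> [1] 0.9882812
```

With regulation intact, essentially every trajectory gains TAG synthesis
capability after treatment (the exact enumerated probability is 0.988);
with the regulome frozen at basal, none do — increased TAG flux is an
emergent property of regulation, not of substrate availability alone.

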