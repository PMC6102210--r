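---
title: "Methods: hybrid Petri-net / flux-balance simulation of hepatocyte metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid Petri-net / flux-balance simulation of hepatocyte metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

## The modelling problem

Hepatic steatosis — the accumulation of triacylglycerol (TAG) in lipid
droplets — emerges from the interplay of three layers that operate on very
different time scales and levels of knowledge: transport kinetics of
monosaccharides across the hepatocyte membrane (seconds to hours, well
parameterised), the genome-scale stoichiometry of central carbon and lipid
metabolism (time-invariant, structurally well known), and
transcription-factor-mediated regulation of enzyme expression (hours to
days, mostly known only as signed gene-to-reaction links). `hepaflux`
couples these layers with a quasi-steady-state Petri-net scheme: a Petri
net carries the kinetic and regulatory state, and at each event or time
step the metabolic layer is re-solved as a linear programme whose flux
bounds are functions of the current marking.

Two complementary pipelines share this machinery.

**Quantitative (dFVA).** Time advances in hours. The medium concentration
$S$ of a monosaccharide sets the transporter's flux bound through
Michaelis–Menten kinetics, $v_{\max}(S) = V_{\max} S / (K_m + S)$. Flux
balance analysis (FBA) then optimises one objective reaction — TAG
synthesis, or the sugar exchange itself — subject to the steady-state
constraint $N v = 0$, the bounds, and a fixed biomass demand. The solved
exchange flux is integrated back into the medium:
$\Delta S = \varphi\, v\, \Delta t$, with $\varphi$ the unit-context factor
converting specific flux (mmol/g DW/h) into a medium concentration change
(mM). *Dynamic flux variability analysis* runs this whole time-stepped
simulation twice, once maximising and once minimising the objective. The
two trajectories bound the feasible envelope; they are two genuinely
different dynamic states (a maximal-uptake run depletes the medium faster
than a minimal-uptake run), which is why the envelope cannot be produced
by a per-step min/max pair along a single trajectory.

**Qualitative (Monte Carlo).** Time is in arbitrary units and reflects
only the order of events. Gene expression is discrete with three stable
levels — 0 (inhibited), 1 (basal), 2 (induced) — changed by guarded rule
transitions: `induce` fires while an activator is present, `repress`
while an inhibitor is present, and `relax` transitions restore the basal
level once the regulator is withdrawn, so regulation is always
reversible. A trajectory repeatedly enumerates the enabled rule
transitions, draws one uniformly at random (seeded), fires it, and
records the *flux capability* of monitored reactions — the FVA maximum
under the current gene-gated bounds with the biomass demand fixed. An
ensemble of independent trajectories yields fraction-of-trajectories
statistics with exact (Clopper–Pearson) binomial confidence intervals.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `dt` | 0.1 | h | Step of the explicit-Euler / quasi-steady-state loop. The per-step LP dominates the error budget; trajectories at `dt` and `dt/10` agree to first order (tested). Config knob. |
| `horizon` | 48 | h | The cell-culture observation window the protocols emulate. |
| Glucose `Vmax`, `Km` | 5, 5 | mmol/g DW/h, mM | Transport saturates near physiological glucose; with the default unit context a 25 mM medium clears on the ~20 h time scale. |
| Fructose `Vmax`, `Km` | 3.5, 5 | mmol/g DW/h, mM | Slower than glucose; a 25 mM fructose medium is not fully cleared within 48 h. |
| Insulin factor | 1.25 | — | Multiplies transporter `Vmax` while insulin is present; matches the ~25% faster first-day sugar clearance seen under 100 nM insulin. |
| Unit context | 0.58 mL/10^6 cells, 300 pg DW/cell | | 0.58 mL is back-derived from the paired observation that removing 9.3 mM glucose corresponds to 0.97 mg per million cells; 300 pg is a literature-typical hepatocyte dry mass. Both config-overridable. |
| Biomass demand | 0.1 | mmol/g DW/h | Fixed maintenance constraint (never the LP objective). |
| Induction factor | 2 | — | Upper-bound scaling applied by an induced gene (level 2); level 0 scales to 0. The true fold change is unknown, so it is a config knob; the qualitative conclusions require only "more than basal". |
| Treatment tokens | 8 | tokens | Agonist pool consumed one token per clearance event. Eight tokens put the toy regulome deep in the responding regime (enumerated success probability 0.988) while keeping every statistic exactly enumerable. |
| Baseline window | 10 | steps | Debounce for declaring a return to baseline in arbitrary-unit time. |

## The desk-scale synthetic models

The package ships generators, not data files. `make_toy_hepatocyte_gsmn()`
builds a 19-reaction, 14-metabolite network carrying the biology that the
full hepatocyte reconstruction has at scale: glucose and fructose exchange
and transport, a capped committed glycolytic step (`GK`, the rate-limiting
step), a fructolysis route (`KHK`) that bypasses that cap, gluconeogenic
glucose export, respiration, de novo lipogenesis, cytosolic TAG synthesis
and a biomass demand. Its optima fit on one page: with uptake magnitude
$u$ and committed-step cap $c$, maximal TAG synthesis under biomass demand
$b$ is

$$T^\ast = \frac{2\,\min(u, c) - b}{13},$$

thirteen triose-equivalents per TAG (twelve through lipogenesis plus one
glycerol backbone); ATP is in surplus whenever the formula is positive.
The tests verify this hand formula, an independent LP oracle, and the
simplex agree.

`make_toy_regulome()` adds one agonist-activated transcription factor
whose target gene(s) gate the TAG route: the basal `TAGS` cap (0.4) sits
below the unconstrained optimum, and induction doubles it, so increased
TAG capability *requires* regulation — the construction that makes the
regulatory-naive contrast sharp (fraction 0 versus ~1). With a handful of
rule transitions, the probability of full induction is computed exactly by
enumerating the uniform-random firing process
(`enumerate_success_probability()`), and ensemble statistics are
calibrated against those exact values.

`simulate_uptake_observations()` integrates the Michaelis–Menten depletion
model in closed form via the Lambert-W function and adds independent
Gaussian observation noise truncated at zero — emulating plate-reader
error on medium concentrations, which is symmetric to good approximation.
What the generator does **not** emulate: medium renewal, cell growth and
death, osmotic effects, other carbon sources competing with the labelled
sugar, or correlated (batch) error across time points. Passing tests
therefore demonstrate correctness of the machinery under the stated
model, not predictive validity on any particular cell line.

## Numerical choices

* **LP solver.** FBA/FVA problems are solved by a dense bounded-variable
  two-phase simplex written for this package. Every pivot refactorises the
  basis (the problems are tiny, robustness beats speed), phase 1 exits the
  moment the artificials reach zero, variables pinned to a point
  (`lb == ub`) are never chosen to enter the basis (they cannot move, and
  excluding them removes a degenerate-cycling mode), and pricing falls
  back to Bland's rule if an iteration budget is exceeded. Tolerances:
  reduced-cost optimality 1e-9; the test suite asserts agreement with an
  independent vertex-enumeration oracle to 1e-6 on a thousand random
  networks.
* **Degeneracy.** Genome-scale (and even toy) FBA optima are rarely
  unique in the flux vector. The objective value is the contract;
  `solve_fba(detect_alt = TRUE)` probes for objective-preserving flux
  freedom by re-optimising a fixed asymmetric functional at the pinned
  optimum. Where a single flux number matters in the qualitative stage,
  the FVA maximum is used instead of any particular FBA vertex.
* **Integration.** Explicit Euler, `dt = 0.1` h. Negative concentrations
  arising from a step overdraft are clipped to zero with a warning.
* **Infeasible steps.** When substrate exhaustion makes the biomass
  demand unattainable, the step records `status = "infeasible"`, the
  objective flux is absent for that step, and the simulation continues —
  exhaustion should terminate flux, not the run.
* **Tie-breaking.** Every deterministic enumeration (enabled transitions,
  ordering of emitted bounds) is lexicographic by id.
* **Degenerate inputs.** A flat uptake time course (< 2% total drop) is
  flagged non-identifiable by `fit_mm()` and returns no estimates; an
  activity list whose intervals overlap, two constraint sources claiming
  one reaction, or a net referencing undeclared places are structural
  errors at construction time.

## Design choices where the design was genuinely open

* **"Symmetrical" activity lists.** The transport constraint places emit
  bounds $(-m, +m)$ with $m$ the kinetically possible rate at the current
  medium concentration: export back into the medium is capped at the same
  magnitude as uptake. This is the simplest reading consistent with
  predicted gluconeogenic glucose export under transport minimisation.
* **Direction semantics.** Exchange flux is positive for release and
  negative for uptake (the FBC convention). "Maximal uptake" is therefore
  the LP *minimum* of the exchange flux — an explicit direction flag in
  the protocol, never a sign convention hidden in the objective.
* **Biomass as constraint.** The biomass function is a fixed demand
  (`lb = ub = demand`), with the monitored reaction as the LP objective.
* **Product bookkeeping.** The TAG accumulator integrates the objective
  flux through the unit context without feeding back into the model: the
  quantity of interest is the production envelope, and the model carries
  no product-inhibition mechanism. Whether the accumulator shares the
  medium's conversion factor is a per-place `scale` column in the
  objectives table.
* **Scheduler.** Uniform random choice among enabled rule transitions.
  Nothing in the qualitative formalism fixes a rate; uniform choice is
  the minimal assumption and the scheduler is the one place randomness
  enters, so it is seeded and swap-friendly.
* **Flux snapshots as FVA maxima.** "Increased flux towards TAG" is read
  as a capability statement; the FVA maximum is robust to LP degeneracy
  where a single FBA vector is not. (Snapshots from FBA vectors would be
  well-defined only up to the solver's arbitrary vertex choice.)
* **Treatment as a token pool.** A finite agonist pool consumed by
  clearance transitions gives "treatment cleared" a precise, enumerable
  meaning and lets the acute phase end stochastically, interleaved with
  the regulatory response.
* **Heatmap matrix.** One column per event (the pre-treatment state is
  the baseline, not a column), signed fluxes, positive rendered green and
  negative red, simulated time left to right.

## Problem sizes used by the shipped tests and scripts

The default verification runs use: 1000 random networks of at most 8
reactions for the solver-versus-oracle check; the 19-reaction toy network
over a 48 h horizon at `dt = 0.1` (≤ 960 LP solves per direction, ~2 s
per direction); 50 replicate fits of 25-point synthetic depletion curves
at 2% noise; ensembles of 100 trajectories for the naive/competent
contrast and 100 repeated ensembles of 1000 trajectories for statistic
calibration (flux capabilities are memoised on the gene-level state, so
an ensemble of 1000 costs about two seconds). These sizes are the
package's own documented study conditions.

## Known limitations

* The quantitative stage's full-scale counterpart (a curated hepatocyte
  genome-scale model with medium and kinetic-cap tables) is consumed via
  the SBML reader and the TSV bounds-override container, but is not
  bundled; the shipped numbers are for the toy models.
* The SBML reader covers the constraint-based subset (species, reactions,
  stoichiometry, FBC bounds) and classifies kinetic laws from their
  parameter signatures (`Vmax`/`Km`, `k`, `rate`); arbitrary MathML rate
  laws are reported as unparseable rather than interpreted.
* Arbitrary-unit regulatory time cannot say how long the reconstitutive
  phase lasts in hours, only that it exists and in what order events
  occur.
* Single transcription factor; no crosstalk between regulators, no
  protein-turnover kinetics.
* The exact-enumeration utility assumes the rule layer's reachable state
  graph is finite and acyclic in the direction of progress (true for the
  shipped motifs, where induction is blocked once the regulator is gone).
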