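---
title: "Methods: enzyme-constrained metabolic modeling with ecgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-constrained metabolic modeling with ecgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgem)
```

## The modeling problem

A genome-scale metabolic model (GEM) represents an organism's metabolism
as a stoichiometric matrix $S$ over reactions with flux bounds and
gene–protein–reaction (GPR) rules. Flux balance analysis (FBA) predicts
growth by maximizing flux through a biomass reaction at steady state
($Sv = 0$). Plain FBA ignores the cost of expressing the catalysts; for
many organisms this produces qualitatively wrong responses to nutrient
availability, because any uptake increase translates into growth
regardless of how much enzyme would be needed to process it.

`ecgem` implements an enzyme-constrained extension in the MOMENT/GECKO
family. Each enzymatic reaction $i$ is capped by the abundance of the
catalyzing enzyme times its turnover number,
$v_i \le E^r_i\,k_{cat,i}$, enzymes compete for a total protein budget
$\sum_k E^g_k\,\mathrm{MW}_k \le C$ (molecular crowding), and a
promiscuity constraint splits each gene's abundance across all reactions
it catalyzes: $\sum_{i \in GPR_k} E^r_{k,i} = E^g_k$. Binary indicators
$y_k$ with $\alpha y_k \le E^g_k \le \beta y_k$ mark genes as expressed
and impose a minimum abundance on expressed genes. GPR rules enter
recursively: a complex (`and`) is bounded by each subunit's allocation, an
isozyme set (`or`) by the sum of the alternatives. The result is a
mixed-integer linear program solved with GLPK.

The key assumptions inherited from this model family: enzyme turnover
numbers measured *in vitro* (and often in other organisms) bound *in
vivo* capacity; the entire measured protein content is available to
metabolic enzymes (no unmodeled-proteome discount); complex subunits are
required in 1:1 stoichiometry; and, where transcripts proxy for proteins,
transcript and protein abundance are proportional.

## Parameters that matter

* `C` — total protein content, g gDW⁻¹. The crowding budget and, via
  biomass rescaling, the protein fraction of biomass. Typical fungal
  measurements span roughly 0.05–0.12; the structure-comparison default is
  0.106 (a maximum measured content). Growth is nondecreasing in `C`
  (property-tested).
* `alpha`, `beta` — minimum/maximum abundance of an expressed gene, mmol
  gDW⁻¹; defaults `1e-10` and `1`. `alpha` exists to give "expressed" a
  numerical meaning; see the numerics section for how the default is
  handled.
* `kcat` values — h⁻¹ after the ×3600 conversion from table units (s⁻¹).
  Assignment rules (maximum over candidates; substrate, then lineage
  filter, each applied only when non-emptying; EC pruning 4→3→2→1; median
  fallback) are exercised one-by-one by the planted table from
  `generate_kcat_table()`.
* `Vmax`, `Km` — transporter kinetics (mmol gDW⁻¹ h⁻¹; mM) turning
  concentrations into uptake bounds; at `[S] = Km` the bound is `Vmax/2`.
* `fraction` — growth floor for variability and sampling; 0.99 for
  enzyme-abundance and structure-flux work, 0.9 for subsystem ranges and
  coupling classes (the conventions of the analyses they feed).
* Differential-call thresholds — 0.6, 0.7, 0.8 on the symmetric effect
  size `max(A_w, 1-A_w)`; calls at stricter thresholds are nested within
  looser ones by construction.

## Design choices where the field leaves room

* **GPR syntax.** `and` binds tighter than `or`, parentheses override —
  the common SBML-fbc reading. Operators are case-insensitive.
* **Filter order in kcat matching.** Substrate filtering precedes lineage
  filtering; both are skipped when they would empty the candidate set, so
  the cascade can never lose a match it already had. Pruning stops at the
  EC class level; queries with no class-level match fall back to the
  median.
* **Distance norm in sampling.** The projection of a random target onto
  the feasible region uses the L1 norm, which keeps every sampling step a
  linear program. No quadratic (L2) variant is offered because the solver
  backend is purely linear.
* **Direction handling in differential calls.** "Differentially
  activated" is direction-agnostic, so calls use
  `max(A_w, 1-A_w) >= threshold`.
* **Splitting and media.** `split_reversible()` always gives exchange
  reactions a reverse (uptake) copy, even when currently closed; a closed
  copy has bounds `[0, 0]` and changes nothing, but it lets
  `apply_medium()` re-open uptakes on an already split model — the
  condition panel relies on this. Uptake is negative flux externally and
  the positive reverse copy internally.
* **Net-flux reporting in the structure comparison.** Flux sampling runs
  on the split model, but effect sizes are computed on net fluxes per
  original reaction. Split forward/reverse pairs can carry arbitrary
  simultaneous flux (a pure bookkeeping artifact); netting removes this
  inflation while leaving genuinely irreversible reactions untouched.
* **Boundary detection.** Exchanges are single-metabolite reactions whose
  metabolite is extracellular (compartment `"e"` when declared); other
  single-metabolite reactions are sinks/demands, as are reactions with a
  configurable id prefix (`sink_`, `DM_`).

## Numerical choices

* **Solver.** All LPs and MILPs go through GLPK (simplex, then
  branch-and-cut for integer problems) with automatic problem scaling and
  GLPK's default tolerances. A 180 s time limit makes a pathological MILP
  fail loudly rather than hang.
* **Conditioning by variable substitution.** Turnover numbers span orders
  of magnitude (up to ~1e5 h⁻¹ here; far more in real tables). Allocation
  and GPR-node variables are therefore held in flux-capacity units
  ($k_{cat}$ × abundance): capacity rows then carry unit coefficients and
  $k_{cat}$ enters only as $1/k_{cat}$ in the gene-total rows. The
  indicator big-M uses the implied bound
  $\min(\beta, C/\mathrm{MW}_k)$, which is equivalent (crowding already
  caps each abundance) but keeps the coefficient on the scale of the
  abundances.
* **The indicator layer at the default `alpha`.** With
  $\alpha = 10^{-10}$ the indicators cannot move any abundance or flux by
  more than $10^{-10}$ — four orders of magnitude below the $10^{-6}$
  feasibility tolerance every solution is audited against — while their
  $10^{-10}$-scale coefficients destabilize the simplex and make
  branch-and-cut degenerate (every $y$ micro-fractional at equal
  objective). For $\alpha \le 10^{-8}$ the indicator rows are therefore
  kept out of the matrix and $y$ is recovered from the abundance support;
  for larger $\alpha$ the true MILP is built and solved, and it is this
  path that is verified against exhaustive enumeration over all $2^g$
  indicator assignments on random toys.
* **Audits.** Every optimal solution is checked post hoc: steady-state
  residual, bounds, enzyme capacities, crowding and indicator coupling
  within $10^{-6}$. Sampled rows failing to solve are recorded and
  skipped, with the count reported.
* **Degenerate inputs.** Empty media close all uptakes; zero protein
  budgets yield zero growth; point variability ranges make every sample
  identical; zero-total transcript counts and missing molecular weights
  are errors naming the offending genes.

## What the synthetic generators emulate — and what they do not

`generate_toy_model()` builds a three-compartment network (extracellular,
cytosol, peroxisome) with the structural features the pipeline must
handle: isozyme pairs, an enzyme complex, a promiscuous gene, an
obligatory lipid (palmitate-like) uptake without which growth is
impossible, a peroxisomal β-oxidation branch fed by a myristate-like
substrate, a decoupled byproduct pathway with its own substrate, subsystem
labels, and a biomass whose coefficient×MW sum is 1 g gDW⁻¹. The network
is a tree once the ATP balance is eliminated, so its optimum has a closed
form that the LP must reproduce to 1e-9 at generation time — the ground
truth is computed independently of the solver. Seeded parameters vary the
respiratory ATP yield, biomass ATP demand and gene molecular weights.

`generate_condition_design()` emulates a 4-sugar × 3-concentration feeding
experiment with Michaelis–Menten uptake kinetics, per-condition protein
contents, and a planted "dry weight" defined as a fixed strictly monotone
transform of the enzyme-constrained growth prediction; a correct pipeline
therefore recovers Spearman ρ = 1. `generate_structure_transcripts()`
emulates averaged counts for three developmental structures, multiplying
the genes of planted reactions by `fold` (and its square root in the
intermediate structure) under multiplicative lognormal noise
(default sd 0.1). Baseline counts are constructed so that non-planted
reactions keep ample capacity margin: their bounds never bind, so count
noise does not move their flux distributions, and recovery tests can
demand zero false calls.

These generators validate the machinery, not the biology: real GEMs have
thousands of reactions with extensive alternate optima, kcat tables are
noisy and biased toward model organisms, real transcript noise is not
lognormal with known σ, and real protein allocation includes a large
unmodeled proteome. Passing the synthetic recovery tests shows the
pipeline is internally correct, not that its predictions for a given
organism are accurate.

## Problem sizes used in the tests

The packaged experiments run at deliberately small scale: toy models of
~30 reactions and ~21 genes, MILP enumeration toys with ≤8 genes (so all
indicator assignments can be enumerated), 100-row sampling audits, and
500-point flux sampling for the recovery analysis. The algorithms are
size-independent; these sizes keep every oracle exhaustive and every run
reproducible in seconds.

## Known limitations

* GLPK offers no quadratic objectives, so only L1 sampling projections are
  available.
* `detect_sbc()` reports cycles on the unsplit model; on a split model the
  forward/reverse copies of every reversible reaction form trivial
  two-cycles that would be reported too.
* SBML support covers Level 3 with the fbc (v2) and groups packages and
  MIRIAM `ec-code` annotations — the subset needed for constraint-based
  models — not the full SBML standard (no kinetic laws, rules, or events).
* The condition panel assumes a single varying carbon source per condition
  on top of a fixed base medium.
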