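# ecgem — enzyme-constrained genome-scale metabolic modeling

`ecgem` analyzes genome-scale metabolic models (GEMs) under enzyme
constraints. It is aimed at modelers of organisms — such as arbuscular
mycorrhizal fungi — for which no proteomics data exist, so that enzyme
capacities must be assembled from EC-number-indexed turnover tables and,
for *in vivo* conditions, from transcript abundances. The package covers
the full path from an SBML (fbc) model to condition-specific growth
predictions, enzyme-abundance sampling, and differential-flux calls
between developmental structures.

## What it computes

**Classical constraint-based analyses.** Flux balance analysis (FBA),
parsimonious FBA, flux variability analysis (FVA), blocked-reaction and
stoichiometrically-balanced-cycle detection, reaction coupling classes
(hard / soft / partial / uncoupled), subsystem flux-sum ranges, ATP
production scans, and EC-overlap comparison of models by Jaccard index.

**Turnover-number assignment.** Each enzymatic reaction receives a kcat
from a table of records (EC number, substrate, lineage, value in s⁻¹):
full-EC matches are filtered for substrate and fungal-lineage agreement
(each filter only when non-emptying), the maximum surviving value wins,
unmatched ECs are retried at pruned EC levels (4→3→2→1), and reactions
that match nothing receive the median of all matched values. Values are
converted to h⁻¹ (×3600).

**The enzyme-allocation MILP.** Growth is maximized subject to

```
max  v_bio
s.t. S v = 0
     0 ≤ v_i ≤ E_i^r · kcat_i              (enzyme capacity, per reaction)
     Σ_{i ∈ GPR_k} E_{k,i}^r = E_k^g       (promiscuity: a gene's abundance
                                            is split across its reactions)
     Σ_k E_k^g · MW_k ≤ C                  (molecular crowding)
     α y_k ≤ E_k^g ≤ β y_k,  y_k ∈ {0,1}   (expression indicators)
```

with GPR rules applied recursively (complexes: capacity bounded by each
subunit; isozymes: by the sum of alternatives). Michaelis–Menten
transporter kinetics convert substrate concentrations into uptake bounds
(`v = Vmax·[S]/(Km+[S])`), and the biomass reaction is rescaled so the
protein component equals the measured protein content `C` while total
biomass mass stays 1 g gDW⁻¹. Feasible enzyme abundances and steady-state
fluxes are sampled by L1-projection of random points onto the feasible
region at ≥99% of optimal growth.

**Transcript-bounded structures.** Relative transcript counts become
protein equivalents (`tc^p = tc′·C/MW`), GPR rules map them onto reactions
(min over complex subunits, max over isozymes), and `v_i ≤ kcat_i·tc^r_i`
bounds each reaction. Sampled flux distributions of two structures are
compared per reaction with the common-language effect size
`A_w = (#(p>q) + 0.5·#(p=q))/(n₁n₂)`; reactions with
`max(A_w, 1−A_w)` above 0.6/0.7/0.8 are called differentially activated.

All linear and mixed-integer programs are solved with GLPK through a small
C interface in `src/`.

## Worked example

Every pipeline stage can be exercised on a seeded synthetic toy model with
analytically known optima:

```r
library(ecgem)
toy <- generate_toy_model(seed = 1)
toy$model
#> metabolic_model 'toygem_seed1': 29 reactions, 21 metabolites, 21 genes
#>   compartments: e, c, p
#>   GPR coverage: 62.1%; exchanges: 8; biomass: BIO

fba(toy$model)$objective_value      # 8.5837, equals the closed form
toy$ground_truth$growth             # 8.5837

assign_kcats(toy$model_split, toy$kcat_table)
#>  reaction kcat_per_h      provenance
#>       AAS      18000  pruned-level-1
#>       BOX      10800  pruned-level-1
#>       BYP      12600 median-fallback
#>      CARB       3600      full-match
#>     GLY_1      18000      full-match
#>  ...

prob <- build_emoment(toy$model_split, toy$enz)
solve_emoment(prob)$growth          # 2.6854 at C = 0.106 g/gDW
```

The growth drop from 8.58 h⁻¹ (FBA) to 2.69 h⁻¹ shows the molecular
crowding constraint binding: the protein budget cannot support the
uptake-limited optimum. On the synthetic 12-condition feeding design
(4 sugars × 3 concentrations), enzyme constraints reverse the qualitative
behaviour of plain FBA at high carbon:

```r
design <- generate_condition_design(toy, seed = 1)
panel <- simulate_condition_panel(toy$model_split, toy$enz,
                                  design$conditions, design$base_medium)
#>  condition uptake_bound growth_fba growth_emoment
#>     glc_10        0.541      0.574          0.574
#>    glc_100        2.297      2.499          1.695
#>   glc_1000        3.399      3.672          1.998
cor(panel$growth_emoment, design$dry_weight, method = "spearman")  # 1
```

At 10 mM the transporter limits growth and both methods agree; at higher
concentrations the enzyme budget caps growth well below the FBA value.
The rank correlation of 1 against the design's planted dry weight confirms
that the pipeline recovers the generator's ground truth exactly.

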