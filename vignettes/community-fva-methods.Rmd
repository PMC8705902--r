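---
title: "Community FVA: model conventions, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community FVA: model conventions, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcomm)
```

## The model

`fluxcomm` treats a gut community at one sampling time as a single
stoichiometric model at steady state. Each strain keeps its own private
compartments (its cytosol and a renamed extracellular space); a shared
lumen `[u]` mediates all cross-feeding; a diet layer `[d]` supplies
nutrients and a fecal layer `[fe]` drains secretions. Flux balance
analysis maximises an objective flux subject to `S v = 0` and bounds;
flux variability analysis (FVA) reports, per reaction, the LP minimum and
maximum of its flux while the objective is held at a fraction `gamma` of
its optimum.

Three conventions matter and are worth stating precisely.

**Abundance enters twice.** The community biomass reaction consumes each
strain's biomass metabolite with its filtered relative abundance `a_k` as
the stoichiometric coefficient, so `v_bio,k = a_k * v_community` by mass
balance. Independently, every strain reaction is coupled to that strain's
biomass flux by two inequality rows, `v - c*v_bio <= u` and
`-v - c*v_bio <= u`. A rare strain therefore has a small metabolic
ceiling even when its substrate is abundant, and a strain with zero
biomass flux is silenced entirely (up to the slack `u`). With the default
community biomass bounds the attainable secretion ceiling of a sole
producer is `cap = c * a_k * v_max + u`, which is the closed form the
synthetic oracle uses.

**Net flux signs.** Diet exchanges satisfy `lb = -flux, ub = 0` (uptake
is negative flux); fecal exchanges are nonnegative. The four FVA
primitives per metabolite are reduced to

```
net_secretion = maxFlux(EX_m[fe]) + minFlux(EX_m[d])
net_uptake    = |minFlux(EX_m[d])| - minFlux(EX_m[fe])
```

The verbal rule "net secretion is maximal secretion plus minimal uptake"
does not fix signs, and the two readings of "minimal uptake" (least or
most negative diet flux) differ. We chose the reading in which a pure
passthrough metabolite — supplied by the diet, touched by nobody — nets
to exactly zero in both directions, which the other reading does not
satisfy; all four primitives are kept in every output table so the
alternative can be reconstructed.

**Strain attribution.** A strain's individual secretion of metabolite m
is the flux of its IEX transport (strain compartment to lumen, secretion
positive). Contribution shares divide each positive FVA maximum by the
sum of positive maxima. Individual maxima are super-additive relative to
the community maximum (each is attained in a different flux state), so
shares describe attainable capacity, not a simultaneous flux split.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `cutoff` | 0.001 | fraction | strains below 0.1% relative abundance are dropped, the rest renormalised; applied to raw abundances, boundary values retained |
| `coupling_c` | 400 | – | coupling factor tying reaction flux to strain biomass |
| `coupling_u` | 0.01 | mmol/day | coupling slack; keeps zero-growth strains from being exactly frozen |
| `biomass_bounds` | [0.4, 1] | 1/day | community biomass flux window |
| `gamma` | 0.9999 | fraction | FVA objective fraction; `gamma = 0` gives unconstrained ranges |
| `big_bound` | 10000 | mmol/day | bound on otherwise-unconstrained community transports |
| `r_thresh`, `p_thresh` | 0.7, 0.1 | – | network thresholds: &#124;rho&#124; > 0.7 and FDR-adjusted p < 0.1, strict |
| `supplement_eps` | 0.1 | mmol/day | trace flux for supplemented micronutrients |

The coupling parameters, `gamma` and the biomass window follow the common
community-modelling toolbox conventions so that outputs remain comparable
with MATLAB-based pipelines; none of them is derived from data, and all
are per-run configurable through `community_config()`.

Units: strain models keep their native mmol/gDW/h bounds; the community
exchange layer is interpreted in mmol/day. The package records this as
model metadata and applies no silent conversion — diet inputs must already
be in mmol/day (as `compose_flux()` produces).

## Statistics

`spearman()` computes rho as the Pearson correlation of average ranks and
a two-sided p from `t = rho*sqrt((n-2)/(1-rho^2))` on `n-2` df — the
convention of the usual correlation-matrix tools, which at n = 7 and
rho = 0.893 gives p = 0.0068. Because n is tiny, an exact option
enumerates all n! permutations (n <= 9); at n = 7 that is 5040
permutations and gives p = 0.0123 for the same rho, roughly double the
t-approximation. Both are available; the t-approximation is the default
and both raw and FDR-adjusted p-values are always emitted.
`fdr_bh()` implements Benjamini–Hochberg step-up adjustment over the full
metabolite-by-clinical pair family (the family is not restricted to
"interesting" rows, which would inflate discoveries).

The rho values attainable at n timepoints form the discrete lattice
`1 - 6S/(n(n^2-1))` with S an even integer; the clinical generator plants
correlations exactly on this lattice (requests off the lattice snap to
the nearest attainable value with a warning).

## The LP engine and its oracle

No LP solver is assumed from the environment: the package carries a
bounded-variable primal simplex (Phase I artificials; Dantzig pricing
with a Bland's-rule fallback for degeneracy; product-form basis-inverse
updates with periodic refactorisation; feasibility/optimality tolerance
1e-9, contract tolerance 1e-6 on fluxes). FVA solves share one prepared
problem and warm-start from the previous optimal basis, which is what
makes per-sample profiling cheap.

The validation oracle is a genuinely separate algorithm: exhaustive
enumeration of the basic solutions of `{A x = b, lb <= x <= ub}` (choose
a column basis, pin the nonbasic variables at bounds, solve the square
system, filter by feasibility). On polytopes with finite bounds the LP
optimum is attained at such a point, so the enumeration is exact; it is
exponential and used only on small random models. The acceptance suite
compares every FVA bound on 100 random models against it at 1e-6.

## What the synthetic scenario does and does not emulate

`generate_scenario()` encodes the shape of a single-subject, 7-timepoint
(days 0–105) high-fiber intervention: a folate-producer strain rising
0.02 → 0.30, a branched-chain-ketoacid producer falling 0.30 → 0.02, a
substrate competitor near 10%, a dominant riser (18% → 36%) that skews
the community so Shannon diversity falls over the intervention, one
strain pinned at 0.05% to exercise the cutoff filter, inert fillers, a
diet held constant across timepoints, and clinical series (BMI declining
from 49.47, leptin 63.8 → 34.5, adiponectin 2.17 → 5.39) planted at
rank correlation ±25/28 against the folate producer's trajectory. The
sub-cutoff strain is held constant so the renormalisation factor is
identical at every timepoint and planted ranks survive filtering exactly.

Toy strains are linear chains (substrate → product at a fixed yield, with
growth on a separate substrate), which is what makes the closed-form
oracle `analytic_net_secretion()` possible:
`min(y * min(supply, cap), cap)` for products, zero for passthroughs, and
`-(sum_k a_k d_k) * gamma * v_max` for the growth substrate. Real GEMs
have branched, looped networks, alternative optima, and metabolites that
are simultaneously consumed and produced by the same strain; passing the
synthetic suite therefore validates the *machinery* (assembly, coupling,
FVA, attribution, statistics), not the biology of any particular model
collection. Real-data headline numbers (hundreds of metabolites, strain
rosters, mmol/day totals) depend on the model collection, the read
mapping and the measured diet, and are out of the package's control.

Problem sizes were chosen to keep every validation exhaustive or
near-exhaustive while each check stays in seconds-to-a-minute territory:
10 strains x 7 timepoints for the default scenario, 5 strains x 20 seeds
for the closed-form sweep, 100 random models for the oracle comparison,
1000 draws for each statistics cross-check.

## Numerical choices and degenerate inputs

* LP tolerances: 1e-9 internally, 1e-6 on all flux contracts; mass
  balance `max |S v|` is asserted at 1e-6 on every optimal solution in
  the tests.
* FVA min/max pairs that cross by roundoff (< 1e-9) are swapped rather
  than reported inverted; only the values, not the flux vectors, are
  contractual (vertex tie-breaking is pivoting-order dependent).
* Inverted bounds, negative abundances, negative diet fluxes, coupling
  to missing anchors and malformed tables all fail fast with descriptive
  errors; infeasible communities report the likely cause (diet supply vs
  the community biomass lower bound).
* An all-below-cutoff sample is an error ("empty community"), not an
  empty model; a model without exchange reactions yields an empty FVA
  table with a warning.
* Filtering is exactly idempotent: profiles already summing to 1 within
  1e-12 are not renormalised again.
* All iteration orders are lexicographic and every output table is
  written with fixed formatting, so reruns are byte-identical; the run
  manifest records config, seed, versions and all collected warnings,
  and deliberately no timestamps.

## Design decisions

* The abundance cutoff retains boundary values (>= rather than >): the
  filter rule is stated as "above 0.1%" in common pipelines without
  specifying the boundary; retaining it is the inclusive reading and is
  logged per sample either way.
* Strain-level exchanges are replaced by IEX transports into one shared
  lumen pool (the standard community-joining choice); a per-strain
  private-pool variant is out of scope.
* The contribution-share denominator uses positive maxima only, so
  shares are in [0, 1] and sum to 1 over producers.
* Strains may in principle enter the correlation screen as features, but
  by default they enter the network only through production edges;
  correlation edges connect clinical parameters and metabolites.
* The host (human) compartment, dynamic FBA, thermodynamic constraints
  and gap-filling are non-goals.

## Known limitations

* The simplex is dense and in pure R: adequate for toy-to-moderate
  models (hundreds of reactions), not tuned for full-size GEM
  collections with tens of thousands of reactions.
* The SBML subset covers species, compartments, fbc bounds/objectives
  and SBO-tagged reaction kinds; couplings only exist in the JSON
  dialect, and writing a coupled model to SBML errors unless couplings
  are explicitly stripped.
* Shares describe attainable (FVA-maximal) production, not realised
  fluxes; super-additivity across strains is expected and documented.
* The t-approximation p-value is anti-conservative at n = 7 relative to
  the exact permutation p; it is kept as the default for comparability
  with the field's standard tooling, and the exact option exists for
  sensitivity analyses.
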