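---
title: "Inconsistency and metabolic coherence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inconsistency and metabolic coherence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcoher)
```

## The two scores

metcoher compares two ways of asking whether a transcriptome profile
"agrees" with a metabolic network.

**Inconsistency (I).** Expression is mapped to reactions through
gene–protein–reaction rules with `and → min` and `or → max`, then
thresholded at *t* (log-signal units): a reaction whose mapped value
falls below *t* is *absent* with deficit weight `w = t − x`; reactions
without any rule are assumed expressed. Flux balance analysis first
finds the maximum achievable objective flux `v_max` under the growth
medium; the inconsistency LP then minimises the deficit-weighted total
flux through absent reactions subject to steady state, the flux bounds,
and `v_obj ≥ l · v_max`. The optimum is *I*; it is zero exactly when the
objective level can be met using present reactions alone, and its
decomposition over the absent reactions that still carry flux — the
inconsistency vector — names the culprits. A uniform-weight mode
(`weight_mode = "uniform"`, every absent reaction weighted 1, the plain
"sum of fluxes" reading) is available; the deficit-weighted score is the
primary output and both are reported in each result.

**Metabolic coherence (MC).** The model is projected onto an undirected
gene network: reactions are adjacent when they share a non-excluded
metabolite, genes are adjacent when they occur in the same or adjacent
reactions. Before projection, the top 4% of metabolites by
reaction-degree are removed *per compartment* (currency metabolites:
ATP, water, protons, ...), with ties broken by id so the cut is
deterministic. For a sample, the genes above *t* induce a subgraph; its
connected-node ratio C (nodes with at least one neighbour inside the
subset, over subset size) is compared against `N` uniformly drawn node
subsets of the same size: `MC = (C − μ)/σ`, with σ the population (1/N)
standard deviation of the null ratios. MC is a z-score: how much more
coherent the expressed gene set is than chance.

The two scores answer related questions from opposite directions — I
needs the full constraint-based machinery (objective, medium, bounds),
MC only the wiring — and across a cohort they anticorrelate: samples
whose expressed genes form connected pathway structure rarely force flux
through unexpressed reactions.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `t` | 2 | log-signal | presence threshold; ties resolve to present |
| `l` | 0.8 | (0, 1] | required fraction of the FBA optimum |
| `weight_mode` | deficit | — | penalty per absent reaction: `t − x` or 1 |
| `N` (null size) | 1000 | draws | MC null sample; exact enumeration replaces it in tests |
| currency fraction | 0.04 | per compartment | degree cut before projection |
| `eps_flux` | 1e-6 | flux | "carries flux" call for vectors and usage |
| uptake bounds | −10 carbon, −1 other | mmol/gDW/h | reference-medium convention, config-exposed |

Random media draw a fraction `f ~ U(0.04, 1)` of the exchange reactions
(the lower end matching the share of exchanges a minimal reference
medium enables), give each selected exchange `lb ~ U(−20, 0)`,
`ub ~ U(0, 20)`, and keep oxygen, protons, sulfate, phosphate and water
open (lb −1000) in every draw. Normalised inconsistency `I / v_obj` is
used whenever media vary, raw `I` otherwise.

## Numerical choices

* **LP engine.** FBA and the inconsistency LP run on a built-in
  two-phase revised simplex with bounded variables (variables may sit at
  either bound; a ratio-test limit at the entering variable's opposite
  bound flips it without a pivot). Reversible reactions are split into
  forward/backward parts so `|v|` penalties are linear; the split is a
  bijection on flux spaces and provably preserves FBA optima. Pivot
  tolerance 1e-9, Dantzig pricing with a Bland fallback against cycling,
  periodic refactorisation of the basis inverse. After phase 1,
  artificial variables are pinned to zero so degenerate bases cannot
  drift infeasible. The solver is cross-checked in the test-suite
  against an independent implementation and against exhaustive vertex
  enumeration on small instances.
* **Infinite bounds** are encoded as ±1000 flux units — the usual COBRA
  convention; every LP stays bounded.
* **Degeneracy.** `v_max = 0` makes the inconsistency undefined: the
  engine raises a typed error and cohort-level code excludes the sample
  (counts are reported). A point-mass MC null (σ = 0) yields MC = 0 with
  a degenerate flag. Boundary expression ties (`x = t`) are present —
  one deterministic convention rather than a coin flip.
* **Ties** in the currency-degree cut and in group assignment
  (I exactly at the control mean goes to HIG) are fixed conventions,
  chosen for reproducibility; both sit on measure-zero events for
  continuous data.

## The synthetic study

`generate_toy_model()` builds a three-compartment network (extracellular,
cytosol, mitochondrion; ~65 reactions at defaults) with glucose/glycerol
carbon uptake, a cytosolic chain, a mitochondrial leg, and a terminal
synthase that condenses a precursor with acetyl-CoA into the objective
metabolite. The synthase co-produces a dead-end by-product that blocks
all steady-state objective flux until an artificial drain is added —
reproducing the mechanism by which a single dead-end metabolite can
silently disable a genome-scale objective pathway.

Planted features carry the ground truth the test-suite asserts against:

* a *just-below-threshold* gene on the main chain (absent in every
  sample, median expression within 0.5 log-units of *t*): an unspecific
  contributor and the JBT/CD marker fixture;
* a penalised mitochondrial step whose parallel three-gene *energy
  pathway* is expressed only in LIG-like samples — LIG therefore pays
  less inconsistency (the elevated-energy-metabolism signature) and
  gains connected active genes;
* a capacity-limited, GPR-less bypass route (the invisible-path fixture);
* ATP/ADP cofactor hubs touching most core reactions, landing in the
  top-4% degree cut;
* pendant two-gene "salvage" modules with borderline expression in
  control and HIG: they carry no flux (so I is untouched) but often
  leave one active gene isolated, giving control samples genuinely
  intermediate coherence;
* decoy gene chains that are never expressed, so the MC null pool is not
  dominated by pathway genes.

The cohort (20 control, 20 LIG-like, 20 HIG-like at defaults) draws
present genes from Normal(3, 0.4) and absent genes from Normal(1, 0.4)
log-signal units with *t* = 2 between the modes — a bimodal histogram
with mode separation of 5σ. HIG samples push a per-sample random
fraction (U(0.65, 0.9)) of pathway genes below threshold. These defaults
were fixed once, as the package's definition of a realistic planted
study: at genome scale the LIG > control > HIG coherence gradient
emerges from network size alone, while at ~65 reactions it has to be
built into the topology (the energy pathway and salvage modules above).
Across seeds the defaults give Spearman ρ(MC, I) between about −0.6 and
−0.87, perfect group recovery, and a threshold-sweep minimum within 0.2
of the planted *t*.

What passing these tests shows — and what it does not. The generator
emulates the *structure* the analysis assumes: bimodal expression, a
reachable objective, planted coherent/incoherent groups, annotation
gaps. It does not emulate microarray noise models, cross-hybridisation,
genome-scale redundancy (thousands of reactions, isozyme families), or
biological covariates; recovering the planted structure validates the
machinery, not the biology of any particular dataset.

## Design choices where the design was open

* **GPR precedence**: `and` binds tighter than `or`, left-associative —
  the common COBRA convention; fully parenthesised (BIGG-style) rules
  are unaffected.
* **Unmeasured model genes** are imputed with the profile median (and
  logged): forcing them absent would manufacture inconsistency out of
  platform coverage.
* **Exchange detection**: single-metabolite stoichiometry or an `EX_`
  id prefix; artificial (`ART_`) drains are excluded, so media can never
  rebind an objective drain.
* **Objective constraint** is the inequality `v_obj ≥ l·v_max`, not an
  equality — the level is a floor to be met, not a target to hit.
* **Gene-network convention**: genes link across one reaction step
  (same or metabolite-adjacent reactions). A one-step convention keeps
  the projection local; the coherence machinery is not particularly
  sensitive to such choices because MC is always measured against the
  matched null of the same graph.
* **Marker thresholds** (`marker_defaults()`): the six topological
  markers operationalise verbal criteria, so every cutoff — absent
  fraction 0.95 and margin 0.5 for JBT, flanked-fraction 0.5 for CD,
  layer distance 2 for CIL/COL, GPR-less neighbour fraction 0.5 at
  radius 1 for IP, and the knockout test `FBA_max < l·v_max` for BN —
  is explicit and config-exposed rather than baked in. Exchange and
  artificial reactions do not count as "missing annotation" in the IP
  neighbourhood: they never carry rules by construction.
* **Specificity calls**: unspecific = strength ≥ 0.9 in every group;
  specific = max pairwise group difference ≥ 0.5; both thresholds are
  arguments. Reactions meeting neither stay unlabelled — absence of
  evidence is not forced into a category.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on the synthetic
defaults: a ~65-reaction model, 60-sample cohort, MC nulls of 500–10,000
draws (with exhaustive subset enumeration as the oracle on graphs up to
12 nodes), a 7-point threshold sweep, and 100 random media. These sizes
were chosen so that every check re-derives its expected value from
scratch — brute-force LP vertex enumeration, definition-level
correlation formulas, full null enumeration — rather than comparing
against stored numbers.

## Known limitations

* The LP returns one optimal flux distribution; alternative optima can
  reshuffle the inconsistency vector between parallel absent routes
  (I itself is unique). No flux-variability analysis is attempted.
* MC needs a non-degenerate null: tiny active sets (or the full gene
  set) give wide or zero-width nulls and the z-score loses meaning.
* Markers are heuristics over a directed share-metabolite graph;
  distance-based calls (CIL/COL) inherit the medium through which
  exchanges are uptake-enabled.
* The SBML layer covers Level 3 + fbc and the Level 2
  notes/kineticLaw dialect; exotic encodings (species-reference
  modifiers, nested function definitions) are out of scope.
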