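# metcoher

Confronting transcriptome profiles with a constraint-based metabolic model
in two complementary ways, and comparing them:

* **Inconsistency (I)** — a GIMME-style linear program. Reactions whose
  mapped expression falls below a threshold *t* are "absent"; the LP keeps
  the flux of a metabolic objective at a level *l* of its FBA maximum
  while minimising the deficit-weighted flux through absent reactions,

  minimise Σᵢ wᵢ·|vᵢ|  over absent i, with wᵢ = max(0, t − xᵢ),
  subject to S·v = 0, bounds, v_obj ≥ l·v_max.

  The optimum is *I*; the absent reactions still carrying flux form the
  *inconsistency vector* ("reinserted" reactions).

* **Metabolic coherence (MC)** — a purely topological z-score. The model
  is projected onto a gene network (currency metabolites removed, genes
  linked through same or adjacent reactions); the connected-node ratio of
  the above-threshold gene set is compared against N random equal-size
  node subsets: MC = (C − μ)/σ.

The package decomposes *I* into per-reaction contribution strengths,
splits a case cohort into low/high-inconsistency groups (LIG/HIG) against
the control mean, separates unspecific from specific contributors, and
classifies contributing reactions with topological markers — bottleneck
(BN), chain disruptor (CD), invisible path (IP), close to input/output
layer (CIL/COL), just below threshold (JBT). Threshold, objective-level
and random-media sweeps probe the robustness of the MC–I anticorrelation.
A seeded synthetic generator (compartmentalised toy model + three-group
expression cohort with planted ground truth) makes the whole analysis
reproducible without external data.

It is aimed at systems-biology researchers who integrate expression data
with genome-scale metabolic reconstructions and want both the
constraint-based and the network view of where model and data disagree.

## Worked example

```r
library(metcoher)

spec  <- synthetic_spec(seed = 1)          # study conditions
model <- generate_toy_model(spec)          # SBML-writable toy network
med   <- toy_reference_medium(model)
m_app <- apply_medium(model, med)

fba <- fba_max(m_app)
fba$v_max
#> [1] 10

co  <- generate_cohort(model, spec)        # 20 control / 20 LIG / 20 HIG
net <- project_gene_network(model, remove_currency_metabolites(model))

i1  <- reaction_expression(co$expr[, 1], model, quiet = TRUE)
g1  <- gimme(m_app, threshold_pattern(i1, spec$t), l = 0.8, fba = fba)
g1
#> <gimme_result> I = 10.6309 (normalized 1.329), v_obj = 8 (level 0.8 of
#> v_max 10), 6 contributing reaction(s)

mc1 <- metabolic_coherence(net, active_genes(co$expr[, 1], spec$t),
                           N = 1000, seed = 101)
mc1
#> <mc_result> MC = 1.882 (ratio 0.7273, null mu 0.4951, sigma 0.1234,
#> N = 1000, |g_sub| = 22)
```

The first control sample pays I ≈ 10.6 — mostly the planted
just-below-threshold step and the penalised mitochondrial segment — while
its active genes are more connected than random subsets of the same size
(MC ≈ 1.9). Across the full cohort the two scores anticorrelate strongly
(at seed 1: Pearson r = −0.82, Spearman ρ = −0.87; group mean I of
66.7 / 11.9 / 3.1 for HIG / control / LIG), and the cohort split against
the control mean recovers the planted LIG/HIG labels exactly.

The full pipeline (scores, groups, contribution table with markers,
sweeps, manifest) runs as one call:

```r
cfg <- run_config(model, co$expr, med,
                  labels = ifelse(co$labels == "control", "control", "case"),
                  out_dir = "out", t = spec$t, l = 0.8, seed = 1)
run_pipeline(cfg)
```

or from a shell via `inst/scripts/run_pipeline.R` (`--simulate` generates
the synthetic study first).

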