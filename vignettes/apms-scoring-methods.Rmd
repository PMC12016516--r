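---
title: "Methods: scoring, ranking and simulating AP-MS spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, ranking and simulating AP-MS spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsrank)
```

## The statistical model

An AP-MS comparison contrasts one bait's tagged purifications (typically
three biological replicates) with parental-strain control purifications
(up to four) performed under the same growth condition. The observable is
the spectral count: the number of MS/MS spectra assigned to peptides of a
protein in one run, a semi-quantitative abundance proxy.

For each protein detected in at least one experimental run we form a 2×2
contingency table from counts **pooled (summed) across replicates**:

|                  | experimental | control |
|------------------|--------------|---------|
| this protein     | a            | b       |
| all other proteins | c          | d       |

Conditioned on the margins, `a` is hypergeometric under the null that the
protein occupies the same fraction of total spectra on both sides. The
one-sided P value is the upper tail `P(X >= a)`, computed via
`stats::phyper`; an enumeration oracle (explicit pmf summation from log
binomial coefficients) verifies it exhaustively in the test suite for all
tables with margins up to 60.

Three modelling decisions deserve justification, since the comparison of
"mean spectral counts" does not by itself pin down an exact test:

* **Pooled counts, not means.** An exact test needs integers; summing
  replicate counts is the natural sufficient reduction. Means are kept for
  the fold change, where they are the interpretable scale.
* **One-sided.** The workflow only seeks proteins *enriched* in tagged
  purifications; depletion is not a signal of interaction.
* **Adjusted P against the thresholds.** Benjamini–Hochberg correction is
  applied across the proteins tested within one bait/condition comparison,
  and the adjusted P is compared to the significance levels. A `p_mode =
  "raw"` configuration switch restores raw-P thresholds for sensitivity
  analyses.

The fold change is `log2((mean_exp + 0.5) / (mean_ctrl + 0.5))`. The
pseudocount of 0.5 (half the smallest observable count) keeps the ratio
finite for the most interesting case — preys entirely absent from
controls — at the cost of a slight downward bias for low-count proteins;
the bias is below 0.1 log2 units once control means exceed ~5 counts.

Proteins never detected in the experimental runs are not tested: the test
asks whether an observed copurification is enriched, and an all-zero
experimental row can never be. All-zero rows remain legal observations in
the count table itself.

## Significance, rescue, rank

A protein is significant when `p < alpha` (0.05) and `log2fc >= fc_min`
(2). Two stricter tiers, `strict_alpha` (0.01, inclusive) and `fc_strict`
(4), define the rank score together with replicate reproducibility:

```
rank = 5 − max(0, 3 − n_detected) − [p > 0.01] − [log2fc < 4],  floored at 1
```

Detection in a replicate means a spectral count of at least 1 in that run
(`detection_floor`); no stronger floor is assumed. The replicate category
always refers to the experimental replicates — control replication enters
through the test and fold change, not through reproducibility. The
one-point-per-missing-replicate rule is the minimal extension of the
three-category deduction scheme that can produce rank 1 (one detected
replicate plus both lax categories), which observed rank distributions
require; with three binary categories the minimum would be 2.

**Bait rescue.** Occasionally the bait itself passes the P criterion but
sits just under the fold-change cutoff (empirically around log2fc ≈ 1.8
for one formate dehydrogenase subunit). Discarding the bait from its own
purification is clearly wrong, so the fold-change threshold for that
comparison is lowered to the bait's own log2fc, and every protein passing
P within the adjusted range is retained and flagged `rescued`. The
`rescue_floor` (default 1) bounds how far the threshold can fall: a
purification whose bait shows essentially no enrichment is a failed
experiment, not an occasion to lower thresholds. Rescued records are
ranked with the same deduction rule; since a rescued record has
`log2fc < 4` by construction, it loses the fold-change point.

The rank deduction uses `log2fc < fc_strict` rather than the interval
`[fc_min, fc_strict)` so that rescued records (below `fc_min`) still rank;
for non-rescued significant records the two formulations coincide.

## Networks

Significant associations become directed, condition-tagged, rank-weighted
bait→prey edges; `(bait, prey, condition)` is unique. Self-edges — the
bait recovering its own protein — are a purification-success annotation,
not partnerships, and are kept apart from partner counts. Condition tags
live on edges rather than in separate networks so that ±S° contrasts are
edge-set queries. Complex-level operations (`reciprocal_pairs`,
`intersect_groups`) treat "copurified by a complex" as "copurified by at
least one tagged subunit of it"; subunits shared between two complexes
(the POR/VOR γ gene) are excluded from reciprocity tests with a warning,
since an edge to a shared subunit is evidence for neither direction.
GraphML export (via igraph) carries rank and condition flags as typed
attributes and round-trips them exactly; SIF carries topology only.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates the comparative structure the scoring
pipeline consumes:

* **Sparse background.** Per-protein baseline (resin-affinity) means are
  gamma distributed with shape 0.3 and mean `background_mean` (default 10
  counts): most of the proteome is at or near zero in any run, a minority
  forms the reproducible background, matching the ~100–700 proteins
  typically identified per run against a ~2,306-protein proteome
  (`proteome_size` default).
* **Planted partners.** Each bait receives `partners_per_bait` (default
  30, the study's average partner yield) true partners whose experimental
  means are their control means scaled by `2^effect`, with effects drawn
  uniformly from `effect_range` (default 2–6 log2 units, deliberately
  spanning the decision boundaries at 2 and 4). Partners are drawn from
  proteins with baseline mean at least `background_mean / 2`, so the
  planted multiplicative effect is observable against the control runs.
* **Sticky binders.** A `sticky_fraction` (default 2%) of proteins is
  elevated (20×) in *all* runs, experimental and control alike; a correct
  pipeline must reject them, which the specificity tests verify.
* **Undetectable proteins.** A configurable fraction emits zero counts
  everywhere regardless of abundance — the ferredoxin-1 phenomenon, a
  protein too small/refractory to yield usable tryptic peptides. Planted
  partners may be undetectable; by construction they can never be
  recovered, and the truth table records the flag.
* **Overdispersion.** Counts are negative binomial with dispersion 0.25
  (variance = μ + 0.25 μ²), not Poisson; spectral counts are overdispersed
  in practice, and Poisson noise would make the calibration tests
  trivially easy.
* **Design.** 3 experimental vs 4 control replicates per condition, two
  conditions (±S°) by default, with optional per-run library-size jitter
  to exercise the optional total-count normalization of means (the Fisher
  test always uses raw pooled counts; the published workflow applies no
  normalization, so it is off by default).

Seeding is hierarchical: baselines, bait identities, partner sets and
every run block draw from separate substreams derived from the master
seed, so enlarging a study (more baits) never perturbs previously
generated runs.

The simulator does **not** emulate peptide-level identification (shared
peptides, protein inference), run-to-run retention-time effects,
condition-dependent interaction rewiring, or correlated contaminant
clusters. Passing recovery and calibration tests therefore demonstrates
that the statistics behave correctly under the stated generative
assumptions — not that real purifications satisfy those assumptions.

## Numerical and testing choices

* Fisher P values are floored at the smallest positive double and capped
  at 1; an all-zero 2×2 table is an error, not P = 1.
* BH adjustment wraps `stats::p.adjust`. Note that the step-up transform
  is *not* idempotent in general (`(0.01, 0.04) → (0.02, 0.04) → (0.04,
  0.04)`); the invariants tested are the ones that hold: adjusted ≥ raw,
  bounded by 1, order-preserving, permutation-equivariant, and constant
  vectors as fixed points.
* Exports sort edges lexicographically so identical networks produce
  byte-identical files; `run_score()` output is a pure function of its
  inputs and configuration.
* Test problem sizes are chosen for tight feedback while keeping the
  statistics honest: proteomes of 200–500 proteins, 50 null simulations
  for false-positive calibration, 25 seeds × 20 planted partners for the
  recovery property, and the exhaustive Fisher sweep over all ~3.6 million
  2×2 tables with margins ≤ 60. The generator defaults (2,306 proteins, 30
  partners) remain those of the full-scale study design.

## Limitations

* The pooled-count Fisher test treats spectra as exchangeable tokens;
  overdispersion between replicates makes it anti-conservative for very
  high-abundance proteins, which is precisely why the fold-change
  threshold and the replicate category of the rank exist. The null
  calibration test measures the joint procedure, not the raw test.
* BH correction within one bait/condition comparison controls FDR per
  purification, not across a whole interactome campaign.
* Rank scores are ordinal confidence tiers, not probabilities; no attempt
  is made to model interaction propensity (SAINT-style mixtures or
  spectral indices like NSAF are out of scope by design).
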