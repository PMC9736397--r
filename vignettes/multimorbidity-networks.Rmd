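---
title: "Multimorbidity networks from hospital discharge records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks from hospital discharge records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnet)
```

This vignette documents the statistical model behind `pdnet`, the
parameters that matter, the synthetic-data generator and what passing tests
on it do and do not show, and the design decisions taken where the
methodology left genuine choices.

## The analysis model

The unit of observation is a hospital discharge record: one hospitalization
with a primary diagnosis and up to 40 secondary diagnoses as ICD-10 codes.
The analysis proceeds in four stages.

**1. Chronic comorbidity identification.** Codes are truncated to their
three-character category, since detail codes below that level distinguish
clinical presentation rather than disease entity. Chapters XIX (injury),
XX (external causes), and XXI (health-status contacts) code circumstances
rather than chronic disease and are removed; we treat the special-purpose U
codes (chapter XXII) the same way, for the same reason — this is
configurable. Remaining codes are intersected with an editable
chronic-condition list (`inst/extdata/chronic_codes.txt`) and pooled per
patient across all hospitalizations, because comorbid burden is defined
over the whole observation period. Diseases whose prevalence is not
*strictly* above the floor (default 1%) are dropped; rare codes give
unstable pairwise estimates. A record-level mode (each hospitalization its
own denominator unit) is available because prevalence tables in the
discharge-record literature are sometimes published on record rather than
patient denominators; the case-control arithmetic in our acceptance checks
back-computes correctly under record counts.

**2. Enrichment.** Each disease's 2×2 case-control table yields an odds
ratio with the Woolf log-normal interval. We chose Woolf over exact
conditional intervals because it reproduces the published interval
arithmetic for this kind of table exactly from rounded counts, and it is
the standard companion of the chi-square test used here (with Yates
correction, falling back to Fisher's exact test when any expected cell is
below 5 — the 2×2 test is otherwise a free choice at these sample sizes).
Zero cells get the Haldane–Anscombe 0.5 correction and a flag; a margin of
two zero cells is undefined and returned as flagged `NaN`. Multiplicity is
handled by Bonferroni over the case comorbidity universe (recomputed from
the data, never hard-coded), and "enriched" means Bonferroni-significant
with OR > 1.5.

**3. Networks.** Edges are weighted by the Salton cosine index
`SCI = n_ab / sqrt(n_a n_b)`, the cosine similarity of the two diseases'
patient sets. Its key property, and the reason it is preferred over
relative risk for small strata, is sample-size immunity: duplicating every
patient leaves SCI (and RR) unchanged while raw counts double. The test
suite asserts this, together with the algebraic consistency
`SCI² · N = RR · n_ab` to 1e-12.

The published methodology prunes edges by "the cut-off of SCI" without
printing a global cutoff, while also defining a t statistic for the
pairwise φ correlation. Our default edge rule is therefore
significance-driven: keep an edge when `n_ab ≥ 2` and the φ t-test
(df = max(n_a, n_b) − 2) is two-sided significant at α = 0.05; an absolute
SCI cutoff is available as a third, independently toggleable criterion, and
every network reports its realized minimum SCI so that results remain
comparable with cutoff-based analyses. Pairs with a marginal of 0 or N have
undefined φ and never form edges under the significance rule.

Shortest-path statistics need a distance; the methodology is silent. We use
`1/SCI` (a strong comorbidity is a short step) by default and provide unit
distances. Diameter and average path length are computed on the largest
connected component; closeness is per-component. Degenerate case: a
network whose largest component is a single node reports diameter 0 and is
flagged.

Node roles use weighted PageRank (damping 0.85, the conventional value) and
HITS. On an undirected graph the hub matrix `W Wᵀ` and authority matrix
`Wᵀ W` are both `W²`, so hub and authority scores coincide mathematically;
we compute each by its own power iteration (from the ones vector, so the
limit is deterministic even when a star-like component makes the top
eigenvalue degenerate; non-convergence within 1000 iterations is an error
with diagnostics) and report both columns, as downstream consumers expect
both. Any analysis that reports *different* hub and authority sets from an
undirected comorbidity network is using a directed variant or an
implementation artifact; we flag this rather than emulate it.

"Top 10 percentile" role sets are the nodes strictly above the 90th
percentile of each score. Tied scores are treated alike — all in or all
out — so the set size is about 10% of nodes, deviating only at ties; with
heavily tied scores (e.g. betweenness 0 on most nodes) the strict rule
correctly admits only the genuinely high scorers.

The degree distribution's power-law plausibility is assessed the standard
way: discrete MLE for the exponent above `x_min`, `x_min` by KS
minimization, and a semi-parametric bootstrap p-value (synthetic samples
from the fitted tail plus the empirical body, refitted per replicate; the
p-value is the share of replicates with KS distance at least the observed).
The replicate count is configurable (default 200); all-equal degrees are
flagged degenerate instead of fitted.

**4. Rule mining.** Apriori is implemented natively: level-wise candidate
join with downward-closure pruning, supports counted on the binary patient
× disease matrix. Rules are targeted at a consequent (heart failure, I50,
by default) with *strict* thresholds — support > 0.01, confidence > 0.5 —
matching the published wording "support >0.01 and confidence >0.5". All
five metrics (support, confidence, lift, leverage, conviction) are
reported, with conviction `Inf` at confidence 1. The suite proves
equivalence with exhaustive enumeration on 30-patient × 8-disease
instances, where all 255 itemsets can be enumerated.

## Matching

Propensity-score matching requires a fitted model that would make the
pipeline's output depend on estimation details irrelevant to the network
methodology, so controls are paired by deterministic caliper matching:
exact on sex and department, birth year (discharge year minus age) within
±2 years, nearest discharge date among eligible candidates, processed in
patient-id order with ties broken by pool patient id. The same inputs
always give the same matching.

## The synthetic generator

`generate()` draws binary disease indicators per patient from a
latent-factor Bernoulli model: disease *i* is present when its independent
baseline `Bern(b_i)` fires or any shared factor `Bern(q_f)` loading on it
fires. Given target marginals and a planted pair's target SCI, the factor
strength `q` is solved by root finding and the baselines are adjusted so
marginal prevalences are preserved; a target is rejected as infeasible when
it exceeds the cosine bound `SCI ≤ sqrt(min(p_a, p_b)/max(p_a, p_b))` or
implies negative dependence. Block modules share one factor across members;
a disease in two blocks becomes a bridge. We chose this construction over
pairwise Ising sampling because it is tractable, exactly seedable, and its
planted quantities have closed-form targets that recovery tests can check.

`paperlike_spec()` fixes the study conditions: 805 case patients with
1 + Poisson(0.3) hospitalizations each (~1036 records), 36.29% female, age
drawn from the seven strata with weights 45/84/123/181/256/218/129 (mean
age ~51), a 60-disease catalogue whose twenty cardiometabolic codes carry
the published case and control prevalences and whose forty fillers sit at
5% (cases) and 0.5% (controls, i.e. below the floor), planted
valve-disorder and heart-failure/complication dependencies, two mild block
modules, and an age-increasing prevalence gradient (multipliers 0.55–1.30,
normalized to preserve marginals). The expected case burden is the sum of
retained case prevalences ≈ 5.86. For controls we kept the twenty published
control prevalences fixed, which implies an expected control burden ≈ 2.6
rather than the published 2.45; we preferred exact published prevalences to
rescaling them, and the calibration tolerance (2.2–2.7) covers the
difference. Index-disease codes (I42, Q24) appear as primary diagnoses in
case records but are excluded from the comorbidity universe via the chronic
list, as comorbidity tables exclude the defining disease.

What the generator does *not* emulate: coding noise and miscoding,
department- or calendar-time-varying prevalence, dependence structures
beyond shared factors (e.g. negative dependence, higher-order
interactions), and the real cohort's co-occurrence matrix, which is not
public. Passing recovery tests therefore shows the pipeline correctly
extracts structure *of the planted kind* at realistic sample sizes — not
that real discharge data satisfies the model. In particular, cohort-level
counts from the original study (71/69 comorbidities, 26 rules, per-stratum
node and edge counts) are not reproducible and are covered only by
property-based checks; with only a handful of planted dependencies, the
significance-pruned synthetic networks are much sparser than real
comorbidity networks, whose dependence is pervasive.

## Numerical choices and degenerate inputs

- Strict prevalence floor: "over 1%" keeps prevalence > 0.01; a disease at
  exactly 1% is dropped (configurable).
- Age at stratification is the age on the patient's first (earliest)
  discharge record; strata must partition ages 0–130 or configuration
  fails.
- φ t-test with `max(n_a, n_b) < 2` would need a negative df; the t
  statistic is computed with df floored at 0 and such pairs are never
  significant.
- Power iteration tolerance 1e-13 on the normalized vector, cap 1000
  iterations; PageRank uses igraph's solver.
- The SCI/RR identity is asserted to 1e-12; topology against the
  brute-force oracle to 1e-9 (shortest-path tie detection on floats).
- Clopper–Pearson is the default prevalence interval (beta quantiles);
  Wilson is available. The interval of the published prevalence table is
  consistent with Clopper–Pearson.

## Problem sizes in the test suite

The suite runs the generator at 805–2000 patients for calibration and
recovery checks, 30×8 matrices (50 replicates) for Apriori-oracle
equivalence, ≤8-node graphs (dozens of instances) for the topology oracle,
1000 random configurations for the SCI/RR identity, and 500 degree draws
for power-law exponent recovery — sizes at which the brute-force oracles
are exact and the whole suite completes in a few minutes on one CPU.

## Limitations

The networks are undirected: edges are co-occurrence, not causation or
temporal sequence. Patient-level pooling ignores within-patient timing, so
a comorbidity acquired after the index condition is indistinguishable from
one preceding it. Bonferroni is deliberately conservative; no FDR option
is provided because the enrichment definition is tied to the family-wise
threshold. The caliper matcher is greedy (not optimal assignment), which
is sufficient when the pool densely covers the case demographics — as the
generator guarantees — but can leave avoidable unmatched cases on sparse
real pools.
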