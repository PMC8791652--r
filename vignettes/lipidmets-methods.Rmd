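---
title: "Methods: consensus lipidomics selection and network integration"
author: "lipidmets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus lipidomics selection and network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmets)
```

This vignette documents the statistical procedures implemented in
`lipidmets`, the assumptions behind them, the parameters that matter, and
the design decisions taken where the problem left genuine latitude. The
setting is a two-group (case–control) plasma lipidomics study with a
companion metabolite panel and a clinical table; the motivating application
is metabolic syndrome in treated HIV cohorts.

## Nomenclature parsing

Complex-lipid-panel shorthand comes in three forms: acyl-sum names
(`CE(18:2)`), acyl-enumerated names (`DAG(16:0/18:1)`), and
triacylglycerol neutral-loss names (`TAG(52:2)-FA(16:0)`), where the head
carries the whole-molecule totals and the tail names one constituent fatty
acid. `parse_lipid_name()` maps each to a class, one of four categories
(glycerolipid, glycerophospholipid, sphingolipid, steroid), total carbons
and total double bonds.

Two decisions here:

* **Sphingoid bases are summed into the totals.** `SM(d18:1/16:0)` is
  read as C34:1 — the `d` long-chain-base prefix is stripped and base and
  acyl chains are summed, because the structural maps (below) index
  species by whole-molecule size and saturation.
* **Unknown classes degrade, never error.** A name like `PG(34:2)` parses
  its totals and lands in category `other`, so panels richer than the
  built-in vocabulary still run; the vocabulary itself is a plain data
  frame (`lipid_class_table()`) that callers can extend.

No chemistry beyond the shorthand is attempted: no masses, no isomer
resolution, no SMILES.

## Preprocessing

The chain is fixed: minimum imputation → median centering →
near-zero-variance filtering → (natural-log transform for the parametric
branch only). Zeros are treated as below-LOD missing by default
(`zeros_as_missing`), and imputation substitutes the feature's minimum
observed positive value — the usual assumption that missingness in
concentration panels is left-censoring, not randomness. After centering,
every feature's median is exactly 1, so log medians are exactly 0.

The near-zero-variance rule is the classical frequency-ratio /
percent-unique convention (defaults 19 and 10): a feature is dropped when
its most common value is ≥ 19× more frequent than its second most common
*and* fewer than 10% of its values are distinct, or when its variance is
exactly zero. Reference analyses of this kind report removing about 5% of
features; that fraction is data-dependent, so the two cuts — not the
fraction — are the exposed parameters. Filtering runs after centering
(centering is per-feature monotone, so it cannot change the verdict).

Normality screening uses a one-sample Kolmogorov–Smirnov test against a
normal with the feature's *estimated* mean and sd. Estimating the
parameters from the same data makes the test conservative (the Lilliefors
caveat); the per-feature p-values are reported for screening only and gate
nothing downstream.

## The four selection arms

**Mann–Whitney U** runs on the (raw-scale, centered) concentrations; being
rank-based it is invariant to any per-feature monotone transform. The
exact null distribution is used when the pooled sample size is ≤ 20 with
no ties; otherwise the normal approximation with tie and continuity
correction. Selection: BH-adjusted q < 0.001.

**Moderated t** runs on log concentrations. Per feature, the group
difference β and pooled variance s² (d = n − 2 df) feed an empirical-Bayes
prior (d₀, s₀²) estimated by method of moments on log s²: the mean and
spread of `log(s²) − ψ(d/2) + log(d/2)` are matched to their digamma /
trigamma expressions, and the trigamma equation is inverted by a monotone
Newton iteration. The posterior variance
`s̃² = (d₀ s₀² + d s²)/(d₀ + d)` yields t on d₀ + d df. Two documented
limits anchor the implementation: forcing d₀ = 0 reproduces the ordinary
equal-variance t to machine precision, and when the observed log variances
show no excess spread over chi-square sampling noise the prior is a point
mass at the common variance, making moderation a no-op. The two-group
design carries no covariates by default; the matched-cohort design this
emulates matches on age and sex, so unadjusted contrasts are the faithful
default.

**PLS-DA** uses sequential NIPALS components with X-deflation on centered,
unit-variance-scaled features (scaling is the default because lipid
concentrations span orders of magnitude; a flag disables it), with the
class coded ±1 and centered. VIP is defined so that the mean of squared
VIPs is identically 1, which makes the conventional VIP > 1 cut
"above-average importance" — and guarantees that not every feature can be
selected unless all are equal. Q²Y = 1 − PRESS/TSS is computed by
stratified k-fold cross-validation (default 7 folds) and may be negative.

**rdCV random forest.** Repeated double cross-validation: per repetition
the samples split into `n_outer` stratified folds; each fold is held out
entirely while recursive feature elimination runs on the remainder. At
each elimination step one forest (ranger, permutation importance) is
fitted; its out-of-bag misclassification is the inner validation signal —
a deliberate simplification of a further explicit inner fold loop that
keeps the nested structure (outer folds never influence selection) at a
fraction of the cost — and the lowest-importance `1 − var_ratio` of
features is dropped. The averaged validation curve defines three models:
`min` (fewest features within 5% of the curve minimum), `max` (most
features within 5%), `mid` (rounded geometric mean); final sets are
top-ranked by average elimination order, hence nested. Defaults
(`n_rep = 5`, `n_outer = 6`, `var_ratio = 0.75`) follow the conventions of
the published rdCV method; the pipeline configuration scales them to
2 × 5 as its own desk-scale default. AUROC is computed exclusively from
held-out outer-fold predictions; on label-permuted data it sits at chance,
which is the operational proof that selection does not leak.

**Consensus** is the plain intersection of the four selected sets
(Mann–Whitney q < 0.001, moderated q < 0.001, VIP > 1, and the RF *Max*
set — the all-relevant model is the inclusive arm, so the intersection
stays conservative through the other three), with all 2ᵏ−1 UpSet-style
exclusive cardinalities reported.

## Structural composition maps

Per lipid class, species are binned on (total carbons × total double
bonds); a cell's effect is the mean moderated-model log difference of its
species (raw fold change would re-introduce the scale differences the log
removed) and its q is the minimum member q — a cell lights up when any
member passes, which is the right semantics for "is anything in this
structural neighbourhood moving". The per-class trend calls `increase` /
`decrease` when at least two thirds of significant cells share a sign.
One reported companion condition in this figure family, "Pearson's
r > 0.7", has no defined referent (r between what and what?) and is
deliberately **not** implemented as a filter; significance is FDR-only.

## Network integration

All pairwise Spearman correlations (midranks, so ties are exact) across
samples; two-sided p from the t approximation, BH across all pairs; an
edge survives at q ≤ 1e-07 **and** ρ ≥ 0.38, positive correlations only,
weight = ρ. Both thresholds are recorded in the object and the manifest.

The topology is contrasted with the G(n, m) Erdős–Rényi null (same nodes,
same edges): degree variance, global clustering, mean shortest path on the
largest component, and a KS divergence of degree distributions, each
flagged when outside the null's 99% envelope. Communities come from the
weighted Leiden algorithm (modularity objective, resolution 1, fixed
recorded seed); per community the size, average *full-network* degree
(the within-community alternative is noted as an open reading; the
full-network definition is implemented), and the mean carbons/double bonds
of glycerolipid members are attached.

Clinical association summarises each community per sample as the mean of
members' z-scored abundances (`community_score = "mean_z"`; a
sign-oriented first-principal-component switch exists because the
literature is split on this choice, and the mean-z default is the more
robust of the two for small communities). Binary variables are regressed
on the score by logistic regression, continuous ones by linear regression
— the regression direction is chosen so a positive estimate reads
"higher community abundance goes with the case phenotype". Logistic
p-values are likelihood-ratio, not Wald: community scores can separate the
groups almost perfectly, where Wald collapses. BH runs across all
community × variable tests. The same machinery tests single features
against one clinical variable (default report cut q ≤ 0.01), and degree
hubs (top 10%, ties broken by strength then id) plus hypergeometric
over-representation against a user-supplied annotation (class labels by
default, standing in for web-service lipid ontologies, which are out of
scope) complete the stage.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. It
emulates the study conditions the pipeline targets:

* 2 × 100 samples; a 917-species panel in the published 602/228/61/26
  category split, with a class inventory inside each category chosen once
  (TAG-dominated glycerolipids, PC/PE-dominated glycerophospholipids) —
  the true inventory is unpublished, so a plausible one is fixed and
  documented in the code;
* multiplicative log-normal concentrations (`noise_sd = 0.5` on the
  natural-log scale, a mid-range CV for targeted panels), an additive
  case-group shift of `effect_log2fc × log 2` on a planted subset of
  DAG/TAG species (default fraction 0.0224 ≈ 13 species, matching the
  scale of the motivating finding; effect size 1 log2 unit, chosen for
  testability as no published per-lipid effect sizes exist);
* a block-diagonal Gaussian copula: planted lipids share a latent factor
  (pairwise r = 0.5) with a glutamate-pathway-like metabolite sub-block,
  and two background blocks (non-planted glycerolipids;
  glycerophospholipids) give the network stage communities to find;
* MNAR missingness: the smallest 2% of draws per feature drop to zero,
  matching minimum-imputation semantics;
* a clinical table drawn from the published marginals (90% male, matched
  age, VAT/SAT log-normal with the reported means/sds — so the VAT group
  difference reproduces as `<0.001` — ART exposure frequencies per arm).

What it does **not** emulate: real concentration distributions of any
vendor panel, inter-class correlation structure beyond the three blocks,
longitudinal sampling, or batch effects. Passing tests therefore certify
the *machinery* — error control, power at the planted effect size,
recovery of planted structure — not performance on any particular real
cohort.

## Numerical choices and degenerate inputs

* Trigamma inversion: Newton iteration from `y = 0.5 + 1/x`, relative
  tolerance 1e-10, with asymptotic fallbacks at both ends.
* NIPALS stops with an error if `X'y` vanishes (a degenerate component);
  constant features get unit scale rather than 0/0.
* All-missing features, nonpositive medians, single-class folds, empty
  graphs, constant clinical variables: each errors or warns by name
  rather than propagating NaNs; zero-variance features are excluded from
  the moderated fit and the correlation network with a warning.
* Hub ranking tie-break (degree, then strength, then id) and the Leiden
  seed are fixed and recorded so ranked outputs are reproducible.
* Exact-vs-approximate Mann–Whitney switches at pooled n = 20; ties force
  the approximation.

## Problem sizes

The test suite exercises the full 917 × 200 configuration where the cost
is linear (generation, parsing, preprocessing, both univariate arms) and
compact configurations elsewhere, as the package's own desk-scale
defaults: ~180-feature cohorts with 40 per group for end-to-end consensus
properties (including a 20-seed global-null series), 50-feature / 60-sample
designs for rdCV recovery, 8-node graphs for the exhaustive-modularity
comparison, and 60-node planted-block networks for partition recovery. The
acceptance script runs the full default configuration end to end.

## Known limitations

* The moderated model is the two-group special case: no contrast
  matrices, covariates, array weights, or robust/trend variants.
* PLS-DA is the single-response NIPALS variant; no OPLS-DA.
* rdCV uses out-of-bag inner validation (see above) and misclassification
  as the selection fitness, with AUROC for reporting only.
* Community–clinical regressions are marginal (one score at a time), not
  joint models; "independently associated" readings require external
  adjustment.
* The ORA stage is a generic hypergeometric test over user annotations;
  it does not reproduce any proprietary ontology service.
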