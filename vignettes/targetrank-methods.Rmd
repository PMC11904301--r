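---
title: "Scoring and optimizing cell-surface immunotherapy target rankings"
author: "targetrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and optimizing cell-surface immunotherapy target rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetrank)
```

## The problem

Immunotherapies such as CAR-T cells and antibody-drug conjugates (ADCs) need
a target protein that is abundantly and homogeneously expressed on the tumor
cell surface, nearly absent from normal tissues, and reachable by an
antibody. Surface-proteomic or RNA-seq screens of a cancer cohort yield
thousands of candidate genes; deciding which handful to validate is a
multi-criteria prioritization problem. `targetrank` turns a genes-by-samples
expression matrix plus a set of per-gene annotation tables into a single
ranked score per gene, measures how well that ranking recovers targets that
are already in the clinic, and tunes its own scoring parameters against that
measure.

## The scoring model

For gene $g$ and feature $i$, let $x_{gi}$ be the feature value after
rescaling to $[0,1]$ and imputation. The score is

$$ s_g \;=\; \frac{\sum_i w_i \, x_{gi}^{\exp(c_i)}}{\sum_i |w_i|}, $$

a normalized weighted average of curved feature values. The pipeline order
is fixed: **rescale → impute → curve → weight**.

* **Rescale.** `rank_percentile` maps a value to $(\mathrm{rank}-1)/(n-1)$
  with average ties (robust to heavy-tailed intensity distributions, the
  default for unbounded features); `minmax` preserves spacing and is the
  default for already-bounded scores and 0/1 flags. Constant columns carry
  no information and map to 0.5.
* **Impute.** Operating on the rescaled scale makes fill constants
  scale-free: `zero` (no evidence contributes nothing — the default for
  therapeutic and localization flags), `neutral` (0.5, used for
  normal-tissue and dependency features where absence of measurement should
  neither reward nor penalize), `min`, `median`. Missing raw cells are never
  silently zero-filled upstream; the imputation method is the single place
  where absence of evidence acquires a value.
* **Curve.** $v \mapsto v^{\exp(c)}$ is our one-parameter curving family.
  The qualitative contract — identity at $c=0$, positive $c$ accentuates
  differences among high values, negative $c$ among low values, always
  strictly monotone and fixing 0 and 1 — admits many parameterizations; we
  chose $\exp(c)$ as the exponent because it keeps the exponent positive for
  every real $c$, makes $c$ an unconstrained real parameter symmetric around
  the identity, and gives convexity exactly for $c>0$.
* **Weight.** Direction is folded into the sign: lower-is-better features
  (normal-tissue expression) default to $w=-1$. Both $w_i$ and $c_i$ are
  free optimizer parameters within default boxes $[-10,10]$ and $[-3,3]$;
  the normalization by $\sum|w_i|$ makes the score invariant to positive
  rescaling of all weights and keeps $s_g \in [-1,1]$.

Ranks break ties by ascending gene symbol. This matters: the evaluation
metric depends on the exact permutation, so reports must be deterministic.

## Features and the default catalog

The catalog spans tumor-expression summaries computed from the user's data
(mean, median, max, upper quartile, fraction of samples expressing) plus
four annotation categories joined from database-style snapshot tables:
normal-tissue expression (maximum across tissues and its rank percentile,
both lower-is-better), surface localization (two bounded evidence scores),
biological annotation (mean dependency and the fraction of phenotype-matched
cell lines with dependency ≥ 0.5), and therapeutic availability (0/1 drug,
ADC and pediatric-target-list flags). It is a representative, extensible
set, not a replication of any particular production catalog; every feature
row declares its snapshot and column, so adding features is a configuration
change. How multi-column sources collapse into single features (max across
tissues, mean across matched cell lines) is a documented package choice.

Two design points deserve emphasis:

* **Left-join semantics.** Genes absent from a snapshot get *missing*
  values, not zeros, so "not measured" and "measured zero" remain
  distinguishable until imputation.
* **Label-leakage guard.** Known positives are derived from drug records
  matching the scored phenotype (active status → positive; all records
  discontinued → negative). If the therapeutic-availability *features* used
  the same records, the feature would equal the label and any optimization
  would trivially overfit. `has_drug`/`has_adc` therefore count only records
  in *other* phenotypes — cross-indication availability — and the effect-free
  null fixture verifies that optimized performance stays within the
  permutation band.

## Evaluation: mean average precision

For a ranking and a positive set $P$, average precision is
$\mathrm{AP} = \frac{1}{|P|}\sum_{p \in P} \frac{\#\{P \text{ at rank} \le r_p\}}{r_p}.$
Across phenotype projects we report the unweighted mean (MAP). Discontinued
targets give a *known-negative* set whose treatment is a modeling choice; we
implement two documented modes rather than guessing a hybrid: `full`
(whole ranking, unlabeled genes non-relevant; default without negatives) and
`labeled_only` (ranking restricted to labeled genes, so the score measures
only the ordering of positives against known negatives; default when
negatives exist). Every result records its mode.

## Parameter optimization

The fitting stack runs two stages, exploratory then local:

1. **SFS + Brent.** Greedy forward selection over the feature pool. The
   baseline objective is the full default catalog (this makes a 100%
   improvement threshold return the default result, a useful degenerate
   contract). A candidate is included only if it improves the current
   objective by a *relative* threshold — default $10^{-4}$ (0.01%);
   $10^{-3}$ (0.1%) is the stricter setting we recommend for production
   fits. After inclusion, the new feature's weight and then curve are
   refined one coordinate at a time by Brent search (weight first, then
   curve, fixed for determinism), and a refinement is kept only if it does
   not decrease the objective.
2. **GA + Nelder-Mead.** A real-coded genetic algorithm over the selected
   features' $(w, c)$ vector, seeded from the SFS result: tournament
   selection (size 3), uniform crossover (rate 0.9), Gaussian mutation (sd =
   10% of each bound's width, per-gene rate 0.15), elitism of one. Every 10
   generations the best individual is polished by Nelder-Mead and replaced
   only if the relative gain is ≥ 0.1%. Elitism plus seeding guarantee the
   final MAP never falls below the SFS result, and the best-so-far trace is
   non-decreasing by construction. Population 40 and 60 generations are
   desk-scale defaults chosen so a two-phenotype, thousand-gene fit
   completes in seconds; all are configurable via `tr_control()`.

Both improvement thresholds are *relative* fractions of the current
objective. One seed drives every stochastic element; the GA saves and
restores the caller's RNG state, and identical seeds give bit-identical
results (an objective cache keyed by the parameter vector accelerates
evaluation without affecting results). The rescaled+imputed feature matrix
does not depend on $w$ or $c$, so it is compiled once per fit and only the
curve/weight stage is recomputed per candidate — this is what keeps the GA
budget cheap.

`strategy = "multi_cancer"` maximizes mean MAP across all projects at once;
`"phenotype_specific"` fits one project. With a single project they
coincide; parameters fitted to one phenotype may transfer lossily to
another, which is exactly what the multi-cancer strategy is for.

Numerical notes: Brent evaluates the interval endpoints in addition to the
interior search so boundary optima are never lost; the Nelder-Mead wrapper
projects evaluations onto the box, restarts once from the converged vertex
to polish the solution, and never returns a point worse than its start;
an all-zero weight vector is an error at the user surface and an
objective value below any attainable MAP inside the optimizers.

## The synthetic benchmark

`build_fixture()` generates a complete self-contained study: per-phenotype
tumor expression (log2 scale, gene baselines $\mathcal{N}(5,2)$, sample
noise sd 1), a gtex-like normal-tissue table (log-normal), surface-evidence
scores (0–5), a dependency table with `<phenotype>.<cell line>` columns, a
pediatric-target-list flag table, and a drug table. Planted "ideal target"
genes (disjoint across phenotypes) receive a +3 log2 tumor shift (three
noise standard deviations), 5-fold normal-tissue suppression, strong surface
evidence with probability 0.9, a +0.6 dependency boost in their own
phenotype's cell lines, active phenotype-matched drug records (which become
the known positives), and cross-indication records with probability 0.7;
non-planted decoys receive discontinued records (known negatives, default
3 per 10 planted). These defaults are the benchmark's strong-signal
conditions; `null_effects = TRUE` collapses every boost to its background
rate, leaving labels with no informative feature — the null case.

The generator emulates intensity-like expression with planted mean shifts
and independent annotation evidence. It does not imitate real marginal
distributions, gene-gene correlation, batch structure, or the incomplete and
biased coverage of real drug databases — so passing benchmarks demonstrate
that the machinery recovers signal it was told to plant, not that any
particular biological ranking is correct. Ground truth lives only in the
manifest, never in a feature table.

The packaged benchmark (1000 genes, 2 phenotypes, 10 planted positives each,
fixture seed 7) is sized so the whole end-to-end fit runs in a few seconds;
on it, default parameters reach MAP ≈ 0.83 and the fitted parameters reach
MAP = 1.0 with every planted gene in the top 5% of ranks, while the
effect-free variant stays within the 99% permutation band of random-ranking
MAP.

```{r benchmark, eval = FALSE}
fix <- build_fixture(fixture_config(decoy_fraction = 0, seed = 7))
projects <- fixture_projects(fix)
objective(default_catalog(), projects)   # default-parameter MAP
fit <- tr_fit(projects, seed = 7)
fit$final_map                            # optimized MAP
plot(fit)                                # SFS + GA trace
```

## Other numerical conventions

* Percentiles are always linear interpolation between closest order
  statistics (`quantile(type = 7)`): in the restricted normal-expression
  filter (genes strictly below the 20th percentile of maximal normal-tissue
  expression by default) and in snapshot-derived percentile features.
* Gene identifiers are uppercased symbols and the join key everywhere; alias
  resolution is out of scope. Duplicate rows collapse by element-wise max by
  default (conservative for "high expression" criteria), configurable to
  mean or a hard error.
* Phenotype matching is exact after case-folding; no ontology mapping.
* Expression matrices are used as provided; no per-sample normalization is
  applied — users pre-normalize.

## Known limitations

* MAP inherits the biases of clinical-stage label sets: active development
  is not proof of a good target, and discontinuation is not proof of a bad
  one. The two negative-handling modes make the choice explicit but cannot
  remove the bias.
* Greedy forward selection can stall below the best feature subset when
  features separate positives only jointly; the exhaustive-oracle tests
  document this rather than hide it.
* The curving family, the summary-statistic set and the snapshot collapse
  rules are package choices within qualitative contracts, not replications
  of any external tool's exact lists.
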