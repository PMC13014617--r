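---
title: "Abundance-integrated scoring of disease–metabolite associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-integrated scoring of disease-metabolite associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrometab)
```

## The model

Direct metabolomic measurement of how a metabolite changes in a disease is
expensive and rare; species-level relative-abundance profiles of disease and
healthy cohorts are plentiful. `micrometab` estimates the direction and
strength of a metabolite's change from the abundance changes of the microbes
that produce it. For one disease and one metabolite,

$$\mathrm{score} = \sum_{i=1}^{N} (D_i - H_i)\, m_i,$$

where $D_i$ and $H_i$ are the median relative abundances of species $i$
across the disease-cohort and healthy-cohort samples, and $m_i \in \{0, 1\}$
flags whether species $i$ produces the metabolite. The producer mask keeps
irrelevant taxa from contributing; the median (rather than the mean) damps
the influence of extreme samples in data that are compositional and highly
dispersed. The score is a difference of relative-abundance fractions —
dimensionless, not normalized by $N$ — so its sign predicts the direction of
the metabolite change and its magnitude reflects how much producer abundance
moved.

The model's central assumptions, which users should keep in view when
interpreting output:

* **Linearity** — metabolite output is taken to scale with producer
  abundance; gene expression, substrate availability and interspecies
  interactions are not modeled.
* **Equal contribution** — every producing species counts equally; no
  weighting by metabolic efficiency or pathway flux.
* **Production only** — the map encodes "produces"; consumption is out of
  scope.
* **Species as strain proxy** — production is usually curated at strain
  level while abundance is species-level; `collapse_to_species()` merges
  strains by logical OR and the species' abundance stands in for its
  strains.
* **Correlation, not causation** — a negative score says the producers are
  depleted in patients, not that supplementing the metabolite treats the
  disease.

## Confidence

For a record with $k$ producing species, a paired-sample t-test on
$[D_1..D_k]$ vs $[H_1..H_k]$ asks whether the per-species median differences
are centred at zero. The t-test and the score are computed over the same
retained producer set, so the sign of the t statistic always agrees with the
sign of the score. P-values are two-sided, since both depletion and
enrichment are interpreted. Benjamini–Hochberg FDR is applied across the
family of defined tests; the family defaults to all tests in the run
(`fdr_scope = "global"`), with a per-disease alternative available, and the
choice is echoed in run manifests because the two scopes give different
FDRs. A Shapiro–Wilk test on the paired differences is attached as a
diagnostic flag only — gating records on a per-pair normality test would
silently reshape the record set, so records failing it keep their p-value
and carry `normality_ok = FALSE`.

Degenerate cases are made explicit rather than forced: with fewer than
`min_producers` species, or identical differences (zero variance), the
p-value and FDR are undefined (`NA`) and the record still reports its score.
Forcing a 0 or 1 there would distort the BH family.

## Tunable parameters

All thresholds live in one `scoring_config()` object:

| parameter | default | role |
|---|---|---|
| `n_top_microbes` | 100 | per disease, species retained by absolute change in median relative abundance |
| `min_group_samples` | 5 | minimum samples required in **each** cohort |
| `min_producers` | 3 | producers needed before a t-test is attached |
| `alpha` | 0.05 | significance level on p-values |
| `fdr_threshold` | 0.1 | BH-FDR significance threshold |
| `per_disease_top` | 5 | candidates reported per disease |
| `fdr_scope` | global | BH family definition |

Two of these encode readings of ambiguous conventions, decided once and
documented here. The sample-size threshold is applied to *both* cohorts: a
one-sided reading would let a single control sample define every $H_i$ for a
disease. `min_producers = 3` because a paired t-test needs at least two
pairs for one degree of freedom and three points before a normality
diagnostic says anything; the score itself is still reported for $k \in
\{1, 2\}$, only its confidence is undefined.

## Numerical conventions

* A species absent from a sample counts as abundance 0 in that sample's
  median — sparse exports omit zero rows, and medians are otherwise
  undefined over ragged supports.
* The median of an even number of samples is the mean of the two central
  order statistics.
* Top-$N$ ranking ties are broken by `species_id` ascending; candidate and
  biomarker ranking ties by `metabolite_id` ascending. All ranking is
  deterministic.
* Scores are summed in `species_id`-ascending order, so repeated runs are
  byte-reproducible.
* A zero score makes no direction claim and is counted as *inconsistent*
  with either literature label in benchmarking; excluding it silently would
  inflate consistency.
* Network exports sort nodes and edges, so two exports of the same network
  are byte-identical.

## Candidate selection and networks

Beneficial candidates are, per disease, the at most five most negative
significant scores (score < 0, p < `alpha`, FDR < `fdr_threshold`):
metabolites whose producers are depleted in patients, hence candidates for
supplementation. Biomarker candidates rank by $|\mathrm{score}|$ over both
signs — strong enrichment is as informative a marker as strong depletion.
The packaged reference table (`load_beneficial_reference()`) carries 48
literature-supported beneficial associations across 27 diseases and is used
by the test suite as a fixed filter-arithmetic check.

The disease–metabolite network keeps, per disease, the top five significant
records by $|\mathrm{score}|$; edge weight is $|\mathrm{score}|$ and edge
sign the association direction. Metabolite nodes are ranked by a **weighted
average score**, defined here as the mean of incident edge weights. The
defining property — and the reason the mean was chosen over a sum — is that
a low-degree metabolite with strong associations can outrank a high-degree
one with weak ones, while a broadly connected metabolite with consistently
strong edges still ranks highly. This is a modeling choice; other
connectivity/strength compromises exist, and the ranking function is
deliberately separate from candidate selection (which is sign-restricted).

In the metabolite–gene network, genes targeted by two or more of the
selected metabolites are flagged as shared hubs: convergence points where
several candidates may act on the same host gene.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the scoring pipeline
assumes: per-species baseline log abundances drawn once
(`baseline_log_sd = 1.5`, spanning roughly three orders of magnitude across
species, as species-level gut profiles do), a planted log-scale shift
(`effect_size`, random sign) on `n_affected_species` in the disease arm,
independent log-normal per-sample noise (`noise_sd`), optional dropout, and
compositional closure (every sample renormalized to sum to 1). The
production map is drawn as independent coin flips at `production_density`.
Defaults (50 species, 20 metabolites, 20 samples per arm, density 0.2, 10
affected species, effect 2, noise 0.5) are the strong-signal conditions used
in the validation studies.

Ground truth is recorded in two forms, and the distinction matters:

* **Realized truth** — per metabolite, the sign of the sum of realized
  post-closure median changes over its producers: an exact statement about
  the generated table. When the top-$N$ cut retains every species, the
  pipeline's score *is* this sum, so recovery against realized truth is
  exact by construction; the informative regimes are those with filters
  biting ($N$ below the species count, producer minima).
* **Planted truth** — the direction implied by the planted effects alone,
  defined on the *closed* scale: $\mathrm{softmax}(b + \mathrm{shift}) -
  \mathrm{softmax}(b)$. The pre-closure version ($e^{b+\mathrm{shift}} -
  e^b$) is the wrong target under compositionality: closure drags every
  unaffected species down when up-effects dominate, and recovery against
  pre-closure signs actually *degrades* at large effects. Against the
  closed planted direction, recovery climbs monotonically with effect size,
  which is the property the test suite checks over a three-point grid.

Under a null cohort (effect 0) the realized truth is still defined — from
noise — and is tautologically recovered by a full-retention scorer reading
the same data. Chance-level behavior is therefore assessed against truth
realized in an *independent* null replicate, whose labels are independent of
the scored data; agreement is then a coin flip, and the test suite checks
it sits within Monte-Carlo error of 50%.

What the generator does **not** emulate: ecological interactions,
phylogenetic correlation between species, sequencing-depth or compositional
zero-inflation structure beyond independent dropout, batch effects, and
cohort heterogeneity. Passing tests therefore demonstrate correctness of
the pipeline's arithmetic and its behavior under the model's own
assumptions — not performance on real repository data.

## Calibration: an honest caveat

The null-calibration study (500 replicates of 40 species, 12 metabolites, 8
samples per arm — sizes chosen to make hundreds of full pipeline runs cheap
while keeping roughly ten defined tests per replicate) observes a rejection
rate of defined p-values near 0.03 at nominal 0.05. This is not a defect of
the t-test implementation (which matches the closed form to 1e-10); it is a
real property of the method: the per-species median differences feeding the
test have scales proportional to each species' baseline abundance, and a
one-sample t-test on such a lognormal scale mixture is conservative —
heavy-tailed heterogeneity inflates the sample standard deviation more than
the mean. The effect would shrink if species abundances were homogeneous,
but three-orders-of-magnitude spread is what real profiles look like. The
practical reading: under the null the pipeline *under*-claims significance,
so its p-values and FDRs err on the safe side; nominal uniformity should
not be assumed when interpreting them as exact error rates.

## Validation study sizes

The test suite runs the score against a brute-force term-by-term oracle on
1000 random instances (machine-precision agreement), checks antisymmetry
and linearity on 500 random cases, cross-checks t-test and BH against
closed-form references on 200 random vectors each, and runs the calibration
and recovery studies at the sizes above (500 null replicates; 20
strong-signal seeds; an 8-seed, 3-point effect grid). These sizes were
chosen so the whole suite completes in about a minute on one CPU while
keeping Monte-Carlo error small relative to the bands being checked.

## Known limitations

* Equal-contribution, linear production is a first-order model; taxa differ
  in metabolic flux, and weighting by functional capacity is a natural
  refinement.
* The t-test across species treats species as exchangeable units; their
  median differences are heteroscedastic (see the calibration caveat) and
  weakly dependent through closure.
* Strain-to-species collapsing treats any producing strain as making the
  whole species a producer; species abundance then proxies strain abundance.
* The literature benchmark depends entirely on the coverage and correctness
  of the supplied validation table; pairs without records are reported as
  unevaluated rather than silently dropped, and that bookkeeping should be
  inspected alongside the headline percentage.
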