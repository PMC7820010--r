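---
title: "Methods: the two-step genetic DLBCL classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step genetic DLBCL classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlbcl2s)
```

## Scope and rationale

Genetic DLBCL subtypes (N1, MCD, BN2, EZB, ST2) were originally defined by
probabilistic classifiers and cohort-level clustering that require large
marker sets and, for some subtypes, copy-number data. `dlbcl2s` implements
a minimal rule system intended for prospective, single-sample use on a
targeted panel: 26 genes scored as mutated/wild-type plus BCL2 and BCL6
break-apart FISH. The A53 (TP53/aneuploidy) subtype is deliberately out of
scope because it cannot be called without copy-number information, and no
composite (e.g. EZB/N1) genotypes are emitted — each sample receives
exactly one label or UNCLASSIFIED.

## The rule system

Let $G$ be the sample's set of mutated genes after filtering, and let each
subtype $s$ have a step-1 list $L_1(s)$ and extended list
$L(s) = L_1(s) \cup L_2(s)$.

1. **N1 precedence.** If any N1 step-1 marker is hit (NOTCH1 in the
   default panel), the call is N1 at step 1, independent of all scores.
   This hard precedence encodes the observation that NOTCH1-mutant disease
   behaves as its own aggressive entity even when co-mutations point
   elsewhere.
2. **Step 1.** For $s \in \{MCD, BN2, EZB, ST2\}$ compute
   $c_1(s) = \sum_{f \in L_1(s)} \mathbf{1}[f\ \text{hit}]$. If the
   maximum is attained by exactly one subtype and is $\ge 1$, assign it.
3. **Step 2.** Otherwise (a tie at the maximum, or all step-1 scores 0)
   compute $c_2(s) = \sum_{f \in L(s)} \mathbf{1}[f\ \text{hit}]$ over the
   same four subtypes. A unique maximum $\ge 2$ assigns the subtype;
   anything else is UNCLASSIFIED.

Feature hits are binary: a gene feature is hit iff the gene is mutated; a
translocation feature iff the FISH status is `present`.

### Design choices where the rule was genuinely open

These points were underdetermined by the rule statement alone; the package
fixes them as follows and records the scores on every call so that
alternative readings can be audited.

* **Step-1 winner.** A step-1 assignment requires a *strict, unique*
  maximum. Any tie at the maximum — two-way or more — defers to step 2;
  step 1 never breaks ties by list order.
* **Step-2 candidates.** All four non-N1 subtypes compete at step 2, not
  only those tied at step 1, and the ≥ 2 threshold applies to the combined
  step-1 ∪ step-2 list. A sample with zero step-1 hits but two step-2
  markers of one subtype is therefore classifiable.
* **Step-2 ties.** A tie at the step-2 maximum, or all scores < 2, yields
  UNCLASSIFIED; there is no third step.
* **The BCL2 feature.** `BCL2` in the EZB step-1 list is hit by BCL2
  mutation *or* BCL2 translocation, contributing at most 1. This reflects
  the tight association between the two lesions in germinal-center
  lymphomas and the classifier's announcement as "26 genes plus BCL2 and
  BCL6 translocations", while keeping EZB's step-1 list at three
  features. A custom panel can instead use the `BCL2_TRANSLOC` token to
  separate the two signals; no cross-check against the original authors'
  implementation was possible, so calls driven by translocation-only BCL2
  deserve scrutiny in critical applications.
* **Unknown FISH.** An unknown translocation status scores 0 and raises a
  `FISH_UNKNOWN` flag on the call rather than blocking classification:
  FISH is routinely unavailable for a sizable fraction of archival
  samples, and a mutation-only call is still informative. The flag lets
  downstream users treat BN2/EZB calls (and non-calls) on FISH-less
  samples with appropriate caution.
* **Cohort definition.** The mutation matrix defines the cohort: FISH
  entries for unknown samples are ignored with a warning, and panel genes
  absent from the matrix are treated as wild-type for all samples, again
  with a warning, so that a panel/matrix vocabulary mismatch is loud but
  not fatal.

## Variant filtering

`filter_variants()` implements the post-annotation filter producing the
binary matrix: total read depth ≥ 50, variant-supporting reads ≥ 5,
VAF ≥ 5 %, localization in {exonic, 5'UTR, 3'UTR, splice site}, a
non-synonymous effect class (missense, nonsense, stop-loss, splicing,
frameshift and in-frame indels), and exclusion of population
polymorphisms. Quality thresholds are inclusive (≥) and the population
threshold strict (<), exactly as stated. Two interpretation points:

* "MAF < 0.01 %" is read literally as a population allele frequency below
  `1e-4` (fraction). Pipelines that intended 1 % can set
  `filter_config(max_pop_af = 0.01)`.
* A variant listed in no database (no population frequency annotation,
  `is_known_snp = FALSE`) passes the polymorphism criterion.

Filtering is per-record, order-preserving, idempotent, and monotone in
every threshold; these are tested properties, not accidents.

## Fisher-exact marker ranking

`rank_genes()` is a panel-curation utility: per gene it forms the 2×2
table (mutated vs wild-type × in-subtype vs rest) and computes the
two-sided exact p-value under the standard convention (total probability
of tables with point mass ≤ the observed one), via `stats::fisher.test`.
The test suite checks it against an independent hypergeometric enumeration
for every table with n ≤ 20. The odds ratio is $(ad)/(bc)$ with
`Inf`/`0` on single zero cells; the fully degenerate 0/0 case is reported
as 1 with a `zero_cell` flag. The shipped default panel is fixed — it was
selected with external-cohort sensitivity/specificity trials that cannot
be reproduced from a single cohort — so the ranking supports building
alternative panels, not re-deriving the default.

## Concordance

`concordance()` evaluates a test labelling against a reference one subtype
at a time, one-vs-rest: positives carry the subtype label, everything else
(including UNCLASSIFIED) is negative. Sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP); a zero denominator yields `NA`, never 0.
Reference-unclassified samples are kept as negatives by default — the only
reading under which a test call on a reference-unclassified sample can
cost specificity, which is how published comparisons against classifiers
with large unclassified fractions behave —
with `exclude_unclassified_reference = TRUE` as the alternative.
Percentages are rounded half-up to one decimal for reporting; raw
fractions are kept internally.

## The synthetic-cohort simulator

`simulate_cohort()` draws each sample from one latent subtype (or a
subtype-free background class `NONE`): own-subtype step-1 features are
Bernoulli(`marker_penetrance` = 0.8), own step-2 features
Bernoulli(`step2_penetrance` = 0.4), every other panel feature
Bernoulli(`background_rate` = 0.02), and each sample's FISH status is
masked to unknown with probability `fish_missing_rate` = 0.3 (both probes
together, as missingness is driven by tissue availability). The default
composition (5 N1, 14 MCD, 18 BN2, 25 EZB, 10 ST2, 12 background = 84
samples) mirrors the subtype mix of a published diagnostic series, giving
the defaults a realistic class imbalance. All draws come from one seeded
generator; a fixed seed reproduces the cohort bit-identically, and the
caller's RNG state is left untouched.

What the simulator does *not* emulate: co-mutation and mutual-exclusivity
structure, subtype-specific background rates, VAF/read-level noise,
subclonality, and panel dropout. Passing recovery tests therefore
demonstrates that the rule logic is implemented correctly and behaves
sensibly under independent-feature noise — not that the classifier attains
any particular accuracy on real tumors, where marker correlation is the
norm.

## Numerical and degenerate-input choices

* All counts are small integers; there is no floating-point tie ambiguity
  in scoring.
* Empty cohorts classify to an empty call set; an all-zero matrix yields
  all-UNCLASSIFIED; a missing FISH table yields flagged, mutation-only
  calls.
* Duplicate sample or gene identifiers, non-binary matrix cells, and
  malformed FISH tokens are hard errors with coordinates, because silent
  repair of identity columns corrupts cohorts.
* Gene symbols are matched by exact uppercase string with no
  alias/synonym resolution; a mismatch surfaces as a "panel gene absent"
  warning rather than a silent zero. The one normalization applied is
  that the step-2 MCD marker is spelled PRDM1 (its HGNC symbol).

## Problem sizes in the shipped tests

The suite exercises: 10,000 random feature sets for the N1-precedence
property; every 2×2 table with n ≤ 20 against the Fisher oracle;
600-sample property sweeps of score bookkeeping; a 2,000-sample
law-of-large-numbers check of the simulator's marginals; and a
1,000-sample recovery study at penetrance 0.9 / background 0.01 whose N1
recall is checked against exact binomial 99 % bounds around 0.9. These
sizes keep the full suite under a minute on a laptop while leaving the
statistical assertions well-powered.

## Known limitations

* Two end-to-end tests assert the published subtype counts and mutational
  profile of the 84-sample cohort the classifier was first applied to;
  the per-sample supplementary tables are not redistributable, so those
  tests fail unless the tables are supplied locally (see
  `tests/testthat/test-acceptance.R`).
* No A53 subtype, no composite genotypes, no probabilistic confidence —
  the classifier is intentionally a transparent rule system.
* Panel-vocabulary genes only: the classifier never looks outside the 26
  genes and two translocations, so matrix columns beyond the panel are
  ignored.
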