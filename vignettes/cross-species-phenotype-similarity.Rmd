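---
title: "Cross-species phenotype similarity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species phenotype similarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The problem

Large-scale mouse knockout phenotyping programmes annotate each mutant
line with Mammalian Phenotype (MP) ontology terms, while Mendelian
disorders are annotated with Human Phenotype Ontology (HPO) terms. When a
knockout's gene has a one-to-one human ortholog associated with a
disease, the two phenotype profiles can be compared over a merged
ontology in which the two vocabularies hang off shared ancestor terms.
phenomatch implements this comparison — a PhenoDigm-style percentage
score — together with the surrounding pipeline: catalogue validation, a
bidirectional one-to-one ortholog filter, match calling, gene-level
aggregation, novelty calling against an external model catalogue, a
lethality-based rescue rule, and an association layer that asks which
model, gene and disease features predict a phenotype match.

## The score

All similarity is computed over the merged DAG's `is_a` hierarchy.
Writing $A(t)$ for the *reflexive* ancestor set of a term, the package
uses:

* **Information content.** $IC(t) = -\ln\big(\mathrm{count}(t)/N\big)$,
  where $\mathrm{count}(t)$ is the number of corpus entities annotated to
  $t$ or any descendant and $N$ is the corpus size. The default corpus is
  the union of all disease HPO sets and all model MP sets handed to the
  pipeline; it is an explicit argument because no single canonical corpus
  exists for a merged graph. Natural log is used throughout. Terms never
  annotated get the bounded maximum $\ln N$ rather than infinity, and
  roots are 0 by construction.
* **Pairwise term similarity.**
  $s(q,h) = \sqrt{J(q,h)\cdot IC(\mathrm{MICA}(q,h))}$, the geometric
  mean of the Jaccard index of the two reflexive ancestor sets and the
  information content of the most-informative common ancestor. IC-only
  and Jaccard-only forms are available behind the `form` argument, but
  the default is fixed so results are reproducible.
* **Profile score.** The disease's HPO terms are the queries. Each query
  keeps its best-matching model MP term; the maximum and the mean of
  these best scores are each divided by the disease's self-comparison
  optimum (what a model mimicking every disease phenotype exactly would
  achieve, $\max_t \sqrt{IC(t)}$ and $\mathrm{mean}_t \sqrt{IC(t)}$) and
  averaged with equal weight, then scaled to a percentage and clamped to
  $[0, 100]$. A pair scores 0 exactly when no query shares an informative
  (positive-IC) ancestor with any model term. A *match* is a pair — or,
  after aggregation, a gene — with a strictly positive percentage.

Directionality is an assumption, not an accident: the disease is the
query profile, so adding HPO terms to a disease tends to lower its score
while adding MP terms to a model can only improve it. A symmetric variant
(`bidirectional = TRUE`) averages the two directions and is off by
default. The mean is taken over query terms only, matching the anchored
direction.

### Exact cross-species equivalence

Under this pairwise form, two *distinct* terms can never attain the
query's self-similarity ceiling: their Jaccard index is strictly below 1.
Real merged ontologies handle exactly-equivalent HP/MP concepts (for
example the same biochemical abnormality named in both vocabularies) by
bridging them into one class, for which the ceiling is attainable. The
package adopts the same convention: exact cross-species equivalents are
represented as a single shared term, and the calibration mode of the
generator (`mirror_copy = TRUE`) annotates a model with the disease's own
shared term ids, which scores exactly 100.00. Mirrored-but-distinct
leaves, the generator's normal mode, yield partial scores strictly
between 0 and 100 — which is also what real cross-species matches look
like.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `min_support` | `one_to_one_orthologs()` | 5 | at least 5 of the 12 orthology prediction services must agree |
| `form` | scoring functions | `"geometric"` | geometric mean of Jaccard and MICA IC |
| `bidirectional` | `phenodigm_score()` | `FALSE` | disease HPO terms are the queries |
| corpus | `information_content()` | study union | no canonical corpus for a merged graph; explicit and overridable |
| `include_childhood` | `lethality_rescue()` | `FALSE` | the stricter pre-infant rule is the primary rescue |
| `conf_level` | stats layer | 0.95 | conventional Wald intervals |

The ortholog threshold is applied **before** the bijectivity test, so a
low-support paralog cannot veto a well-supported one-to-one pair. A
consequence worth knowing: raising `min_support` does not always shrink
the mapping, because dropping a paralog can un-veto a pair. The test
suite pins this behaviour down with an explicit counter-example.

Ties are broken deterministically everywhere: MICA ties on IC go to the
lexicographically smallest term id, best-match ties to the smallest hit
id, and gene-level ties on the best percentage to the smallest
(model id, disease id) pair. None of these affect score values, only
reported identities.

## The synthetic study

Real consortium releases, disease annotation dumps and curated ortholog
files cannot ship with a package, so every layer is exercised on a
generated study whose statistical structure is planted and therefore
recoverable. The defaults are the stated world and are not tuned per
test:

* ~2400 disease-associated genes, matching the scale of a current
  knockout-phenotyping release, with an expected gene-level match rate
  calibrated to 55%;
* homozygote viability mix of 24% lethal / 8% subviable / 68% viable;
  lethal genes contribute a homozygous embryo model plus a heterozygous
  early-adult model, other genes one homozygous (rarely hemizygous)
  early-adult model;
* pair-level match propensity follows a logistic model with planted
  coefficients (+0.35 procedures completed, +0.8 MP terms, −0.45 HPO
  terms per SD; +0.4 homozygous, +0.6 early death) plus per-category odds
  multipliers (endocrine ×3, respiratory ×0.75), the qualitative pattern
  reported for real data; the intercept is solved by `uniroot()` so the
  expected gene-level match rate hits the target;
* 3–12 HPO terms per disease and 1–10 MP terms per model, order-of-
  magnitude choices for ontology annotation profiles, with MP counts
  weakly coupled to procedure counts.

The generator makes the realised pipeline outcome equal the planted
label *exactly*: a matched pair's model carries mirror images of some of
its disease's HPO terms (sharing an informative system ancestor), while
an unmatched pair's model draws all its terms from phenotype systems
disjoint from the gene's diseases, so the only shared ancestor is the
root, whose IC is identically 0. This is deliberately cleaner than real
data, where weak incidental overlaps blur the boundary. A green
recovery test therefore establishes that the scorer, the aggregation
rules and the statistical layer do what they claim on data whose truth
is known — not that the defaults reproduce any real release's counts,
which depend on curation and on ontologies orders of magnitude larger
than the toy graph.

Determinism: one seed governs the study, with fixed per-table sub-seeds
derived from it, so regenerating only part of a study (for example the
truth table without annotation sets, `annotations = FALSE`) reproduces
identical draws. Two runs with the same configuration are byte-identical
on disk.

## Numerical and statistical choices

* Percentages are computed and compared at full double precision;
  writers round to 2 decimals, the conventional reporting precision.
  Match calling uses the unrounded value, strictly greater than 0.
* Odds ratios are the sample `ad/bc` with a Wald log-scale CI, reported
  as `Inf` when `bc = 0` with `a, d > 0` and as missing when a margin is
  empty; p-values come from Fisher's exact test and are BH-adjusted over
  the family of categories tested. Genes annotated to several categories
  contribute to each category's table.
* Enrichment is computed per gene; the regression per model–disease
  pair. Both units are reported because multiple models and multiple
  disorders per gene are the rule, not the exception.
* The logistic fit standardises continuous covariates, one-hot encodes
  categorical ones against declared references (heterozygous, viable,
  `AR`, first category), pools hemizygous with homozygous, and treats
  early death as a binary indicator. Non-convergence and separation are
  errors, never silent.
* The ±2 SE recovery criterion for planted continuous coefficients is a
  ~95% nominal-coverage statement per coefficient; the acceptance test
  requires it in ≥90% of replicates per coefficient rather than jointly,
  since joint coverage of three coefficients is ~86% by construction.

## Known limitations

* Only `is_a` edges are honoured; `part_of` and logical definitions are
  out of scope, as is OWL/JSON parsing. The merged OBO must already
  contain the cross-species bridge.
* Obsolete terms are dropped at parse time and annotations to them are a
  hard error; no `replaced_by` chasing.
* All eligible models are scored against the same disease HPO set
  regardless of life stage; aligning embryo models with stage-matched
  human phenotypes is future work.
* The toy ontology's IC range is compressed relative to vocabularies
  with tens of thousands of terms, so synthetic percentage scores
  cluster more tightly than real score distributions.
* Viability is an input label; the package does not recompute it from
  breeding counts.
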