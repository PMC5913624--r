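---
title: "Discovering mechanistic intermediates from two literatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering mechanistic intermediates from two literatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmech)
```

## The discovery model

`litmech` operationalises the ABC model of literature-based discovery: if
concept A relates to intermediate X in one literature, and X relates to
outcome B in another, then A → X → B is a candidate mechanism even though no
single article states it. The raw material is two annotation layers over a
corpus of articles:

* **Predications**: directed subject–PREDICATE–object triples extracted from
  titles and abstracts, with the subject and object drawn from a controlled
  concept vocabulary (in real data, UMLS concept identifiers) and the
  predicate from a closed relation vocabulary (`INHIBITS`,
  `ASSOCIATED_WITH`, ...).
* **MeSH annotations**: curated descriptors per article, with a major-topic
  flag; descriptors live in a tree of dot-separated position codes, whose
  minimum depth we use as a specificity measure.

Concept identity is the identifier string; names are display-only. Triples
are directed: `(x, P, y)` and `(y, P, x)` are different statements, and the
chaining step deliberately honours that direction (see Limitations).

### Why enrichment, not raw co-occurrence

Counting shared terms between two article sets drowns signal in ubiquitous
terms and in extraction noise. Two design rules counter this:

1. **Distinct-article counting.** A term's support inside a set is the number
   of *distinct member articles* containing it, never the number of mentions,
   so a single enthusiastic abstract cannot manufacture enrichment.
2. **Enrichment against the corpus background.** A term qualifies only if its
   set frequency is improbable under its global frequency. We form the
   disjoint 2×2 table for each key,

   |            | with key | without key |
   |------------|----------|-------------|
   | in set     | a        | b           |
   | outside    | c = g − a| d           |

   with `g` the key's distinct-article corpus frequency and the "outside"
   row excluding set members (a disjoint table is the standard exact-test
   formulation; the counting conventions are recorded in each result's
   metadata). The two-tailed Fisher's exact test p-value is the sum of
   hypergeometric probabilities of all tables with the observed margins that
   are no more probable than the observed one, using a `1e-7` relative
   tolerance for ties — the convention of the reference implementations.
   P-values are corrected per (set, method) family with the
   Benjamini–Hochberg step-up (`adj_i = min_{j ≥ i} m·p_j / j`, clipped to 1,
   implemented literally in that form), and keys survive at corrected
   *P* < `alpha`, default `1e-5`. Keys with a single supporting article are
   tested rather than pre-excluded: with the default cutoff they cannot
   survive unless the set is very small, which is the desired behaviour.

   Degenerate tables (a zero margin) carry no evidence and return *p* = 1.
   The odds ratio is the sample estimate `(a·d)/(b·c)`, with `Inf` as the
   sentinel whenever `b·c = 0`.

### Chaining and the linking-term threshold

For triple results, a mechanism chain is emitted for every enriched A-triple
`(s₁, P₁, x)` and enriched B-triple `(x, P₂, o₂)` sharing the linking term
`x` — a cartesian join, so two A-triples and three B-triples through the same
`x` yield six chains. The linking term must fall **below** a global
occurrence threshold; this single filter removes "Patients"/"Cells"-class
terms that would otherwise dominate. Two deliberate scope choices:

* The threshold applies only to the *linking position* (A-objects /
  B-subjects), not to the outer subject and object.
* All predicates are kept: chains through common predicates such as
  `ASSOCIATED_WITH` can still be informative and are handled downstream by
  the predicate-frequency-rank (PFR) filter instead of a hard predicate cut.

**Counting units.** The store keeps two global frequencies per concept:
distinct articles, and (article, slot) occurrences where one article
contributes separately for the concept-as-subject and concept-as-object.
Published threshold values for full predication databases (150,000) are
occurrence-scale numbers, so the linking filter compares against the
occurrence count; enrichment tables stay in article units on both sides so
the 2×2 is unit-consistent. On synthetic or reduced corpora the threshold
must be rescaled — the default study configuration uses 100.

### Ranking and filtering

The balance score `min(uniq_a, uniq_b)/max(uniq_a, uniq_b) × (uniq_a +
uniq_b)` promotes elements supported by many articles *on both sides*:
(5, 5) → 10 beats (1, 100) → 1.01 despite the smaller total. It intentionally
risks burying mechanisms with genuinely one-sided literatures, which is why
three alternative orderings exist (mean corrected *P* ascending; min of the
two predicate ranks, rarer first; MeSH depth, deeper first). All orderings
break ties by total support then lexicographic identity, so every ordering is
total and reproducible.

Filters apply in a fixed stage order — corrected *P*, odds ratio, PFR/depth,
keywords, top-N — with survivor counts recorded per stage. Keyword matching
is case-insensitive substring matching on any of the five chain positions
(an exact-match mode exists); "include" lists restrict, "exclude" lists
remove. The first-view dynamic defaults are a package parameterisation of a
stated behaviour ("relax filters when results are few"), not a published
rule: ≤ 50 results pass through; ≤ 1000 truncate to the top 100 by score;
above that the 5 globally most frequent predicates are also cut. All four
numbers are arguments of `dynamic_defaults()` and are written into run
metadata.

## The synthetic study corpus

`generate_corpus()` emulates the statistical structure the method relies on,
with known ground truth:

* two article sets of 200 plus 2,000 background articles;
* a 500-concept vocabulary whose background usage follows a Zipf
  rank-frequency law (exponent 1.2 — a realistic skew for term frequencies in
  text), sampled independently of set membership so background keys carry no
  true signal;
* five planted chains at penetrance 0.1, placed in an *exact*
  `ceiling(penetrance × n)` number of member articles (a Bernoulli mode
  exists for power studies; exact placement keeps the contingency tables of
  the planted keys deterministic so statistical behaviour can be tested
  separately from sampling noise);
* three injected ubiquitous concepts scattered corpus-wide (rate 0.3 per
  article) whose occurrence counts sit far above the rescaled linking
  threshold of 100, each also forming a *decoy chain* at planted penetrance —
  enriched on both sides, and correctly removed by the linking filter alone;
* a MeSH layer mirroring the concept layer (descriptor = concept with a `D`
  prefix), with planted annotations deterministic and background annotations
  subject to 30% dropout plus non-major noise, so the `mesh`, `concept` and
  `triple` methods are all testable from one corpus.

Planted and common concepts are reserved out of the background vocabulary:
the planted signal is clean by construction. Real corpora differ in ways the
generator does not emulate — extraction errors correlated with writing style,
synonymous concepts with distinct identifiers, publication-date structure,
and literatures of very unequal size — so passing recovery tests demonstrate
the engine's correctness and statistical calibration, not end-to-end
performance on MEDLINE-scale data.

With these defaults, across 20 seeds, the pipeline recovers all planted
chains (recall 1.0) with the five planted chains occupying the top ranks by
score, no decoy chain survives the linking filter, and on background-only
corpora no key reaches corrected *P* < 1e-5 (the acceptance script and
`test-acceptance.R` recompute exactly these quantities).

## Numerical and engineering choices

* **Exact test implementation**: vectorised summation of `dhyper` masses over
  the support, with the `1e-7` relative tie tolerance. Unit tests check it
  against both an independent log-binomial enumeration oracle (to `1e-10`)
  and `stats::fisher.test`.
* **BH implementation**: the step-up definition is coded directly (the
  algebraically identical `stats::p.adjust` associates the multiplication
  differently and can differ in the last ulp; it remains a cross-check).
* **Caching**: enrichment results are stored per (set, method) as TSV with
  17-significant-digit doubles (lossless round-trip) plus a JSON manifest
  keyed by store fingerprint (MD5 over a canonical serialisation of the
  indexes), member hash and alpha. A mismatched fingerprint triggers
  recomputation with a warning, never silent reuse.
* **Determinism**: store construction sorts inputs, so any row order yields
  identical indexes and byte-identical exports; predicate ranks break count
  ties alphabetically; result orderings are total.
* **Degenerate inputs**: empty enrichment tables, empty chain sets and empty
  export documents are valid values, not errors; an article set with no
  coverage in the store is an error, since no denominator exists.
* **Problem sizes**: the validation suite uses 20–50-article toy corpora for
  oracle-equivalence checks and 20 replicates of the 2,400-article default
  study for recovery and type-I checks — sizes at which exhaustive oracles
  are feasible while leaving every statistical quantity well inside its
  asymptotic regime of interest.

## Limitations

* **Directionality.** Chains run strictly A-object → B-subject. Predicates
  such as `PART_OF` or `ASSOCIATED_WITH` are not logically directional, so
  true intermediates expressed in the reverse orientation are missed; the
  restriction is kept because removing it trades a few true positives for
  many false ones. No predicate-symmetry inference is attempted.
* **Single-step chains only.** Multi-step paths (A → X → Y → B) are not
  enumerated by the core algorithm; the network export makes them visible to
  a human reader.
* **The literature is a biased sample.** Enrichment inherits publication
  bias, extraction bias and curation bias; results are hypotheses to be
  triaged against the linked supporting articles (which is why every chain
  carries its per-side PubMed ID lists), never conclusions.
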