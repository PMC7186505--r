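---
title: "Multi-evidence gene prioritization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence gene prioritization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evigene)
```

## The integration model

`evigene` integrates candidate-gene lists produced by heterogeneous
computational prioritization methods. The model is deliberately simple:
each evidence *source* — a method-dataset combination — contributes one
point to every gene it nominates, and a gene's cumulative score is the
number of distinct sources attesting it. The rationale is that the methods
draw on complementary signals (eQTL colocalization, protein-interaction
connectivity, co-function networks, predicted gene function), so genes
genuinely involved in disease susceptibility should recur across several of
them, while method-specific artifacts should not.

The assumptions this encodes are worth stating explicitly:

- **Equal weights.** Every source counts 1. A per-source weight vector is
  accepted in principle by filtering or duplicating sources, but the
  default is all-ones: without a calibration dataset there is no principled
  way to set differential weights, and equal weighting is transparent.
- **Sources are counted by label.** The same algorithm applied to two
  datasets forms two sources and can contribute two points. This matters in
  practice: in the packaged worked example one gene reaches the
  high-confidence tier only because an eQTL-colocalization method was run
  on two expression datasets.
- **Conditional independence is not assumed but also not corrected for.**
  Two network-based methods sharing an interaction database are positively
  correlated; the score makes no attempt to deflate this. The synthetic
  generator therefore offers correlated false positives as a stress test
  (by configuring shared sampling), and the limitation is discussed below.

Ranking is score-descending with ties broken by gene symbol: within a score
tier no evidence distinguishes genes, so the tie-break is purely for
determinism of outputs and tests.

## Identifier normalization

Gene symbols drift between resources (the same phosphatase gene appears as
`PPAP2B` in one table and `PLPP3` in another). All loaders push symbols
through `normalize_genes()`: upper-case, trim, then apply a user-supplied
alias table (`alias_map()`), which must be idempotent — chains of aliases
are rejected at construction. No online identifier resolution is performed;
reproducibility of a run must not depend on the current state of a web
service. Records whose symbol is empty after trimming are dropped with a
warning rather than failing a whole source file.

## Filtering helpers

Two small operations recur in this kind of analysis and are exposed
directly. `bonferroni_threshold(alpha, n)` is `alpha / n`, used for
per-gene significance cutoffs (0.05 over 5,747 tested genes gives 8.7e-6;
over 25 tissues, 0.002). `smr_heidi_filter()` implements the two-step
retention rule of summary-data Mendelian randomization: keep a gene only
when its association p-value is below the corrected threshold *and* its
heterogeneity (HEIDI) p-value is at least 0.05 — a low heterogeneity
p-value indicates linkage of distinct causal variants rather than a shared
one, so such genes are discarded. The rule errors, rather than guesses,
when heterogeneity p-values are missing.

## Enrichment statistics

The pathway-enrichment statistic is the one-sided hypergeometric upper
tail: the probability of observing at least the actual overlap when the
query is drawn uniformly without replacement from the background universe.
For the 2x2 margins involved this is identical to a one-sided Fisher exact
test; the package uses the hypergeometric formulation for pathways and the
Fisher formulation in the tissue module (mirroring how each analysis is
conventionally described), and a test asserts their numerical equality on
shared margins. Only over-representation is tested; depletion is not of
interest in this design.

The **background universe** is the single most consequential free choice in
enrichment analysis. The default is the union of all genes in the loaded
collection, overridable explicitly. Published enrichment p-values from web
services are generally *not* reproducible without knowing their background
and annotation version, which is why this package treats such printed
values as context rather than assertions.

Multiple-testing correction uses Benjamini-Hochberg (`bh_adjust()`, the
standard step-up) across the sets of a collection, with Bonferroni values
reported alongside. P-values are kept at full double precision; formatting
belongs to the report layer.

## Tissue specificity

The tissue module consumes a precomputed gene x tissue specificity-index
(pSI) matrix; deriving pSI from raw expression is out of scope and the
synthetic generator emits the matrix directly. A gene is tissue-enriched
when its pSI is *strictly* below the cutoff (default 0.05); missing values
never qualify. Candidate overlap per tissue is a one-sided Fisher exact
test over the matrix's gene universe, with the significance flag at
`alpha / n_tissues` (0.002 for 25 tissues at alpha 0.05).

## Network permutation test

The connectivity statistic of a gene set is its within-set edge count.
Because all null sets have the same size, the count and any density
normalization order identically, so the raw count is used. The null is
1,000 gene sets drawn uniformly without replacement from the network's
node set; significance is summarized as
`z = (observed - null_mean) / null_sd` with a one-sided upper-tail normal
p-value, and an empirical permutation p-value `(r + 1) / (n + 1)` is
reported alongside as a finite-sample safeguard.

Two deliberate choices:

- **Uniform, not degree-matched, null sampling** is the default, matching
  the plain "random gene sets" formulation. Uniform nulls are
  anti-conservative for hub-rich query sets; users testing sets suspected
  of being degree-biased should interpret the z accordingly or pre-filter
  hubs. Degree-aware sampling was considered and left out of the default
  because it changes the null hypothesis being tested.
- **Degenerate nulls are flagged, not hidden.** On a vertex-transitive
  graph (e.g. a complete graph) every same-size set has the same count;
  the null standard deviation is zero, `z` is undefined and the p-value is
  set to 1 (or 0 if the observed count exceeds the constant null) with a
  message.

Genes absent from the network are dropped *before* sizing the null sets;
padding the null with absent genes would deflate the null mean and inflate
significance. The seed is a required argument: identical seed and inputs
give bit-identical results.

## Pathway crosstalk

Crosstalk connects enriched pathways through their shared *candidate*
genes (not their full annotated membership). Three inclusion rules are
applied: adjusted p < 0.05, at least 3 candidate genes per pathway, and at
least 2 shared candidates per retained pair. Each edge carries the Jaccard
coefficient `JC = |A∩B| / |A∪B|`, the overlap coefficient
`OC = |A∩B| / min(|A|, |B|)` (always ≥ JC) and their arithmetic mean as
weight.

Centralities (degree, normalized betweenness) are computed on the
*unweighted* retained graph: the weights are overlap summaries for display
width, not distances, and treating them as either lengths or capacities
would assert semantics the analysis does not carry. Betweenness is
normalized by the number of non-endpoint pairs; rankings are invariant to
this, the normalization is fixed only so tests are deterministic.

Isolated eligible pathways are kept in the node report but excluded from
component sizes. This convention affects "module" counts: on the packaged
24-pathway worked example, exhaustive application of the three rules gives
a 73-edge graph whose largest connected component has 19 pathways, with a
separate 2-pathway component and one isolate. Alternative conventions —
for instance attaching small satellite components or isolates to the main
module when drawing the network — would report a larger module from the
same graph; this package reports exactly what its stated rules compute,
and the component partition is asserted in the test suite.

## The synthetic benchmark

`generate_synthetic_data()` emits every pipeline input with known planted
structure and a seed that makes all files byte-identical across runs. Its
defaults are the package's reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2,000 | universe size (symbols `G000001`...) |
| `n_true` | 200 | planted causal genes |
| `sources` | 9 at sensitivity 0.8, 20 FP | per-source Bernoulli reporting plus uniform false positives |
| `n_pathways`, size | 50, 10-40 | annotation sets; first 3 draw 80% of members from true genes |
| `network_n_nodes` | 300 | module genes plus background sample |
| `background_edge_prob` / `module_edge_prob` | 0.05 / 0.5 | Erdős–Rényi background with an upgraded 30-gene module block |
| `n_tissues` | 25 | pSI matrix width; planted entries drawn below quantile 0.01 |

Per-source reporting is independent Bernoulli given the truth — the
simplest generative model consistent with the consensus-scoring rationale.
Nine sources at sensitivity ≥ 0.7 with ≤ 20 false positives over a
2,000-gene universe put a true gene's score at Binomial(9, 0.8) against a
false gene's Binomial(9, ≈0.011), which is why the score ≥ 3 tier recovers
essentially all planted genes at high precision; the test suite checks
≥ 90% recovery and ≥ 95% precision averaged over 50 seeds.

What the generator does **not** emulate: correlated method errors from
shared databases by default, realistic degree distributions (the network
background is Erdős–Rényi, not scale-free), linkage-disequilibrium
structure among sources' false positives, and pSI values derived from
actual expression profiles. Passing tests on this benchmark therefore
demonstrate the pipeline's correctness and calibration under its stated
model, not robustness to all failure modes of real data — in particular,
uniform-null network tests on hub-rich real sets remain anti-conservative
as noted above.

Gene symbols are synthetic (`G000001`...) to avoid implying claims about
real genes in test output.

## Numerical and testing choices

- The permutation-test calibration check uses a 120-node Erdős–Rényi
  network with 1,000 independent runs of 300 permutations each, and the
  module-rejection check 100 seeds at 1,000 permutations on 300-node
  networks; these sizes make the Monte-Carlo error small relative to the
  asserted bounds (|mean z| < 0.1, sd in [0.85, 1.15]) while keeping the
  suite quick.
- Exhaustive enumeration oracles (all C(N, q) draws) back the
  hypergeometric tail for universes up to 25; beyond that the identity
  with `phyper` is relied upon.
- Ties and orderings everywhere are broken deterministically (score then
  symbol; p-value then set id) so byte-identical reruns are a testable
  contract.
- Degenerate inputs have defined behavior rather than errors where a
  convention exists (empty query: p = 1; pSI cutoff 0: empty sets) and
  errors where none does (two empty sets in a Jaccard coefficient; missing
  heterogeneity p-values).

## Known limitations

Equal weighting cannot downweight correlated or low-quality sources; the
score is a vote count, not a posterior. The enrichment module does not
traverse ontology graphs or propagate annotations. The tissue module
inherits whatever tissue grouping the supplied pSI matrix encodes. The
crosstalk "key pathway" question — how to combine degree and betweenness
into a single selection — is left to the analyst; the package reports both
rankings and does not fabricate a composite criterion.
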