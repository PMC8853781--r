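---
title: "Syndrome recommendation from a clinical knowledge graph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syndrome recommendation from a clinical knowledge graph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A traditional Chinese medicine (TCM) consultation records its evidence in a
handful of free-text fields — tongue inspection, pulse taking, listening and
smelling, inspection, body surface examination, diagnosis of TCM — and ends
in a *syndrome*, the diagnostic category that drives treatment. The central
obstacle to predicting the syndrome from the evidence is **symptom overlap**:
in large clinical corpora the same symptom string ("two-inch floating pulse")
recurs under many different syndromes, with per-field repetition rates
around 86–98%. No single finding is decisive, so classification approaches
that score a record as a bag of features struggle to separate closely
related syndromes.

`dsds` treats diagnosis as **knowledge-graph completion** instead. Records
are decomposed into typed (head, relation, tail) triples; a link-prediction
model learns to score candidate tails; an unseen record is *dismantled* into
one tail-missing query per symptom, and the per-query answers are combined
by **frequency voting** so that the plurality of the evidence, not any
single high-scoring symptom, decides.

## The knowledge graph

For every record, each segmented token $s$ of field type $t$ yields two
triples:

* $(\text{method}_t,\ \texttt{performance of } t,\ s)$ — the examination
  method exhibits the finding;
* $(s,\ \texttt{t-syndrome},\ y)$ — the finding supports the record's
  syndrome $y$.

Entity identity is the pair (name, field type): identical strings observed
under two field types are distinct entities, matching the eight-way typing
of the corpus statistics. Triples are deduplicated across records.
Two structural choices were genuinely open and are resolved as follows:

* **Shared method nodes.** Per-record method nodes would fragment the graph
  into record-sized islands and play no role in prediction; one global
  method node per field type keeps the graph connected.
* **Nursing precautions** stay in the graph (they enrich training) but
  their relations carry a `diagnostic = FALSE` flag and are never queried
  at prediction time, since care instructions are a consequence of a
  diagnosis, not evidence for one.

Segmentation is punctuation splitting only, over a configurable set of
ASCII and full-width separators; no synonym table and no sub-token analysis
are applied, so tokens compare by exact string equality. This is faithful
to how the target corpora were curated, and it means out-of-vocabulary
variants of a known symptom are skipped, not fuzzily matched.

## The embedding model

Entities and relations are embedded in $\mathbb{C}^d$ and a triple is scored
by the ComplEx function

$$\phi(h, l, t) = \mathrm{Re}\,\langle e_h, e_l, \bar e_t\rangle
  = \mathrm{Re}\sum_{k=1}^d e_h[k]\, e_l[k]\, \overline{e_t[k]},$$

the real part of the Hermitian three-way product. A purely real relation
vector makes $\phi$ symmetric in $(h, t)$, a purely imaginary one
antisymmetric — both are exercised as property tests. Training minimises a
pointwise logistic loss, $+1$ for graph triples and $-1$ for sampled
corruptions, with L2 regularisation.

Numerical choices:

* **Negative sampling is type-aware**: a corruption replaces the tail with
  a uniformly drawn entity *of the relation's legal tail type* (syndrome
  relations corrupt within syndromes). This mirrors restricting prediction
  to syndrome candidate sets and makes the learned contrasts the ones that
  matter for ranking. Corruptions colliding with the positive's own tail
  are redrawn (bounded retries), because with desk-scale syndrome
  vocabularies such collisions are frequent enough to invert the intended
  sign of positive scores.
* **Optimizer.** Plain fixed-rate SGD is available but diverges easily
  here: syndrome entities are hubs that accumulate hundreds of summed
  gradient contributions per minibatch. The default is AdaGrad, the
  optimizer used in the original ComplEx work, whose per-coordinate step
  normalisation absorbs exactly this imbalance.
* **Initialisation** is seeded Gaussian ($\sigma = 0.1$) on both planes;
  every stochastic component (init, shuffling, corruption draws) derives
  from the single config seed, so training is bit-reproducible.
* **Defaults** ($d = 100$, 200 epochs, learning rate 0.05, 20 negatives
  per positive, reg $10^{-3}$) are package choices, not published facts —
  the reference work reports no hyperparameters. Tests and the synthetic
  recovery experiment use smaller, faster settings ($d = 16$–$25$, 40–60
  epochs), which suffice at desk scale.

## Dismantling and scoring-and-voting

A test record is segmented, each in-vocabulary token becomes a query
$(h, \texttt{t-syndrome}, ?)$, and an $m \times n$ matrix of scores over
the $n$ candidate syndromes is filled. The aggregation wraps a frequency
operator around the per-query scores: each query contributes its top-$k$
candidates; syndromes are ranked by the number of shortlists they appear on,
ties broken by summed score across appearances, then by ascending entity id.
The published description of this aggregation is a one-line formula whose
precise reading is ambiguous; the per-query top-$k$ shortlist reading
implemented here is the one consistent with its surrounding prose (the
highest single score is explicitly *not* to be trusted; all symptoms are to
be judged comprehensively). Because $k$ could also be read as a global score
threshold, it is exposed as a parameter (default 10) rather than fixed.

Useful consequences, all property-tested: the output is invariant to query
and candidate order; vote counts are integers in $[1, m]$; and the ranking
for a larger $N$ extends the ranking for a smaller $N$ as a prefix, which
is what makes top-1/top-3/top-5 accuracy necessarily monotone.

## Evaluation

Metrics are the weighted one-vs-rest family: per class
$\mathrm{Precision}_i = TP_i/(TP_i+FP_i)$,
$\mathrm{Recall}_i = TP_i/(TP_i+FN_i)$, weights proportional to true class
sizes, weighted precision/recall as weight-averaged sums, F1 as their
harmonic mean, accuracy as the fraction of exact top-1 matches, and top-N
accuracy as the fraction of records whose label appears in the first $N$
recommendations. As printed in the reference formulas, the weighted sums
carry an extra division by the class count $L$; combined with
proportional weights that double-normalises and leaves $[0, 1/L]$-bounded
values, so the standard weighted average is the default and the literal
variant is kept behind `divide_by_L = TRUE` for comparison. A class that is
never predicted receives precision 0; classes present only among
predictions receive weight 0.

## What the synthetic generator does and does not emulate

The clinical corpus the method was developed on is proprietary, so the
package ships a generator with *planted* structure: per field type, each
syndrome owns a private token pool and all syndromes share a common pool;
`shared_pool_fraction` sets the share of a syndrome's pool that is common
and is the direct control for cross-syndrome symptom overlap; records
subsample their pools; `noise_rate` swaps tokens in from unrelated
syndromes. Defaults state a desk-scale world: 20 syndromes × 30 records,
pools of 8 tokens per field type, 60% subsampling, no overlap, no noise.
Token strings are synthetic identifiers — the method is string-agnostic, so
imitating clinical Chinese would add nothing testable.

The generator reproduces the *structure* that matters (typed fields,
many-records-per-syndrome, controllable overlap) but not real symptom
frequency distributions, field-length skew, or misspelling/variant noise.
A green recovery test therefore establishes that the pipeline recovers
planted symptom–syndrome structure at the stated overlap, not that it
attains any particular accuracy on real clinical text: with zero overlap
top-1 recovery is essentially perfect, and at 50% overlap top-1 degrades
while top-5 stays high — the qualitative monotone pattern the voting
design targets — but the published headline accuracies from the
108,746-record corpus are expressly not reproduction targets.

## Degenerate inputs and edge policies

* Empty field text segments to an empty token list; a record whose every
  token is out-of-vocabulary (or that has only nursing text) is "not
  diagnosable" and raises an error — the evaluation harness counts such
  records as wrong rather than dropping them.
* `shared_pool_fraction` high enough to leave zero private tokens makes
  syndromes indistinguishable by construction and is rejected.
* Tab and newline are forbidden inside field values (bit-exact TSV
  round-trips beat escaping); values are otherwise arbitrary UTF-8.
* Score ties anywhere are broken by ascending entity id, so every ranking
  is deterministic.

## Known limitations

Exact-string token matching transfers poorly across corpora with different
curation conventions; the embedding trainer is single-threaded base R and
is sized for desk-scale graphs (tens of thousands of triples), not the
million-triple graphs of a production registry; and the literal reading of
the published aggregation formula, as well as two internally inconsistent
rows of the published corpus statistics table, cannot be settled from the
source — the package documents the choices it makes in each case rather
than forcing numbers to agree.
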