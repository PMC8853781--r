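# dsds — syndrome diagnosis recommendation from clinical knowledge graphs

`dsds` is an R implementation of a decision-support pipeline for syndrome
diagnosis in traditional Chinese medicine (TCM). A consultation record
carries free-text evidence in up to seven diagnostic fields (tongue
inspection, pulse taking, listening and smelling, inspection, body surface
examination, diagnosis of TCM, nursing precautions) and a *syndrome* label.
Because the same symptom string recurs under many syndromes (per-field
repetition rates of 86–98% in large clinical corpora), no single finding is
decisive. The package therefore:

1. **builds a typed knowledge graph** from records — per segmented token
   `s` of field type `t` with syndrome `y`, two triples:
   `(method_t, performance of t, s)` and `(s, t-syndrome, y)`;
2. **learns ComplEx embeddings** — entities and relations in ℂ^d, a triple
   scored by the real part of the Hermitian three-way product
   `φ(h,l,t) = Re Σ_k e_h[k]·e_l[k]·conj(e_t[k])`, trained with a logistic
   loss over graph triples and type-aware sampled corruptions;
3. **recommends syndromes by scoring-and-voting** — an unseen record is
   dismantled into one tail-missing query `(symptom, t-syndrome, ?)` per
   in-vocabulary token, each query shortlists its top-k candidates by
   score, and syndromes are ranked by how many shortlists they appear on
   (ties: summed score, then id), returning the top-N;
4. **evaluates** with weighted one-vs-rest precision/recall/F1, accuracy
   and top-N accuracy over a seeded train/test split.

Clinical corpora of this kind are proprietary, so the package includes a
synthetic-corpus generator with planted symptom–syndrome structure and a
controllable cross-syndrome overlap rate, which drives all tests.

## Worked example

```r
library(dsds)

gen <- generate_corpus(synth_config(n_syndromes = 6, records_per_syndrome = 10,
                                    shared_pool_fraction = 0.25, seed = 42))
kg  <- build_kg(gen$records)
kg
#> <dsds_kg> 279 entities, 14 relations, 602 triples

emb <- train_model(kg, train_config(d = 16, epochs = 40, lr = 0.1,
                                    negatives = 5, seed = 42))

rec <- gen$records[1, ]                      # true label: "syndrome 01"
out <- recommend(rec, kg, emb, k = 3, N = 3)
out$syndrome <- kg$entities$name[out$syndrome]
out
#>      syndrome count score_sum
#> 1 syndrome 01    22  78.22222
#> 2 syndrome 02    15 -58.79971
#> 3 syndrome 05    13 -52.22904
```

The record dismantled into m = 26 symptom queries over n = 6 candidate
syndromes; "syndrome 01" appeared on 22 of the 26 per-query shortlists with
a positive summed score, so it is recommended at rank 1 — despite 25% of
each syndrome's symptom pool being shared with other syndromes, which is
exactly the ambiguity the vote (rather than any single best-scoring
symptom) resolves.

```r
rpt <- evaluate_split(gen$records, seed = 42,
                      config = train_config(d = 16, epochs = 40, lr = 0.1,
                                            negatives = 5))
rpt
#> <metrics_report> L = 5 | weighted P/R/F1 = 1.0000/1.0000/1.0000 | accuracy = 1.0000
#>   top-N accuracy: top-1 1.0000, top-3 1.0000, top-5 1.0000
```

At this modest overlap the planted structure is recovered perfectly on the
held-out 20%; raising `shared_pool_fraction` to 0.5 degrades top-1 while
top-5 stays high (see `recovery_experiment()` and the methods vignette).

A command-line entry point covers the same pipeline: see `?dsds_cli`
(`simulate`, `corpus`, `kg`, `train`, `predict`, `evaluate`, `run`
subcommands; the launcher script installs to `exec/dsds`).

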