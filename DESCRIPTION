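Package: dsds
Title: Syndrome Diagnosis Recommendation from Clinical Knowledge Graphs
Version: 0.1.0
Authors@R: person("DSDS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Builds a typed knowledge graph from electronic medical records of
    traditional Chinese medicine (TCM), learns complex-valued link-prediction
    embeddings (ComplEx), and recommends top-N syndromes for an unseen record
    by dismantling it into tail-missing queries and aggregating per-query
    candidate shortlists with frequency voting. Includes a synthetic-corpus
    generator with planted symptom-syndrome structure and controllable
    cross-syndrome symptom overlap, weighted multiclass evaluation metrics,
    and an end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
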