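# Fixtures are built in code; nothing is read from disk.

# three records, one deterministic pulse symptom each -> separable toy graph
toy_corpus <- function() {
  emr_corpus(fields = list(pulse_taking = c("A1", "A2", "A3"),
                           tongue_inspection = c("B1", "B2", "B3")),
             syndrome = c("S1", "S2", "S3"))
}

toy_kg <- function() build_kg(toy_corpus())

# a richer mixed-field corpus for round trips and statistics
mixed_corpus <- function() {
  emr_corpus(
    record_id = sprintf("M%02d", 1:5),
    fields = list(
      pulse_taking = c("two-inch floating pulse", "deep pulse,slow pulse",
                       "", "two-inch floating pulse", "stringlike pulse"),
      tongue_inspection = c("white and thin tongue fur", "red tongue",
                            "red tongue", "", "white and thin tongue fur"),
      nursing_precautions = c("keep warm", "", "keep warm,light diet", "", ""),
      inspection = c("", "pale face", "", "pale face", "")),
    syndrome = c("S1", "S2", "S2", "S1", "S3"))
}

random_embeddings <- function(n_ent, n_rel, d, seed = 1) {
  set.seed(seed)
  rmat <- function(n) matrix(complex(real = rnorm(n * d),
                                     imaginary = rnorm(n * d)), n, d)
  dsds:::new_complex_embeddings(rmat(n_ent), rmat(n_rel), train_config(d = d))
}

# naive per-component complex-arithmetic scoring oracle
oracle_score <- function(h, l, t, emb) {
  acc <- 0
  for (k in seq_len(emb$d)) {
    eh <- emb$entities[h, k]; el <- emb$relations[l, k]
    et <- emb$entities[t, k]
    prod <- eh * el * complex(real = Re(et), imaginary = -Im(et))
    acc <- acc + Re(prod)
  }
  acc
}

# independent weighted-metrics reference built on table(), not on the
# per_class_counts() path
oracle_weighted_metrics <- function(preds, truths) {
  classes <- sort(unique(c(preds, truths)))
  cm <- table(factor(truths, classes), factor(preds, classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  w <- rowSums(cm) / length(truths)
  wp <- sum(prec * w); wr <- sum(rec * w)
  list(wp = wp, wr = wr,
       wf1 = if (wp + wr > 0) 2 * wp * wr / (wp + wr) else 0,
       acc = sum(tp) / length(truths))
}

# brute-force score-and-vote oracle: enumerate shortlists by sorting
oracle_vote <- function(mat, k, N) {
  cand <- as.integer(colnames(mat))
  tally <- list()
  for (i in seq_len(nrow(mat))) {
    ord <- order(-mat[i, ], cand)[seq_len(k)]
    for (j in ord) {
      key <- as.character(cand[j])
      prev <- tally[[key]]
      tally[[key]] <- c((if (is.null(prev)) 0 else prev[1]) + 1,
                        (if (is.null(prev)) 0 else prev[2]) + mat[i, j])
    }
  }
  df <- data.frame(syndrome = as.integer(names(tally)),
                   count = vapply(tally, `[`, 0, 1),
                   score_sum = vapply(tally, `[`, 0, 2))
  df <- df[order(-df$count, -df$score_sum, df$syndrome), ]
  rownames(df) <- NULL
  head(df, N)
}

# small, fast training config for harness-level tests
fast_train <- function(seed = 1L)
  train_config(d = 16L, epochs = 40L, lr = 0.1, negatives = 5L,
               batch_size = 256L, seed = seed)
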