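#' Per-class one-vs-rest confusion counts
#'
#' For every class appearing in `truths` or `predictions`: `TP` (predicted
#' as the class and truly of it), `FP` (predicted as the class but truly
#' another), `FN` (truly of the class but predicted another).
#'
#' @param predictions Character vector of top-1 predicted labels.
#' @param truths Character vector of true labels, same length.
#' @return Data frame with columns `class`, `TP`, `FP`, `FN`, `N` (true
#'   class size), sorted by class.
#' @export
per_class_counts <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  if (!length(truths)) stop("empty label vectors")
  classes <- sort(unique(c(truths, predictions)))
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  out$TP <- vapply(classes, function(cl)
    sum(predictions == cl & truths == cl), 0L)
  out$FP <- vapply(classes, function(cl)
    sum(predictions == cl & truths != cl), 0L)
  out$FN <- vapply(classes, function(cl)
    sum(predictions != cl & truths == cl), 0L)
  out$N <- vapply(classes, function(cl) sum(truths == cl), 0L)
  out
}

#' Weighted multiclass metrics report
#'
#' Per class: `Precision_i = TP/(TP+FP)` and `Recall_i = TP/(TP+FN)` (a
#' class never predicted gets precision 0 by convention).  Class weights
#' are the true class proportions, `W_i = N_i / sum(N)` (classes absent
#' from the truths get weight 0).  Weighted precision/recall are
#' `sum(metric_i * W_i)`; weighted F1 is their harmonic mean; accuracy is
#' the fraction of exact top-1 matches.
#'
#' A literal variant that additionally divides the weighted sums by the
#' number of classes `L` is available via `divide_by_L = TRUE` for
#' comparison; the default form is the standard weighted average, the only
#' one bounded by `[0, 1]` for all inputs.
#'
#' @param predictions,truths Label vectors as in [per_class_counts()].
#' @param top_n_hits Optional named list: for each N, a logical vector
#'   marking records whose truth appeared in the top-N recommendation.
#' @param divide_by_L Apply the extra `1/L` normalisation.
#' @return A `metrics_report` list: `per_class` table (with `precision`,
#'   `recall`, `weight`), `L`, `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`, `accuracy`, `top_n` (named numeric vector).
#' @export
weighted_report <- function(predictions, truths, top_n_hits = NULL,
                            divide_by_L = FALSE) {
  counts <- per_class_counts(predictions, truths)
  prec <- ifelse(counts$TP + counts$FP > 0, counts$TP / (counts$TP + counts$FP), 0)
  rec <- ifelse(counts$TP + counts$FN > 0, counts$TP / (counts$TP + counts$FN), 0)
  w <- counts$N / sum(counts$N)
  counts$precision <- prec; counts$recall <- rec; counts$weight <- w
  L <- nrow(counts)
  denom <- if (divide_by_L) L else 1
  wp <- sum(prec * w) / denom
  wr <- sum(rec * w) / denom
  wf1 <- if (wp + wr > 0) 2 * wp * wr / (wp + wr) else 0
  acc <- mean(predictions == truths)
  topn <- if (!is.null(top_n_hits))
    vapply(top_n_hits, mean, 0) else stats::setNames(numeric(0), character(0))
  structure(list(per_class = counts, L = L, weighted_precision = wp,
                 weighted_recall = wr, weighted_f1 = wf1, accuracy = acc,
                 top_n = topn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> L =", x$L,
      "| weighted P/R/F1 =", sprintf("%.4f/%.4f/%.4f", x$weighted_precision,
                                     x$weighted_recall, x$weighted_f1),
      "| accuracy =", sprintf("%.4f", x$accuracy), "\n")
  if (length(x$top_n))
    cat("  top-N accuracy:",
        paste(sprintf("top-%s %.4f", names(x$top_n), x$top_n), collapse = ", "),
        "\n")
  invisible(x)
}

#' Top-N accuracy of a recommendation set
#'
#' Fraction of records whose true label appears among the first `N`
#' recommended syndromes.  An empty recommendation counts as wrong for
#' every `N`.
#'
#' @param recommendations List (one element per record) of character
#'   vectors of recommended syndrome names in rank order.
#' @param truths Character vector of true labels.
#' @param N Cut-off rank.
#' @return Fraction in `[0, 1]`.
#' @export
top_n_accuracy <- function(recommendations, truths, N) {
  stopifnot(N >= 1L, length(recommendations) == length(truths))
  hits <- mapply(function(rec, tr)
    length(rec) > 0 && tr %in% utils::head(rec, N),
    recommendations, truths)
  mean(hits)
}

#' Train/test evaluation harness
#'
#' Seeded shuffle-split by record; the knowledge graph and embeddings are
#' built from the training partition only, every test record is dismantled
#' and scored against the training graph's syndromes, and weighted metrics
#' plus top-N accuracies are reported.  Test records that are not
#' diagnosable (no in-vocabulary symptom) receive an empty recommendation
#' and count as wrong.
#'
#' @param corpus A labelled `emr_corpus`.
#' @param train_frac Fraction of records assigned to training.
#' @param seed Seed controlling the split, initialisation and sampling.
#' @param config A [train_config()] (its seed is overridden by `seed`).
#' @param k Shortlist size for [score_and_vote()].
#' @param top_n Vector of N values to report.
#' @param punctuation Separator set.
#' @return A `metrics_report`; attributes `split` (record ids per
#'   partition) and `recommendations` (per-record ranked syndrome names).
#' @export
evaluate_split <- function(corpus, train_frac = 0.8, seed = 1L,
                           config = train_config(), k = 10L,
                           top_n = c(1L, 3L, 5L),
                           punctuation = default_punctuation()) {
  corpus <- validate_corpus(corpus, require_labels = TRUE)
  n <- nrow(corpus)
  set.seed(seed)
  ntr <- floor(train_frac * n)
  if (ntr < 1L || ntr >= n)
    stop("split leaves an empty partition (n = ", n, ", train = ", ntr, ")")
  perm <- sample.int(n)
  tr_idx <- sort(perm[seq_len(ntr)])
  te_idx <- sort(perm[(ntr + 1L):n])
  train <- new_emr_corpus(as.data.frame(corpus)[tr_idx, , drop = FALSE])
  test <- new_emr_corpus(as.data.frame(corpus)[te_idx, , drop = FALSE])

  kg <- build_kg(train, punctuation = punctuation)
  config$seed <- as.integer(seed)
  emb <- train_model(kg, config)

  syn_ids <- kg_syndrome_ids(kg)
  syn_names <- stats::setNames(kg$entities$name, kg$entities$id)
  recs <- vector("list", nrow(test))
  max_n <- max(top_n)
  for (i in seq_len(nrow(test))) {
    row <- new_emr_corpus(as.data.frame(test)[i, , drop = FALSE])
    rec <- tryCatch(
      suppressWarnings(recommend(row, kg, emb, k = k, N = max_n,
                                 candidates = syn_ids,
                                 punctuation = punctuation)),
      error = function(e) NULL)
    recs[[i]] <- if (is.null(rec)) character(0) else
      unname(syn_names[as.character(rec$syndrome)])
  }
  truths <- test$syndrome
  preds <- vapply(recs, function(r)
    if (length(r)) r[[1L]] else "<none>", "")
  hits <- lapply(stats::setNames(top_n, top_n), function(N)
    vapply(seq_along(recs), function(i)
      length(recs[[i]]) > 0 && truths[[i]] %in% utils::head(recs[[i]], N),
      logical(1L)))
  rep <- weighted_report(preds, truths, top_n_hits = hits)
  attr(rep, "split") <- list(train = train$record_id, test = test$record_id)
  attr(rep, "recommendations") <- stats::setNames(recs, test$record_id)
  rep
}
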