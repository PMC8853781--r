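#' Dismantle a record into tail-missing queries
#'
#' Segments every diagnostic field of the record (nursing precautions are
#' excluded: they are never evidence for a diagnosis), maps each token to a
#' known symptom entity of the matching field type, and pairs it with that
#' field's `{t}-syndrome` relation, yielding one `(h, l, ?)` query per
#' resolvable token.  Tokens absent from the vocabulary are skipped with a
#' warning; a record with zero resolvable queries is not diagnosable and
#' raises an error.
#'
#' @param record A single-row `emr_corpus` (or one row of one).
#' @param kg The `dsds_kg` the embeddings were trained on.
#' @param punctuation Separator set for [segment_field()].
#' @return Data frame with columns `h` (symptom entity id), `l` (relation
#'   id), `field_type`, `token`, in order of appearance.
#' @export
dismantle_record <- function(record, kg, punctuation = default_punctuation()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  rel <- kg$relations
  ss <- rel[rel$kind == "symptom_syndrome" & rel$diagnostic, , drop = FALSE]
  ent <- kg$entities
  rows <- list(); unknown <- character(0)
  for (ft in intersect(diagnostic_field_types(), ss$field_type)) {
    toks <- segment_field(as.character(record[[ft]][1L]), punctuation)
    if (!length(toks)) next
    ids <- ent$id[match(paste(ft, toks, sep = "\r"),
                        paste(ent$etype, ent$name, sep = "\r"))]
    if (anyNA(ids))
      unknown <- c(unknown, paste0(ft, ":", toks[is.na(ids)]))
    keep <- !is.na(ids)
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        h = ids[keep], l = ss$id[ss$field_type == ft],
        field_type = ft, token = toks[keep], stringsAsFactors = FALSE)
  }
  if (length(unknown))
    warning("skipping out-of-vocabulary token(s): ",
            paste(unknown, collapse = ", "))
  if (!length(rows))
    stop("record not diagnosable: no resolvable symptom queries")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the m x n candidate score matrix
#'
#' For `m` queries and `n` candidate syndromes, entry `(i, j)` is the
#' Hermitian-product score of the completed triple
#' `(queries$h[i], queries$l[i], candidates[j])`.
#'
#' @param queries Data frame from [dismantle_record()] (columns `h`, `l`).
#' @param candidates Non-empty integer vector of syndrome entity ids.
#' @param emb A `complex_embeddings`.
#' @return `m x n` numeric matrix; `dimnames` carry query row indices and
#'   candidate ids.
#' @export
build_candidate_matrix <- function(queries, candidates, emb) {
  if (!nrow(queries)) stop("no queries")
  if (!length(candidates)) stop("empty candidate set")
  # phi(h, l, c) = Re( (e_h * e_l) %*% Conj(e_c)^T ), all candidates at once
  HL <- emb$entities[queries$h, , drop = FALSE] *
    emb$relations[queries$l, , drop = FALSE]
  C <- emb$entities[candidates, , drop = FALSE]
  m <- Re(HL %*% t(Conj(C)))
  dimnames(m) <- list(seq_len(nrow(queries)), candidates)
  m
}

#' Aggregate per-query scores into a top-N recommendation
#'
#' The scoring-and-voting aggregation: each query row contributes its top
#' `k` candidates by score (score ties broken by ascending candidate id);
#' every syndrome is then ranked by how many shortlists it appears on
#' (frequency statistics), with ties broken by its summed score across
#' appearances and finally by ascending id.  A single symptom's best score
#' is deliberately not decisive — overlapping symptoms make the plurality
#' across all queries the better signal.
#'
#' @param matrix Score matrix from [build_candidate_matrix()].
#' @param k Per-query shortlist size, `1 <= k <= ncol(matrix)`.
#' @param N Maximum recommendations returned.
#' @return Data frame with columns `syndrome` (entity id), `count`,
#'   `score_sum`, at most `N` rows, in rank order.  Attribute `shortlists`
#'   holds the per-query shortlist for audit.
#' @export
score_and_vote <- function(matrix, k = 10L, N = 5L) {
  stopifnot(is.matrix(matrix), N >= 1L)
  n <- ncol(matrix); m <- nrow(matrix)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  cand <- as.integer(colnames(matrix))
  shortlists <- lapply(seq_len(m), function(i) {
    ord <- order(-matrix[i, ], cand)[seq_len(k)]
    data.frame(syndrome = cand[ord], score = matrix[i, ord])
  })
  pooled <- do.call(rbind, shortlists)
  cnt <- rowsum(rep(1L, nrow(pooled)), pooled$syndrome)
  ssum <- rowsum(pooled$score, pooled$syndrome)
  agg <- data.frame(syndrome = as.integer(rownames(cnt)),
                    count = as.integer(cnt), score_sum = as.numeric(ssum))
  agg <- agg[order(-agg$count, -agg$score_sum, agg$syndrome), , drop = FALSE]
  out <- utils::head(agg, N)
  rownames(out) <- NULL
  attr(out, "shortlists") <- shortlists
  out
}

#' Recommend top-N syndromes for a record
#'
#' End-to-end composition: dismantle the record into queries, score every
#' candidate syndrome per query, and aggregate with [score_and_vote()].
#'
#' @inheritParams dismantle_record
#' @param emb A `complex_embeddings` trained on `kg`.
#' @param k Per-query shortlist size (capped at the candidate count).
#' @param N Maximum recommendations.
#' @param candidates Syndrome entity ids to consider; defaults to every
#'   syndrome entity in `kg`.  A restricted syndrome group may be supplied
#'   to narrow the prediction to clinically similar syndromes.
#' @return As [score_and_vote()]; attribute `queries` carries the dismantled
#'   query table, `m` and `n` the matrix dimensions.
#' @export
recommend <- function(record, kg, emb, k = 10L, N = 5L, candidates = NULL,
                      punctuation = default_punctuation()) {
  if (is.null(candidates)) candidates <- kg_syndrome_ids(kg)
  queries <- dismantle_record(record, kg, punctuation)
  mat <- build_candidate_matrix(queries, candidates, emb)
  rec <- score_and_vote(mat, k = min(k, ncol(mat)), N = N)
  attr(rec, "queries") <- queries
  attr(rec, "m") <- nrow(mat)
  attr(rec, "n") <- ncol(mat)
  rec
}
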