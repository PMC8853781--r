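make_row <- function(...) {
  co <- emr_corpus(fields = list(...), syndrome = NA)
  dsds:::new_emr_corpus(as.data.frame(co)[1, , drop = FALSE])
}

test_that("dismantle_record maps tokens to field-typed queries", {
  kg <- build_kg(emr_corpus(
    fields = list(pulse_taking = "two-inch floating pulse",
                  tongue_inspection = "white and thin tongue fur",
                  nursing_precautions = "keep warm"),
    syndrome = "S"))
  rec <- make_row(pulse_taking = "two-inch floating pulse",
                  tongue_inspection = "white and thin tongue fur",
                  nursing_precautions = "keep warm")
  q <- dismantle_record(rec, kg)
  expect_equal(nrow(q), 2L)   # nursing evidence is never queried
  rname <- setNames(kg$relations$name, kg$relations$id)
  expect_setequal(paste(q$token, rname[as.character(q$l)]),
                  c("two-inch floating pulse pulse_taking-syndrome",
                    "white and thin tongue fur tongue_inspection-syndrome"))
  expect_true(all(kg$entities$etype[q$h] == q$field_type))

  # nursing-only record is not diagnosable
  expect_error(dismantle_record(make_row(nursing_precautions = "keep warm"), kg),
               "not diagnosable")
  # out-of-vocabulary tokens warn, all-unknown errors
  expect_warning(dismantle_record(
    make_row(pulse_taking = "two-inch floating pulse,unseen pulse"), kg),
    "out-of-vocabulary")
  expect_error(suppressWarnings(
    dismantle_record(make_row(pulse_taking = "unseen pulse"), kg)),
    "not diagnosable")
})

test_that("build_candidate_matrix equals the element-wise scoring loop", {
  emb <- random_embeddings(40, 5, 7, seed = 13)
  queries <- data.frame(h = c(1L, 4L, 9L, 2L, 7L), l = c(1L, 2L, 3L, 4L, 5L))
  cand <- c(11L, 13L, 17L, 19L, 23L, 29L, 31L)
  mat <- build_candidate_matrix(queries, cand, emb)
  expect_equal(dim(mat), c(5L, 7L))
  for (i in 1:5) for (j in 1:7)
    expect_equal(mat[i, j], oracle_score(queries$h[i], queries$l[i],
                                         cand[j], emb), tolerance = 1e-9)
  # permuting candidates permutes columns identically
  perm <- c(3L, 1L, 7L, 5L, 2L, 6L, 4L)
  expect_equal(unname(build_candidate_matrix(queries, cand[perm], emb)),
               unname(mat[, perm]))
  # 1x1 case reduces to score_triple
  expect_equal(as.numeric(build_candidate_matrix(queries[1, ], cand[1], emb)),
               score_triple(queries$h[1], queries$l[1], cand[1], emb))
  expect_error(build_candidate_matrix(queries, integer(0), emb),
               "empty candidate")
})

test_that("score_and_vote counts shortlist occurrences with the stated tie-breaks", {
  # shortlists {S1:5, S2:3}, {S2:4, S1:2}, {S1:6, S3:1} -> S1(3), S2(2), S3(1)
  mat <- rbind(c(5, 3, 0),
               c(2, 4, -1),
               c(6, -2, 1))
  dimnames(mat) <- list(1:3, c(101L, 102L, 103L))
  rec <- score_and_vote(mat, k = 2L, N = 5L)
  expect_equal(rec$syndrome, c(101L, 102L, 103L))
  expect_equal(rec$count, c(3L, 2L, 1L))
  expect_equal(rec$score_sum, c(5 + 2 + 6, 3 + 4, 1))
  expect_equal(rec, oracle_vote(mat, 2L, 5L), ignore_attr = TRUE)

  # equal counts fall back to summed score
  mat2 <- rbind(c(5, 4, -9), c(4, 3, -9))
  dimnames(mat2) <- list(1:2, c(1L, 2L, 3L))
  rec2 <- score_and_vote(mat2, k = 2L, N = 2L)
  expect_equal(rec2$syndrome, c(1L, 2L))      # 9 > 7
  expect_equal(rec2$score_sum, c(9, 7))

  # m = 1, k = 1: single best candidate with count 1
  one <- score_and_vote(mat[1, , drop = FALSE], k = 1L, N = 3L)
  expect_equal(one$syndrome, 101L)
  expect_equal(one$count, 1L)

  # score ties within a row shortlist break by ascending id
  tie <- matrix(c(1, 1, 0), 1, dimnames = list(1, c(7L, 5L, 9L)))
  expect_equal(score_and_vote(tie, k = 1L, N = 1L)$syndrome, 5L)

  expect_error(score_and_vote(mat, k = 4L), "k must be")
})

test_that("score_and_vote output is invariant to query and candidate order", {
  set.seed(17)
  for (i in 1:20) {
    m <- sample(2:6, 1); n <- sample(3:8, 1); k <- sample(seq_len(n), 1)
    mat <- matrix(rnorm(m * n), m, n,
                  dimnames = list(seq_len(m), sample(1000L, n)))
    base <- score_and_vote(mat, k, N = n)
    qperm <- sample(m); cperm <- sample(n)
    shuffled <- mat[qperm, cperm, drop = FALSE]
    expect_equal(base, score_and_vote(shuffled, k, N = n),
                 ignore_attr = TRUE)
    expect_equal(base, oracle_vote(mat, k, n), ignore_attr = TRUE)
    # counts are integers in [1, m], total bounded by m * k
    expect_true(all(base$count >= 1L & base$count <= m))
    expect_lte(sum(base$count), m * k)
    # prefix property: smaller N is a prefix of larger N
    for (N in seq_len(nrow(base)))
      expect_equal(score_and_vote(mat, k, N), base[seq_len(N), ],
                   ignore_attr = TRUE)
  }
})

test_that("recommend composes the stages end to end", {
  kg <- toy_kg()
  emb <- train_model(kg, train_config(d = 8L, epochs = 200L, lr = 0.1,
                                      negatives = 5L, batch_size = 16L,
                                      seed = 2L))
  # A2 occurs under exactly one training syndrome -> that syndrome ranks 1
  rec <- recommend(make_row(pulse_taking = "A2"), kg, emb, k = 1L, N = 3L)
  expect_equal(kg$entities$name[rec$syndrome[1]], "S2")
  expect_true(all(kg$entities$etype[rec$syndrome] == "syndrome"))
  # N beyond the distinct shortlisted syndromes returns a shorter list
  expect_lte(nrow(recommend(make_row(pulse_taking = "A2"), kg, emb,
                            k = 1L, N = 10L)), 10L)
  # k = n makes every count m, so ordering falls back to summed score
  rec2 <- recommend(make_row(pulse_taking = "A1", tongue_inspection = "B1"),
                    kg, emb, k = 3L, N = 3L)
  expect_true(all(rec2$count == 2L))
  q <- attr(rec2, "queries")
  mat <- build_candidate_matrix(q, dsds:::kg_syndrome_ids(kg), emb)
  sums <- colSums(mat)
  expect_equal(rec2$score_sum, unname(sort(sums, decreasing = TRUE)))
})
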