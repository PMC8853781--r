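test_that("score_triple computes the Hermitian three-way product", {
  # all-zero embeddings score zero
  z <- dsds:::new_complex_embeddings(matrix(0+0i, 2, 3), matrix(0+0i, 1, 3),
                                     train_config(d = 3))
  expect_equal(score_triple(1L, 1L, 2L, z), 0)
  # d = 1 hand case: Re((1+i) * i * Conj(1-i)) = Re((1+i) * i * (1+i)) = -2
  e <- dsds:::new_complex_embeddings(matrix(c(1+1i, 1-1i), 2, 1),
                                     matrix(0+1i, 1, 1), train_config(d = 1))
  expect_equal(score_triple(1L, 1L, 2L, e), -2)
  expect_error(score_triple(3L, 1L, 1L, e), "entity id")
  expect_error(score_triple(1L, 2L, 1L, e), "relation id")
})

test_that("score_triple agrees with the naive complex-arithmetic oracle", {
  emb <- random_embeddings(30, 6, 12, seed = 21)
  set.seed(22)
  for (i in 1:100) {
    h <- sample(30, 1); l <- sample(6, 1); t <- sample(30, 1)
    expect_equal(score_triple(h, l, t, emb), oracle_score(h, l, t, emb),
                 tolerance = 1e-9)
  }
})

test_that("real relations score symmetrically, imaginary ones antisymmetrically", {
  set.seed(33)
  for (i in 1:100) {
    d <- sample(2:8, 1)
    eh <- complex(real = rnorm(d), imaginary = rnorm(d))
    et <- complex(real = rnorm(d), imaginary = rnorm(d))
    re_rel <- complex(real = rnorm(d), imaginary = rep(0, d))
    im_rel <- complex(real = rep(0, d), imaginary = rnorm(d))
    emb_re <- dsds:::new_complex_embeddings(rbind(eh, et), rbind(re_rel),
                                            train_config(d = d))
    emb_im <- dsds:::new_complex_embeddings(rbind(eh, et), rbind(im_rel),
                                            train_config(d = d))
    expect_equal(score_triple(1L, 1L, 2L, emb_re),
                 score_triple(2L, 1L, 1L, emb_re), tolerance = 1e-12)
    expect_equal(score_triple(1L, 1L, 2L, emb_im),
                 -score_triple(2L, 1L, 1L, emb_im), tolerance = 1e-12)
  }
})

test_that("sample_negatives respects type pools, filtering and the seed", {
  kg <- toy_kg()
  ss <- kg$triples[kg$relations$kind[kg$triples$l] == "symptom_syndrome", ]
  tri <- as.integer(ss[1, ])
  # only 3 syndromes: filtered corruption must avoid the true tail
  set.seed(1)
  neg <- sample_negatives(tri, kg, 20, mode = "tail", filtered = TRUE)
  expect_equal(nrow(neg), 20L)
  expect_true(all(kg$entities$etype[neg$t] == "syndrome"))
  expect_false(any(paste(neg$h, neg$l, neg$t) %in%
                     paste(kg$triples$h, kg$triples$l, kg$triples$t)))
  # two-entity pool forces the single other entity
  co <- emr_corpus(fields = list(pulse_taking = c("a", "b")),
                   syndrome = c("X", "Y"))
  kg2 <- build_kg(co)
  tri2 <- as.integer(kg$triples[1, ])
  ss2 <- kg2$triples[kg2$relations$kind[kg2$triples$l] == "symptom_syndrome", ]
  forced <- sample_negatives(as.integer(ss2[1, ]), kg2, 5, "tail",
                             filtered = TRUE)
  expect_equal(length(unique(forced$t)), 1L)
  expect_true(forced$t[1] != ss2$t[1])
  # determinism under an explicit seed
  set.seed(7); a <- sample_negatives(tri, kg, 10, "both")
  set.seed(7); b <- sample_negatives(tri, kg, 10, "both")
  expect_identical(a, b)
})

test_that("training is seeded, reproducible and separates the toy graph", {
  kg <- toy_kg()
  cfg <- train_config(d = 8L, epochs = 200L, lr = 0.1, negatives = 5L,
                      batch_size = 16L, seed = 2L)
  emb <- train_model(kg, cfg)
  # bit-identical rerun
  expect_identical(emb$entities, train_model(kg, cfg)$entities)
  # epochs = 0 returns the seeded initialisation untouched
  cfg0 <- cfg; cfg0$epochs <- 0L
  init <- dsds:::init_embeddings(nrow(kg$entities), nrow(kg$relations), cfg0)
  expect_identical(train_model(kg, cfg0)$entities, init$entities)
  # positives above zero on average, and above every filtered tail corruption
  tri <- kg$triples
  expect_gt(mean(score_triple(tri$h, tri$l, tri$t, emb)), 0)
  syn <- dsds:::kg_syndrome_ids(kg)
  ss <- tri[kg$relations$kind[tri$l] == "symptom_syndrome", ]
  for (i in seq_len(nrow(ss))) {
    corr <- setdiff(syn, ss$t[i])
    pos <- score_triple(ss$h[i], ss$l[i], ss$t[i], emb)
    neg <- score_triple(rep(ss$h[i], length(corr)),
                        rep(ss$l[i], length(corr)), corr, emb)
    expect_gt(pos, max(neg))
    expect_lt(mean(neg), 0)
  }
})

test_that("training loss is non-increasing at a small enough learning rate", {
  kg <- toy_kg()
  emb <- train_model(kg, train_config(d = 8L, epochs = 50L, lr = 0.05,
                                      negatives = 20L, batch_size = 64L,
                                      seed = 2L))
  loss <- attr(emb, "loss")
  expect_true(all(is.finite(loss)))
  expect_lte(mean(diff(loss) > 0), 0.05)
})

test_that("rank_candidates matches the score-all-then-sort oracle", {
  emb <- random_embeddings(60, 4, 10, seed = 8)
  set.seed(9)
  cand <- sample(60, 50)
  got <- rank_candidates(3L, 2L, cand, emb)
  sc <- vapply(cand, function(t) oracle_score(3L, 2L, t, emb), 0)
  ord <- order(-sc, cand)
  expect_equal(got$candidate, cand[ord])
  expect_equal(got$score, sc[ord], tolerance = 1e-9)
  # single candidate ranks first whatever its score
  expect_equal(nrow(rank_candidates(1L, 1L, cand[1], emb)), 1L)
  expect_error(rank_candidates(1L, 1L, integer(0), emb), "empty candidate")
  # moving a candidate's embedding toward the query never worsens its rank
  hl <- emb$entities[3L, ] * emb$relations[2L, ]
  worst <- got$candidate[nrow(got)]
  before <- which(got$candidate == worst)
  emb2 <- emb
  emb2$entities[worst, ] <- emb2$entities[worst, ] + 2 * Conj(hl)
  after <- which(rank_candidates(3L, 2L, cand, emb2)$candidate == worst)
  expect_lte(after, before)
})

test_that("checkpoints round-trip bit-exactly", {
  kg <- toy_kg()
  emb <- train_model(kg, fast_train(4L))
  dir <- withr::local_tempdir()
  save_checkpoint(emb, dir)
  back <- load_checkpoint(dir)
  expect_identical(back$entities, emb$entities)
  expect_identical(back$relations, emb$relations)
  expect_equal(unclass(back$config), unclass(emb$config))
})
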