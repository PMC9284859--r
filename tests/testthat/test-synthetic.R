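test_that("corpus generation is deterministic and honors degenerate mixes", {
  cs <- corpus_spec(schema = tiny_schema(), n_respondents = 50,
                    proportions = c(positive = 1, negative = 0,
                                    neutral = 0, empty = 0), seed = 3)
  g1 <- generate_corpus(cs)
  g2 <- generate_corpus(cs)
  expect_identical(g1$responses$text, g2$responses$text)
  expect_identical(g1$truth, g2$truth)
  expect_true(all(g1$truth$sentiment == "positive"))
  expect_false(any(g1$responses$empty))
})

test_that("sentiment mix concentrates at the requested proportions", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 500,
                    proportions = c(positive = 0.67, negative = 0.05,
                                    neutral = 0.18, empty = 0.10), seed = 11)
  g <- generate_corpus(cs)
  n_pos <- sum(g$truth$sentiment == "positive")
  # exact binomial 99% interval around 0.67 at n = 500
  ci <- qbinom(c(0.005, 0.995), 500, 0.67)
  expect_gte(n_pos, ci[1])
  expect_lte(n_pos, ci[2])
})

test_that("answer lengths reproduce the target summary statistics", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 4000,
                    proportions = c(positive = 0.9, negative = 0.05,
                                    neutral = 0.05, empty = 0), seed = 8)
  g <- generate_corpus(cs)
  len <- lengths(strsplit(g$responses$text[!g$responses$empty], " ", fixed = TRUE))
  expect_equal(median(len), 2)
  q <- unname(quantile(len, c(0.25, 0.75), type = 1))
  expect_equal(q[1], 1)
  expect_true(abs(q[2] - 11) <= 2)
  expect_lte(max(len), 192)
})

test_that("ground truth and emitted text are consistent", {
  cs <- corpus_spec(schema = tiny_schema(), n_respondents = 80, seed = 5)
  g <- generate_corpus(cs)
  modeled <- g$truth$sentiment %in% c("positive", "negative") & !g$responses$empty
  for (i in which(modeled)) {
    lex <- cs$topic_lexicons[[paste(g$truth$question_id[i], g$truth$sentiment[i],
                                    g$truth$topic[i], sep = ".")]]
    toks <- strsplit(g$responses$text[i], " ", fixed = TRUE)[[1]]
    expect_gt(length(intersect(toks, lex)), 0)
  }
  # topic defined iff modeled sentiment and non-empty
  expect_true(all(is.na(g$truth$topic[!modeled])))
  expect_false(anyNA(g$truth$topic[modeled]))
})

test_that("synthetic embeddings hit their target cosine geometry", {
  groups <- list(g1 = paste0("aaa", letters[1:10]), g2 = paste0("bbb", letters[1:10]))
  emb <- generate_embeddings(embedding_spec(groups, dim = 50, within_cosine = 0.8,
                                            seed = 4))
  v1 <- emb$vectors[groups$g1, ]; v2 <- emb$vectors[groups$g2, ]
  S11 <- tcrossprod(v1); S12 <- tcrossprod(v1, v2)
  expect_equal(mean(S11[upper.tri(S11)]), 0.8, tolerance = 0.1)
  expect_lte(abs(mean(S12)), 0.15)  # between-group near orthogonal
  expect_equal(unname(sqrt(rowSums(emb$vectors^2))),
               rep(1, nrow(emb$vectors)), tolerance = 1e-9)
  # target cosine 1 -> identical members within a group
  emb1 <- generate_embeddings(embedding_spec(groups, dim = 20, within_cosine = 1,
                                             seed = 4))
  w <- emb1$vectors[groups$g1, ]
  expect_equal(max(abs(sweep(w, 2, w[1, ]))), 0, tolerance = 1e-12)
  # determinism
  embA <- generate_embeddings(embedding_spec(groups, seed = 9))
  embB <- generate_embeddings(embedding_spec(groups, seed = 9))
  expect_identical(embA$vectors, embB$vectors)
  # anisotropic variant: unrelated words share the base cosine
  embC <- generate_embeddings(embedding_spec(groups, dim = 100,
                                             within_cosine = 0.8,
                                             base_cosine = 0.25, seed = 2))
  S <- tcrossprod(embC$vectors[groups$g1, ], embC$vectors[groups$g2, ])
  expect_lt(abs(mean(S) - 0.25), 0.1)
})

test_that("spelling corruption injects single edits at the requested rate", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 400,
                    proportions = c(positive = 0.8, negative = 0.2,
                                    neutral = 0, empty = 0), seed = 6)
  g <- generate_corpus(cs)
  # rate 0 is the identity
  c0 <- corrupt_spelling(g$responses, rate = 0, seed = 1)
  expect_identical(c0$responses$text, g$responses$text)
  expect_equal(nrow(c0$log), 0)

  c1 <- corrupt_spelling(g$responses, rate = 0.1, seed = 1)
  n_tokens <- sum(lengths(strsplit(g$responses$text[!g$responses$empty], " ")))
  expect_gt(n_tokens, 1000)
  ci <- qbinom(c(0.005, 0.995), n_tokens, 0.1)
  expect_gte(nrow(c1$log), ci[1])
  expect_lte(nrow(c1$log), ci[2])
  # every corrupted token is at Damerau-Levenshtein distance exactly 1
  sampled <- c1$log[sample.int(nrow(c1$log), 100), ]
  for (i in seq_len(nrow(sampled))) {
    expect_equal(dl_distance(sampled$original[i], sampled$corrupted[i]), 1L)
    expect_false(identical(sampled$original[i], sampled$corrupted[i]))
  }
  expect_error(corrupt_spelling(g$responses, rate = 1.5), "rate")
})

test_that("generated scores separate sentiment groups on the 1-10 scale", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 300, seed = 2)
  g <- generate_corpus(cs)
  sc <- generate_scores(g$truth, seed = 2)
  expect_true(all(sc$score >= 1 & sc$score <= 10))
  lab <- g$truth$sentiment[match(premtext:::doc_key(sc$respondent_id, sc$question_id),
                                 premtext:::doc_key(g$truth$respondent_id,
                                                    g$truth$question_id))]
  expect_gt(mean(sc$score[lab == "positive"]), mean(sc$score[lab == "negative"]))
})

test_that("injected typos are corrected back through preprocessing", {
  cs <- benchmark_corpus_spec(3)
  g <- generate_corpus(cs)
  lex <- lexicon_for_corpus(cs)
  cor <- corrupt_spelling(g$responses, rate = 0.05, seed = 3)
  docs <- preprocess_responses(cor$responses, lexicon = lex,
                               config = normalizer_config(min_word_length = 1))
  key <- premtext:::doc_key(cor$responses$respondent_id,
                            cor$responses$question_id)
  ok <- 0L
  for (i in seq_len(nrow(cor$log))) {
    d <- docs[[match(premtext:::doc_key(cor$log$respondent_id[i],
                                        cor$log$question_id[i]), key)]]
    if (identical(d$corrected_tokens[cor$log$position[i]],
                  cor$log$original[i])) ok <- ok + 1L
  }
  expect_gte(ok / nrow(cor$log), 0.9)
})

test_that("corpus specs round-trip through YAML", {
  spec <- corpus_spec(schema = tiny_schema(), n_respondents = 40,
                      proportions = c(positive = 0.6, negative = 0.2,
                                      neutral = 0.1, empty = 0.1),
                      topics_per_stratum = 3, seed = 12)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_corpus_spec(spec, f)
  back <- read_corpus_spec(f)
  expect_identical(back$topic_lexicons, spec$topic_lexicons)
  expect_identical(back$proportions, spec$proportions)
  expect_identical(generate_corpus(back)$responses$text,
                   generate_corpus(spec)$responses$text)
})
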