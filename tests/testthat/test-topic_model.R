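planted_matrix <- function(n_docs = 30, n_terms = 12, k = 3, seed = 5) {
  set.seed(seed)
  W0 <- matrix(0, n_docs, k)
  for (i in seq_len(n_docs)) W0[i, sample.int(k, 1)] <- rexp(1) + 0.5
  H0 <- matrix(0, k, n_terms)
  blocks <- split(seq_len(n_terms), rep(seq_len(k), length.out = n_terms))
  for (j in seq_len(k)) H0[j, blocks[[j]]] <- rexp(length(blocks[[j]])) + 0.5
  list(X = W0 %*% H0, W0 = W0, H0 = H0)
}

test_that("NMF reconstructs a planted block-separable factorization", {
  pm <- planted_matrix()
  fit <- fit_nmf(pm$X, 3, seed = 2)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  expect_lt(fit$rel_error, 0.05)
})

test_that("NMF handles degenerate inputs and enforces preconditions", {
  z <- fit_nmf(matrix(0, 4, 5), 2, seed = 1)
  expect_equal(z$W, matrix(0, 4, 2))
  expect_equal(z$H, matrix(0, 2, 5))
  expect_equal(z$rel_error, 0)
  expect_error(fit_nmf(matrix(1, 3, 3), 4, seed = 1), "exceeds")
  expect_error(fit_nmf(matrix(c(-1, 1, 1, 1), 2, 2), 1), "nonnegative")
})

test_that("NMF is deterministic given a seed and its residual is non-increasing", {
  pm <- planted_matrix(seed = 9)
  f1 <- fit_nmf(pm$X, 3, seed = 4)
  f2 <- fit_nmf(pm$X, 3, seed = 4)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(diff(f1$residuals) <= 1e-8))
})

test_that("topic coherence follows cosine geometry and is permutation-invariant", {
  v <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(1, 0, 0))
  emb_same <- embedding_table(v)
  expect_equal(topic_coherence(c("a", "b", "c"), emb_same), 1)
  emb_orth <- embedding_table(rbind(x = c(1, 0), y = c(0, 1)))
  expect_equal(topic_coherence(c("x", "y"), emb_orth), 0)
  # two vectors at 60 degrees -> 0.5
  emb60 <- embedding_table(rbind(x = c(1, 0), y = c(cos(pi / 3), sin(pi / 3))))
  expect_equal(topic_coherence(c("x", "y"), emb60), 0.5, tolerance = 1e-12)
  # bounded and permutation invariant on random sets
  set.seed(21)
  m <- matrix(rnorm(40), 8); rownames(m) <- letters[1:8]
  emb <- embedding_table(m)
  terms <- letters[1:8]
  c1 <- topic_coherence(terms, emb)
  c2 <- topic_coherence(rev(terms), emb)
  expect_equal(c1, c2)
  expect_true(c1 >= -1 && c1 <= 1)
  # n-grams average their word vectors; unseen-word terms are skipped
  expect_equal(topic_coherence(c("a b", "b a", "qq zz"), emb),
               1, tolerance = 1e-12)
  expect_warning(co <- topic_coherence(c("qq", "zz"), emb), "fewer than 2")
  expect_equal(co, 0)
})

test_that("k selection clips the range, breaks ties small, and reports candidates", {
  pm <- planted_matrix(n_docs = 6, n_terms = 8, k = 2, seed = 3)
  vocab <- letters[1:8]
  set.seed(1)
  m <- matrix(rnorm(8 * 10), 8); rownames(m) <- vocab
  emb <- embedding_table(m)
  sel <- sel6 <- select_k(pm$X, vocab, emb, k_range = 2:15, seed = 1)
  expect_false(sel$skipped)
  expect_true(all(sel$candidates$k <= 6))  # clipped to min(dim)
  expect_true(sel$k %in% sel$candidates$k)
  expect_equal(sel$coherence, max(sel$candidates$coherence))
  # ties go to the smallest k
  cands <- data.frame(k = c(2, 3, 4), coherence = c(0.7, 0.7, 0.5))
  expect_equal(cands$k[which(cands$coherence == max(cands$coherence))[1]], 2)
  # stratum too small -> skip signal, not an error
  small <- select_k(pm$X[1:2, ], vocab, emb, seed = 1)
  expect_true(small$skipped)
})

test_that("topic assignment follows argmax with zero-row and tie rules", {
  W <- rbind(d1 = c(0.9, 0.1), d2 = c(0, 0), d3 = c(0.4, 0.4))
  a <- assign_topics(W)
  expect_equal(unname(a), c(1L, NA_integer_, 1L))
  expect_equal(names(a), c("d1", "d2", "d3"))
  # optional minimum-weight threshold
  expect_equal(unname(assign_topics(W, tau = 0.5)), c(1L, NA_integer_, NA_integer_))
})

test_that("descriptors are length-sorted, deduplicated, and capped", {
  vocab <- c("went very well", "went well", "staff", "kind staff", "waiting")
  h <- c(5, 4, 3, 2, 1)
  d <- topic_descriptors(h, vocab)
  expect_false("went well" %in% d)       # contiguous subsequence removed
  expect_true("went very well" %in% d)
  expect_equal(d[1], "went very well")   # most words first
  expect_lte(length(d), 5)
  # fewer survivors than show -> all returned
  expect_equal(length(topic_descriptors(c(2, 1), c("alpha", "beta"), show = 5)), 2)
  # trigram before unigram
  d2 <- topic_descriptors(c(3, 5), c("heel goed geholpen", "goed"))
  expect_equal(d2[1], "heel goed geholpen")
  expect_warning(d0 <- topic_descriptors(c(0, 0), c("a", "b")), "all-zero")
  expect_length(d0, 0)
  # no retained descriptor is covered by another (in-order token subsequence,
  # which includes every contiguous-subsequence pair)
  set.seed(8)
  words <- c("zorg", "goede", "uitleg", "arts")
  for (rep in 1:10) {
    vocab_r <- unique(replicate(12, paste(sample(words, sample(1:3, 1)), collapse = " ")))
    d <- suppressWarnings(topic_descriptors(runif(length(vocab_r)), vocab_r))
    toks <- strsplit(d, " ", fixed = TRUE)
    for (i in seq_along(toks)) for (j in seq_along(toks)) {
      if (i != j) expect_false(premtext:::is_token_subseq(toks[[i]], toks[[j]]))
    }
  }
})

test_that("per-stratum counts are conserved and neutral is never modeled", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 120,
                    proportions = c(positive = 0.5, negative = 0.3,
                                    neutral = 0.1, empty = 0.1),
                    topics_per_stratum = 2, seed = 42)
  g <- generate_corpus(cs)
  emb <- embeddings_for_corpus(cs)
  labels <- data.frame(respondent_id = g$truth$respondent_id,
                       question_id = g$truth$question_id,
                       label = ifelse(g$truth$sentiment == "empty", "neutral",
                                      g$truth$sentiment))
  strata <- fit_strata(g$responses, labels, emb, k_range = 2:6, seed = 1)
  expect_setequal(names(strata), c("Q1.positive", "Q1.negative"))
  for (st in strata) {
    expect_equal(sum(st$counts$topic) + st$counts$unassigned,
                 length(st$doc_keys))
    expect_equal(length(st$assignment), length(st$doc_keys))
  }
})
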