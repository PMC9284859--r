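test_that("sampling sizes follow the 20%-with-minimum-10 rule", {
  expect_equal(sampling_plan_size(100), 20)   # 20% of the answers per topic
  expect_equal(sampling_plan_size(8), 8)      # below the minimum: take all
  expect_equal(sampling_plan_size(30), 10)    # max(ceil(6), 10)
  # closed-form rule over all topic sizes 1..100
  for (n in 1:100) {
    want <- if (n < 10) n else max(ceiling(0.2 * n), 10)
    expect_equal(sampling_plan_size(n), want)
  }
})

test_that("sampling plans are deterministic, without replacement, and sized", {
  assignments <- setNames(rep(1:3, c(100, 8, 30)), sprintf("d%03d", 1:138))
  p1 <- make_sampling_plan(assignments, seed = 5)
  p2 <- make_sampling_plan(assignments, seed = 5)
  expect_identical(p1$samples, p2$samples)
  expect_equal(p1$sizes$sampled, c(20, 8, 10))
  for (t in names(p1$samples)) {
    expect_false(anyDuplicated(p1$samples[[t]]) > 0)
    expect_true(all(p1$samples[[t]] %in% names(assignments)))
  }
  expect_error(make_sampling_plan(assignments, frac = 0), "frac")
  expect_error(make_sampling_plan(assignments, frac = 1.2), "frac")
})

test_that("representativeness pools counts, not rates", {
  j <- data.frame(
    doc_key = sprintf("d%02d", 1:12),
    stratum = "Q1.positive",
    topic = rep(c(1, 2), c(4, 8)),
    judge_id = "ON",
    fits = c(1, 1, 0, 0, rep(1, 8)),
    stringsAsFactors = FALSE
  )
  r <- representativeness(j, "ON")
  expect_equal(r$per_topic$rate, c(2 / 4, 8 / 8))
  expect_equal(r$overall, 10 / 12)  # pooled, not mean(0.5, 1) = 0.75
  # 9 of 10 fit -> 90%
  j2 <- data.frame(doc_key = sprintf("x%02d", 1:10), stratum = "s", topic = 1,
                   judge_id = "ON", fits = c(rep(1, 9), 0))
  expect_equal(representativeness(j2, "ON")$overall, 0.9)
  # pooling is invariant under topic relabeling
  j3 <- j; j3$topic <- rep(c(7, 5), c(4, 8))
  expect_equal(representativeness(j3, "ON")$overall, r$overall)
})

test_that("representativeness reports gaps against a sampling plan", {
  assignments <- setNames(rep(1, 5), paste0("d", 1:5))
  plan <- make_sampling_plan(assignments, seed = 1)
  j <- data.frame(doc_key = paste0("d", 1:4), stratum = "s", topic = 1,
                  judge_id = "ON", fits = 1)
  expect_error(representativeness(j, "ON", plan), "d5")
})

test_that("topic overlap counts distinct matched manual topics", {
  manual <- c(paste0("pos", 1:14), paste0("neg", 1:6))
  matched <- c(paste0("pos", 1:12), paste0("neg", 1:6))
  expect_equal(topic_overlap(manual, matched), 0.9)
  expect_equal(topic_overlap(manual, manual), 1)
  # duplicate matches count once
  expect_equal(topic_overlap(c("a", "b"),
                             data.frame(manual_topic = c("a", "a"),
                                        auto_topic = c("t1", "t2"))), 0.5)
  expect_error(topic_overlap(c("a"), "zz"), "unknown")
})

test_that("group comparison matches hand-applied pooled formulas", {
  cmp <- compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5), variant = "pooled")
  expect_equal(cmp$t, -1.0954451, tolerance = 1e-6)
  expect_equal(cmp$df, 6)
  # identical groups -> t = 0, p = 1
  same <- compare_groups(c(3, 3, 4), c(3, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_groups(c(1), c(1, 2)), "at least 2")
})

test_that("group comparison agrees with the reference t-test on random data", {
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, 5, 10), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, 5, 10), sd = runif(1, 0.5, 3))
    for (variant in c("pooled", "welch")) {
      got <- compare_groups(x, y, variant = variant)
      ref <- t.test(x, y, var.equal = (variant == "pooled"))
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    }
    # summary form agrees with raw form
    s <- compare_groups(list(n = length(x), mean = mean(x), sd = sd(x)),
                        list(n = length(y), mean = mean(y), sd = sd(y)))
    r <- compare_groups(x, y)
    expect_equal(s$t, r$t, tolerance = 1e-12)
    expect_equal(s$p, r$p, tolerance = 1e-12)
  }
})

test_that("summary-form comparison accepts printed group summaries", {
  for (variant in c("pooled", "welch")) {
    cmp <- compare_groups(list(n = 359, mean = 9.7, sd = 0.9),
                          list(n = 26, mean = 8.1, sd = 2.4), variant = variant)
    expect_true(is.finite(cmp$t) && is.finite(cmp$df) && is.finite(cmp$p))
    expect_gt(cmp$t, 0)
    expect_true(cmp$p >= 0 && cmp$p <= 1)
  }
})

test_that("per-question score comparison joins labels and scores", {
  cs <- corpus_spec(schema = survey_schema("Q1", "p"), n_respondents = 200,
                    proportions = c(positive = 0.6, negative = 0.2,
                                    neutral = 0.1, empty = 0.1), seed = 2)
  g <- generate_corpus(cs)
  scores <- generate_scores(g$truth, seed = 2)
  labels <- data.frame(respondent_id = g$truth$respondent_id,
                       question_id = g$truth$question_id,
                       label = ifelse(g$truth$sentiment == "empty", "neutral",
                                      g$truth$sentiment))
  out <- compare_scores_by_sentiment(scores, labels)
  expect_equal(out$question_id, "Q1")
  expect_gt(out$mean_pos, out$mean_neg)  # generator plants higher positive scores
  expect_equal(attr(out, "multiple_testing"), "none")
})
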