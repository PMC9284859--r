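# Letter-only synthetic words (the tokenizer keeps letters only): topic
# words encode (question, sentiment, topic, word) indices, markers encode
# (class, word), noise words (word) — all >= 3 characters and globally
# disjoint by construction. Index letters are doubled so any two distinct
# words are at edit distance >= 2, as in a natural vocabulary; a
# single-character typo then never coincides with another valid word.
syn_topic_word <- function(qi, s, t, w) {
  paste0("top", strrep(letters[qi], 2), strrep(substr(s, 1, 1), 2),
         strrep(letters[t], 2), strrep(letters[w], 2))
}
syn_marker_word <- function(s, w) {
  paste0("mark", strrep(substr(s, 1, 1), 2), strrep(letters[w], 2))
}
syn_noise_word <- function(w1, w2) {
  paste0("noise", strrep(letters[w1], 2), strrep(letters[w2], 2))
}

#' Specification of a synthetic questionnaire corpus
#'
#' Describes the data regime the generator emulates: very short free-text
#' answers (median two tokens, interquartile range about 1–11, hard cap 192
#' — a discretized log-normal reproduces that summary), a sentiment mix
#' dominated by positive answers, planted latent topics per (question x
#' sentiment) stratum with disjoint topic lexicons, per-class sentiment
#' marker words, and background noise words.
#'
#' @param schema a [survey_schema()] (default: five questions Q1–Q5).
#' @param n_respondents number of respondents (default 534).
#' @param proportions per-question sentiment mix: either one named vector
#'   `c(positive=, negative=, neutral=, empty=)` summing to 1 used for all
#'   questions, or a list of such vectors named by question_id. The default
#'   mirrors a positive-dominated clinical survey (about 67% positive, 5%
#'   negative per question).
#' @param topics_per_stratum planted number of topics k per (question,
#'   sentiment) stratum (default 4).
#' @param words_per_topic size of each disjoint topic lexicon (default 10).
#' @param markers_per_class sentiment marker words per class (default 6).
#' @param n_noise_words size of the shared noise vocabulary (default 40).
#' @param topic_rate,marker_rate,noise_rate mixing probabilities for tokens
#'   after the first (must sum to 1; defaults 0.5 / 0.3 / 0.2 — answers
#'   lean on topic words, carry frequent evaluative markers, and some
#'   filler). The first token of a positive/negative answer is always a
#'   topic word, so every such answer contains at least one word of its
#'   planted lexicon.
#' @param length_meanlog,length_sdlog,max_len discretized log-normal answer
#'   length: `min(max(1, round(rlnorm(meanlog, sdlog))), max_len)`. The
#'   defaults (`log(2.2)`, 2.4, 192) give median 2 and IQR \[1, 11\].
#' @param seed integer master seed; all randomness flows from it through
#'   named substreams (sentiment, topic, length, tokens, typo).
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(schema = default_schema(),
                        n_respondents = 534L,
                        proportions = c(positive = 0.67, negative = 0.05,
                                        neutral = 0.18, empty = 0.10),
                        topics_per_stratum = 4L,
                        words_per_topic = 10L,
                        markers_per_class = 6L,
                        n_noise_words = 40L,
                        topic_rate = 0.5, marker_rate = 0.3, noise_rate = 0.2,
                        length_meanlog = log(2.2), length_sdlog = 2.4,
                        max_len = 192L, seed = 1L) {
  stopifnot(inherits(schema, "survey_schema"))
  if (!is.list(proportions)) {
    proportions <- stats::setNames(rep(list(proportions), nrow(schema)),
                                   schema$question_id)
  }
  for (q in schema$question_id) {
    p <- proportions[[q]]
    if (is.null(p) || !all(c("positive", "negative", "neutral", "empty") %in% names(p))) {
      stop("proportions for ", q, " must name positive, negative, neutral, empty")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("proportions for ", q, " must be nonnegative and sum to 1")
    }
  }
  mix <- c(topic_rate, marker_rate, noise_rate)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("topic_rate + marker_rate + noise_rate must equal 1")
  }
  if (max_len < 11) stop("max_len must be at least the IQR upper bound")
  k <- as.integer(topics_per_stratum)
  if (k < 1 || k > 26) stop("topics_per_stratum must be in 1..26")
  lexicons <- list()
  for (qi in seq_len(nrow(schema))) {
    for (s in c("positive", "negative")) {
      for (t in seq_len(k)) {
        nm <- paste(schema$question_id[qi], s, t, sep = ".")
        lexicons[[nm]] <- vapply(seq_len(words_per_topic), function(w)
          syn_topic_word(qi, s, t, w), "")
      }
    }
  }
  markers <- list(
    positive = vapply(seq_len(markers_per_class), function(w)
      syn_marker_word("positive", w), ""),
    negative = vapply(seq_len(markers_per_class), function(w)
      syn_marker_word("negative", w), ""),
    neutral = vapply(seq_len(markers_per_class), function(w)
      syn_marker_word("xeutral", w), "")
  )
  noise <- as.vector(outer(seq_len(ceiling(n_noise_words / 26)), 1:26,
                           Vectorize(syn_noise_word)))[seq_len(n_noise_words)]
  structure(list(
    schema = schema, n_respondents = as.integer(n_respondents),
    proportions = proportions, topics_per_stratum = k,
    words_per_topic = as.integer(words_per_topic),
    topic_lexicons = lexicons, markers = markers, noise_words = noise,
    topic_rate = topic_rate, marker_rate = marker_rate, noise_rate = noise_rate,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    max_len = as.integer(max_len), seed = as.integer(seed)
  ), class = "corpus_spec")
}

#' @rdname corpus_spec
#' @export
default_schema <- function() {
  survey_schema(
    paste0("Q", 1:5),
    c("How was the provided information?",
      "How was the personal approach?",
      "How was the collaboration between healthcare professionals?",
      "How was the organization of care?",
      "What else would you like to share about your experience?")
  )
}

# named substream seeds derived once from the master seed
substream_seeds <- function(seed, streams) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

sample_lengths <- function(n, spec) {
  raw <- round(stats::rlnorm(n, spec$length_meanlog, spec$length_sdlog))
  pmin(pmax(raw, 1), spec$max_len)
}

#' Generate a ground-truthed synthetic corpus
#'
#' For every (respondent, question) pair a sentiment is drawn from the
#' question's mix; empty answers get empty text; positive/negative answers
#' get a planted topic drawn uniformly from the stratum's lexicons and a
#' token sequence mixing topic words, sentiment markers and noise words
#' (first token always a topic word); neutral answers mix neutral markers
#' and noise. Deterministic given the spec seed.
#'
#' @param spec a [corpus_spec()].
#' @return List with `responses` (a [response_set()]) and `truth` (data
#'   frame: `respondent_id`, `question_id`, `sentiment`, `topic` — `NA`
#'   unless the answer is non-empty positive/negative).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  seeds <- substream_seeds(spec$seed, c("sentiment", "topic", "length", "tokens"))
  resp_ids <- sprintf("R%04d", seq_len(spec$n_respondents))
  grid <- expand.grid(respondent_id = resp_ids,
                      question_id = spec$schema$question_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)

  set.seed(seeds[["sentiment"]])
  sentiment <- character(n)
  for (q in spec$schema$question_id) {
    sel <- grid$question_id == q
    p <- spec$proportions[[q]]
    sentiment[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
  }

  set.seed(seeds[["topic"]])
  topic <- rep(NA_integer_, n)
  modeled <- sentiment %in% c("positive", "negative")
  topic[modeled] <- sample.int(spec$topics_per_stratum, sum(modeled), replace = TRUE)

  set.seed(seeds[["length"]])
  len <- sample_lengths(n, spec)

  set.seed(seeds[["tokens"]])
  text <- character(n)
  for (i in seq_len(n)) {
    s <- sentiment[i]
    if (s == "empty") { text[i] <- ""; next }
    L <- len[i]
    if (s == "neutral") {
      pool_m <- spec$markers$neutral
      toks <- ifelse(stats::runif(L) < 0.6,
                     sample(pool_m, L, replace = TRUE),
                     sample(spec$noise_words, L, replace = TRUE))
    } else {
      lex <- spec$topic_lexicons[[paste(grid$question_id[i], s, topic[i], sep = ".")]]
      toks <- character(L)
      toks[1] <- sample(lex, 1)
      if (L > 1) {
        kind <- sample(c("topic", "marker", "noise"), L - 1, replace = TRUE,
                       prob = c(spec$topic_rate, spec$marker_rate, spec$noise_rate))
        n_t <- sum(kind == "topic"); n_m <- sum(kind == "marker")
        n_z <- sum(kind == "noise")
        toks[-1][kind == "topic"] <- sample(lex, n_t, replace = TRUE)
        toks[-1][kind == "marker"] <- sample(spec$markers[[s]], n_m, replace = TRUE)
        toks[-1][kind == "noise"] <- sample(spec$noise_words, n_z, replace = TRUE)
      }
    }
    text[i] <- paste(toks, collapse = " ")
  }

  truth <- data.frame(respondent_id = grid$respondent_id,
                      question_id = grid$question_id,
                      sentiment = ifelse(sentiment == "empty", "empty", sentiment),
                      topic = topic, stringsAsFactors = FALSE)
  responses <- response_set(grid$respondent_id, grid$question_id, text, spec$schema)
  list(responses = responses, truth = truth)
}

#' Specification of synthetic word embeddings
#'
#' Every vector is a unit-normalized sum of three parts: a global direction
#' shared by all words (controlling the background cosine between any two
#' words — real word2vec spaces are anisotropic, with unrelated words at a
#' small positive similarity), a group centroid shared within a word group
#' (a topic lexicon), and isotropic noise. The scales are chosen so that
#' the expected pairwise cosine is `within_cosine` inside a group and
#' `base_cosine` between unrelated words. Extra words carry only the global
#' direction plus noise.
#'
#' @param groups named list of character vectors (e.g. the topic lexicons of
#'   a [corpus_spec()]).
#' @param extra_words words embedded with no group structure (e.g. markers
#'   and noise words).
#' @param dim embedding dimension (default 50).
#' @param within_cosine target expected within-group cosine in (0, 1\]
#'   (default 0.8).
#' @param base_cosine target expected cosine between unrelated words, in
#'   \[0, `within_cosine`\] (default 0: near-orthogonal).
#' @param seed integer seed.
#' @return An `embedding_spec` list.
#' @export
embedding_spec <- function(groups, extra_words = character(), dim = 50L,
                           within_cosine = 0.8, base_cosine = 0, seed = 1L) {
  if (length(groups) == 0 || any(lengths(groups) == 0)) {
    stop("groups must be a non-empty list of non-empty word sets")
  }
  if (within_cosine <= 0 || within_cosine > 1) {
    stop("within_cosine must be in (0, 1]")
  }
  if (base_cosine < 0 || base_cosine > within_cosine) {
    stop("base_cosine must be in [0, within_cosine]")
  }
  if (dim < 2) stop("dim must be >= 2")
  if (dim < 2 * length(groups)) {
    warning("dimension ", dim, " is small for ", length(groups),
            " near-orthogonal group centroids")
  }
  structure(list(groups = groups, extra_words = extra_words,
                 dim = as.integer(dim), within_cosine = within_cosine,
                 base_cosine = base_cosine, seed = as.integer(seed)),
            class = "embedding_spec")
}

random_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

#' Generate synthetic word embeddings
#'
#' @param spec an [embedding_spec()].
#' @return An [embedding_table()] covering all group members and extra
#'   words, unit-normalized.
#' @export
generate_embeddings <- function(spec) {
  stopifnot(inherits(spec, "embedding_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  rho <- spec$within_cosine
  base <- spec$base_cosine
  # v = a*u0 + b*centroid + s*noise, each part a unit vector:
  # E[cos] = a^2 between unrelated words, a^2 + b^2 within a group
  a <- sqrt(base); b <- sqrt(rho - base); s <- sqrt(1 - rho)
  u0 <- random_unit(d)
  words <- character(0); rows <- list()
  for (g in names(spec$groups)) {
    centroid <- random_unit(d)
    for (w in spec$groups[[g]]) {
      v <- a * u0 + b * centroid + s * random_unit(d)
      rows[[length(rows) + 1L]] <- v / sqrt(sum(v^2))
      words <- c(words, w)
    }
  }
  s_extra <- sqrt(1 - base)
  for (w in spec$extra_words) {
    v <- a * u0 + s_extra * random_unit(d)
    rows[[length(rows) + 1L]] <- v / sqrt(sum(v^2))
    words <- c(words, w)
  }
  dup <- duplicated(words)
  mat <- do.call(rbind, rows)[!dup, , drop = FALSE]
  rownames(mat) <- words[!dup]
  embedding_table(mat)
}

#' Embeddings matching a corpus spec
#'
#' Convenience wrapper: topic lexicons become coherent groups; sentiment
#' markers and noise words get no group structure (sentiment wording varies
#' widely, so markers are not modeled as one tight semantic cluster). The
#' default background cosine of 0.25 mimics the anisotropy of trained
#' word2vec spaces, where unrelated words still share a small positive
#' similarity.
#'
#' @param cspec a [corpus_spec()].
#' @param dim,within_cosine,base_cosine,seed as in [embedding_spec()].
#' @return An [embedding_table()].
#' @export
embeddings_for_corpus <- function(cspec, dim = 50L, within_cosine = 0.8,
                                  base_cosine = 0.25, seed = cspec$seed) {
  generate_embeddings(embedding_spec(
    groups = cspec$topic_lexicons,
    extra_words = c(unlist(cspec$markers, use.names = FALSE), cspec$noise_words),
    dim = dim, within_cosine = within_cosine, base_cosine = base_cosine,
    seed = seed
  ))
}

random_edit <- function(token) {
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ops <- c("substitution", "insertion")
  if (n >= 2) ops <- c(ops, "deletion")
  if (n >= 2 && any(chars[-n] != chars[-1])) ops <- c(ops, "transposition")
  op <- sample(ops, 1)
  if (op == "deletion") {
    i <- sample.int(n, 1)
    paste(chars[-i], collapse = "")
  } else if (op == "transposition") {
    cand <- which(chars[-n] != chars[-1])
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    paste(c(chars[seq_len(i - 1)], chars[i + 1], chars[i],
            chars[seq_len(n - i - 1) + i + 1]), collapse = "")
  } else if (op == "substitution") {
    i <- sample.int(n, 1)
    chars[i] <- sample(setdiff(letters, chars[i]), 1)
    paste(chars, collapse = "")
  } else {
    i <- sample.int(n + 1, 1)
    paste(c(chars[seq_len(i - 1)], sample(letters, 1),
            chars[seq_len(n - i + 1) + i - 1]), collapse = "")
  }
}

#' Inject spelling errors into a response set
#'
#' Each token is independently corrupted with probability `rate` by one
#' random single-character edit (deletion, adjacent transposition,
#' substitution or insertion, always producing a different token at edit
#' distance exactly 1). A typo log records every change.
#'
#' @param responses a [response_set()].
#' @param rate corruption probability per token, in \[0, 1\].
#' @param seed integer seed.
#' @return List with `responses` (corrupted copy) and `log` (data frame:
#'   `respondent_id`, `question_id`, `position`, `original`, `corrupted`).
#' @export
corrupt_spelling <- function(responses, rate, seed = 1L) {
  stopifnot(inherits(responses, "response_set"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  set.seed(seed)
  out <- responses
  log_rows <- list()
  if (rate > 0) {
    for (i in seq_len(nrow(out))) {
      if (out$empty[i]) next
      toks <- strsplit(out$text[i], " ", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(toks)) < rate & nzchar(toks))
      for (j in hit) {
        orig <- toks[j]
        toks[j] <- random_edit(orig)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          respondent_id = out$respondent_id[i], question_id = out$question_id[i],
          position = j, original = orig, corrupted = toks[j],
          stringsAsFactors = FALSE)
      }
      if (length(hit)) out$text[i] <- paste(toks, collapse = " ")
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(respondent_id = character(0), question_id = character(0),
               position = integer(0), original = character(0),
               corrupted = character(0), stringsAsFactors = FALSE)
  list(responses = out, log = log)
}

#' Frequency lexicon of a corpus spec's vocabulary
#'
#' All planted words with frequencies decaying by within-lexicon rank, for
#' exercising the spelling corrector with full coverage of true words.
#'
#' @param spec a [corpus_spec()].
#' @return A [frequency_lexicon()].
#' @export
lexicon_for_corpus <- function(spec) {
  words <- c(unlist(spec$topic_lexicons, use.names = FALSE),
             unlist(spec$markers, use.names = FALSE), spec$noise_words)
  words <- unique(words)
  frequency_lexicon(words, pmax(1L, 100L - seq_along(words) %% 50L))
}

#' Generate matched structured scores correlated with planted sentiment
#'
#' Emits one integer 1–10 score per non-empty answer, normally distributed
#' around a sentiment-dependent mean (defaults follow a strongly satisfied
#' patient group and a moderately dissatisfied one), clamped to the scale.
#'
#' @param truth ground-truth data frame from [generate_corpus()].
#' @param mean_by_sentiment,sd_by_sentiment named numeric vectors over
#'   positive/neutral/negative.
#' @param seed integer seed.
#' @return Data frame `respondent_id`, `question_id`, `score`.
#' @export
generate_scores <- function(truth,
                            mean_by_sentiment = c(positive = 9.7, neutral = 9.0,
                                                  negative = 8.1),
                            sd_by_sentiment = c(positive = 0.9, neutral = 1.2,
                                                negative = 2.4),
                            seed = 1L) {
  set.seed(seed)
  keep <- truth$sentiment %in% names(mean_by_sentiment)
  t2 <- truth[keep, , drop = FALSE]
  mu <- mean_by_sentiment[t2$sentiment]
  sg <- sd_by_sentiment[t2$sentiment]
  score <- round(pmin(10, pmax(1, stats::rnorm(nrow(t2), mu, sg))))
  data.frame(respondent_id = t2$respondent_id, question_id = t2$question_id,
             score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Planted-structure benchmark specification
#'
#' The recovery benchmark stratum: a single question answered by 470
#' respondents with a balanced positive/negative mix, so each modeled
#' stratum holds about 200 non-empty documents with 4 planted topics and
#' disjoint lexicons. Used by the recovery experiments and the acceptance
#' checks.
#'
#' @param seed integer seed.
#' @return A [corpus_spec()].
#' @export
benchmark_corpus_spec <- function(seed = 1L) {
  corpus_spec(
    schema = survey_schema("Q1", "How was the provided information?"),
    n_respondents = 470L,
    proportions = c(positive = 0.425, negative = 0.425,
                    neutral = 0.10, empty = 0.05),
    topics_per_stratum = 4L,
    seed = seed
  )
}

#' Read / write a corpus specification as YAML
#'
#' Serializes the scalar fields, per-question proportions and the schema;
#' lexicons, markers and noise words are reconstructed deterministically by
#' [corpus_spec()], so the file stays small and human-editable.
#'
#' @param path YAML file path.
#' @param spec a [corpus_spec()].
#' @return `read_corpus_spec` returns a [corpus_spec()]; `write_corpus_spec`
#'   returns `path` invisibly.
#' @export
read_corpus_spec <- function(path) {
  y <- yaml::read_yaml(path)
  schema <- survey_schema(vapply(y$questions, `[[`, "", "question_id"),
                          vapply(y$questions, `[[`, "", "prompt"))
  props <- lapply(y$proportions, function(p) unlist(p))
  corpus_spec(schema = schema, n_respondents = y$n_respondents,
              proportions = props,
              topics_per_stratum = y$topics_per_stratum,
              words_per_topic = y$words_per_topic,
              markers_per_class = y$markers_per_class,
              n_noise_words = y$n_noise_words,
              topic_rate = y$topic_rate, marker_rate = y$marker_rate,
              noise_rate = y$noise_rate,
              length_meanlog = y$length_meanlog,
              length_sdlog = y$length_sdlog,
              max_len = y$max_len, seed = y$seed)
}

#' @rdname read_corpus_spec
#' @export
write_corpus_spec <- function(spec, path) {
  stopifnot(inherits(spec, "corpus_spec"))
  yaml::write_yaml(list(
    questions = lapply(seq_len(nrow(spec$schema)), function(i)
      list(question_id = spec$schema$question_id[i],
           prompt = spec$schema$prompt[i])),
    n_respondents = spec$n_respondents,
    proportions = lapply(spec$proportions, as.list),
    topics_per_stratum = spec$topics_per_stratum,
    words_per_topic = spec$words_per_topic,
    markers_per_class = length(spec$markers$positive),
    n_noise_words = length(spec$noise_words),
    topic_rate = spec$topic_rate, marker_rate = spec$marker_rate,
    noise_rate = spec$noise_rate,
    length_meanlog = spec$length_meanlog, length_sdlog = spec$length_sdlog,
    max_len = spec$max_len, seed = spec$seed
  ), path)
  invisible(path)
}
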