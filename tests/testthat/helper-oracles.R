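# Independent oracles and small fixtures shared across tests.

# Unrestricted Damerau-Levenshtein distance (Lowrance-Wagner): the minimum
# number of single-character deletions, insertions, substitutions and
# adjacent transpositions turning `a` into `b`. Equals the minimum number
# of Norvig edit operations, including chains through intermediate strings
# (e.g. dl("ca", "abc") == 2 via "ac").
dl_distance <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0) return(m)
  if (m == 0) return(n)
  maxd <- n + m
  d <- matrix(0L, n + 2, m + 2)
  d[1, ] <- maxd; d[, 1] <- maxd
  d[2, 2:(m + 2)] <- 0:m
  d[2:(n + 2), 2] <- 0:n
  alphabet <- unique(c(A, B))
  da <- stats::setNames(rep(0L, length(alphabet)), alphabet)
  for (i in 1:n) {
    db <- 0L
    for (j in 1:m) {
      k <- da[[B[j]]]; l <- db
      if (A[i] == B[j]) { cost <- 0L; db <- j } else cost <- 1L
      d[i + 2, j + 2] <- min(
        d[i + 1, j + 1] + cost,                     # substitution / match
        d[i + 2, j + 1] + 1L,                       # insertion
        d[i + 1, j + 2] + 1L,                       # deletion
        d[k + 1, l + 1] + (i - k - 1L) + 1L + (j - l - 1L)  # transposition
      )
    }
    da[[A[i]]] <- i
  }
  d[n + 2, m + 2]
}

# Brute-force Norvig correction: scan the whole lexicon with dl_distance,
# prefer distance 0 over 1 over 2, break ties by frequency then
# lexicographically; fall back to the token.
oracle_correct <- function(token, lexicon) {
  words <- names(lexicon)
  if (token %in% words) return(token)
  dist <- vapply(words, dl_distance, 0L, a = token)
  for (dd in 1:2) {
    hits <- words[dist == dd]
    if (length(hits)) {
      freq <- unclass(lexicon)[hits]
      return(hits[order(-freq, hits)][1])
    }
  }
  token
}

# Brute-force TF-IDF: per-cell recomputation of the stated formula.
oracle_tfidf <- function(token_lists, ngram_min = 1, ngram_max = 3, min_df = 1) {
  grams_of <- function(toks) {
    out <- character(0)
    for (n in ngram_min:ngram_max) {
      if (length(toks) < n) break
      for (s in 1:(length(toks) - n + 1)) {
        out <- c(out, paste(toks[s:(s + n - 1)], collapse = " "))
      }
    }
    out
  }
  grams <- lapply(token_lists, grams_of)
  vocab <- sort(unique(unlist(grams)))
  df <- vapply(vocab, function(t) sum(vapply(grams, function(g) t %in% g, TRUE)), 0)
  vocab <- vocab[df >= min_df]
  df <- df[df >= min_df]
  N <- length(token_lists)
  m <- matrix(0, N, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(N)) {
    for (t in seq_along(vocab)) {
      tf <- sum(grams[[i]] == vocab[t])
      m[i, t] <- tf * (log((1 + N) / (1 + df[t])) + 1)
    }
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}

# small fixtures -------------------------------------------------------------

tiny_schema <- function() survey_schema(c("Q1", "Q2"), c("prompt one", "prompt two"))

# a small linearly separable annotated corpus: disjoint marker lexicons per
# class, ground truth by construction
separable_annotations <- function(n = 300, seed = 7) {
  set.seed(seed)
  lex <- list(
    negative = c("slecht", "boos", "klacht", "traag", "fout"),
    neutral = c("ging", "keer", "soms", "week", "dag"),
    positive = c("goed", "prima", "fijn", "vriendelijk", "duidelijk")
  )
  label <- sample(names(lex), n, replace = TRUE, prob = c(0.25, 0.25, 0.5))
  text <- vapply(label, function(cl) {
    paste(sample(lex[[cl]], sample(2:5, 1), replace = TRUE), collapse = " ")
  }, "")
  data.frame(text = text, label = label,
             respondent_id = sprintf("R%03d", seq_len(n)),
             question_id = "Q1", annotator_id = "A1",
             stringsAsFactors = FALSE)
}

cluster_purity <- function(assigned, planted) {
  ok <- !is.na(assigned)
  if (!any(ok)) return(0)
  sum(vapply(split(planted[ok], assigned[ok]),
             function(x) max(table(x)), 0)) / sum(ok)
}
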