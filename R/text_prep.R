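#' Tokenize a free-text answer
#'
#' Lowercases, strips punctuation and digits, and splits on any
#' non-letter run, so hyphenated compounds split into their parts.
#' Letters include Unicode letters (Dutch diacritics survive).
#'
#' @param text character scalar (or vector; result is a list then).
#' @return Character vector of tokens; `character(0)` for empty text.
#' @examples
#' tokenize("Prima geholpen!")   # "prima" "geholpen"
#' tokenize("wacht-tijd")        # "wacht" "tijd"
#' @export
tokenize <- function(text) {
  if (length(text) > 1) return(lapply(text, tokenize))
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  toks <- strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

# All single-edit variants of a word: deletions, adjacent transpositions,
# substitutions and insertions over a-z (the Norvig candidate set).
norvig_edits1 <- function(word) {
  letters_nl <- letters
  n <- nchar(word)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  pre <- substring(word, 0, 0:n)      # prefixes incl. ""
  suf <- substring(word, 1:(n + 1), n) # suffixes incl. ""
  out <- character(0)
  if (n >= 1) {
    out <- c(out, paste0(pre[1:n], substring(word, 2:(n + 1), n)))  # deletions
  }
  if (n >= 2) {
    i <- 1:(n - 1)
    out <- c(out, paste0(pre[i], chars[i + 1], chars[i],
                         substring(word, i + 2, n)))                # transpositions
  }
  if (n >= 1) {
    i <- rep(1:n, each = 26)
    out <- c(out, paste0(pre[i], letters_nl, suf[i + 1]))           # substitutions
  }
  i <- rep(1:(n + 1), each = 26)
  out <- c(out, paste0(pre[i], letters_nl, suf[i]))                 # insertions
  unique(out)
}

#' Norvig spelling correction of one token
#'
#' Classic frequency-lexicon-driven correction: a token found in the lexicon
#' is returned unchanged; otherwise the highest-frequency lexicon word
#' reachable by one edit (deletion, adjacent transposition, substitution,
#' insertion) is returned; otherwise the highest-frequency word reachable by
#' two edits; otherwise the token itself. Frequency ties break
#' lexicographically for determinism. Correction is per token, out of
#' context.
#'
#' @param token lowercase character scalar.
#' @param lexicon a [frequency_lexicon()].
#' @return The corrected token (always a single string).
#' @export
correct_spelling <- function(token, lexicon) {
  stopifnot(inherits(lexicon, "frequency_lexicon"))
  if (length(lexicon) == 0 || !nzchar(token)) return(token)
  words <- names(lexicon)
  if (token %in% words) return(token)
  e1 <- norvig_edits1(token)
  hits <- e1[e1 %in% words]
  if (length(hits) == 0) {
    # two edits: prefilter the lexicon before the expensive enumeration;
    # any word within two Norvig edits is within plain Levenshtein 4 and
    # within 2 in length difference.
    cand <- words[abs(nchar(words) - nchar(token)) <= 2L]
    if (length(cand)) {
      cand <- cand[utils::adist(token, cand)[1, ] <= 4L]
    }
    if (length(cand)) {
      e2 <- unique(unlist(lapply(e1, norvig_edits1), use.names = FALSE))
      hits <- cand[cand %in% e2]
    }
  }
  if (length(hits) == 0) return(token)
  freq <- unclass(lexicon)[hits]
  hits <- hits[order(-freq, hits)]
  hits[1]
}

#' Normalizer configuration
#'
#' Filtering rules applied after lemmatization: stopwords, a minimum word
#' length (default three letters), and a part-of-speech whitelist (default
#' verbs, adverbs, nouns and adjectives). Length and stopword tests apply to
#' the lemma.
#'
#' @param stopwords character vector of stopwords (lowercase).
#' @param min_word_length minimum lemma length kept (default 3).
#' @param kept_pos POS classes kept; non-empty subset of the tagger's tags.
#' @return A `normalizer_config` list.
#' @export
normalizer_config <- function(stopwords = character(),
                              min_word_length = 3L,
                              kept_pos = c("verb", "adverb", "noun", "adjective")) {
  min_word_length <- as.integer(min_word_length)
  if (min_word_length < 1L) stop("min_word_length must be >= 1")
  if (length(kept_pos) == 0) stop("kept_pos must be non-empty")
  structure(list(stopwords = tolower(stopwords),
                 min_word_length = min_word_length,
                 kept_pos = kept_pos),
            class = "normalizer_config")
}

#' Lemmatizer/POS-tagger plugins
#'
#' The normalizer delegates lemmatization and POS tagging to a plugin so a
#' full morphological tagger can be swapped in. `identity_plugin()` returns
#' each token as its own lemma tagged `"noun"` (nothing is removed by the
#' POS filter). `lookup_plugin()` wraps a rule list: a data frame with
#' columns `word`, `lemma`, `pos`; unlisted words fall back to identity.
#'
#' @param table for `lookup_plugin`, a data frame with columns `word`,
#'   `lemma`, `pos`.
#' @return A plugin: list with fields `name` and `tag(tokens)`, where `tag`
#'   returns a data frame with columns `lemma` and `pos`.
#' @export
identity_plugin <- function() {
  structure(list(
    name = "identity",
    tag = function(tokens) {
      data.frame(lemma = tokens, pos = rep("noun", length(tokens)),
                 stringsAsFactors = FALSE)
    }
  ), class = "lemma_plugin")
}

#' @rdname identity_plugin
#' @export
lookup_plugin <- function(table) {
  stopifnot(all(c("word", "lemma", "pos") %in% names(table)))
  tab <- table
  structure(list(
    name = "lookup",
    tag = function(tokens) {
      i <- match(tokens, tab$word)
      data.frame(
        lemma = ifelse(is.na(i), tokens, tab$lemma[i]),
        pos = ifelse(is.na(i), "noun", tab$pos[i]),
        stringsAsFactors = FALSE
      )
    }
  ), class = "lemma_plugin")
}

#' Lemmatize and filter tokens
#'
#' Each token is lemmatized by the plugin, then dropped if its lemma is a
#' stopword, shorter than `min_word_length`, or tagged with a POS class not
#' in `kept_pos`. Order of survivors is preserved.
#'
#' @param tokens lowercase character vector.
#' @param config a [normalizer_config()].
#' @param plugin a lemmatizer plugin ([identity_plugin()] by default).
#' @return Character vector of kept lemmas.
#' @export
normalize_tokens <- function(tokens, config = normalizer_config(),
                             plugin = identity_plugin()) {
  stopifnot(inherits(config, "normalizer_config"))
  if (length(tokens) == 0) return(character(0))
  tagged <- tryCatch(plugin$tag(tokens), error = function(e) {
    stop("lemmatizer plugin '", plugin$name, "' failed: ", conditionMessage(e))
  })
  keep <- !(tagged$lemma %in% config$stopwords) &
    nchar(tagged$lemma) >= config$min_word_length &
    tagged$pos %in% config$kept_pos
  tagged$lemma[keep]
}

#' Preprocess a response set into tokenized documents
#'
#' Runs the whole preprocessing chain per answer: tokenize, Norvig-correct
#' each token against the lexicon, lemmatize and filter. Keeps a per-token
#' provenance trace (raw, corrected, kept flag).
#'
#' @param responses a [response_set()].
#' @param lexicon a [frequency_lexicon()] for spelling correction; `NULL`
#'   skips correction.
#' @param config a [normalizer_config()].
#' @param plugin a lemmatizer plugin.
#' @return A list of `tokenized_doc`s: each has `doc_key`, `respondent_id`,
#'   `question_id`, `raw_tokens`, `corrected_tokens`, `kept_tokens` and a
#'   `provenance` data frame.
#' @export
preprocess_responses <- function(responses, lexicon = NULL,
                                 config = normalizer_config(),
                                 plugin = identity_plugin()) {
  stopifnot(inherits(responses, "response_set"))
  lapply(seq_len(nrow(responses)), function(i) {
    raw <- tokenize(responses$text[i])
    corrected <- if (is.null(lexicon) || length(raw) == 0) raw else {
      vapply(raw, correct_spelling, "", lexicon = lexicon, USE.NAMES = FALSE)
    }
    kept <- normalize_tokens(corrected, config, plugin)
    # provenance: a corrected token is "kept" if it survives filtering;
    # duplicates are matched greedily left to right
    kept_flag <- logical(length(corrected))
    j <- 1L
    for (t in seq_along(corrected)) {
      if (j <= length(kept) && identical(normalize_tokens(corrected[t], config, plugin),
                                         kept[j])) {
        kept_flag[t] <- TRUE
        j <- j + 1L
      }
    }
    structure(list(
      doc_key = doc_key(responses$respondent_id[i], responses$question_id[i]),
      respondent_id = responses$respondent_id[i],
      question_id = responses$question_id[i],
      raw_tokens = raw,
      corrected_tokens = corrected,
      kept_tokens = kept,
      provenance = data.frame(raw = raw, corrected = corrected,
                              kept = kept_flag, stringsAsFactors = FALSE)
    ), class = "tokenized_doc")
  })
}

ngrams_of <- function(tokens, nmin, nmax) {
  out <- character(0)
  for (n in nmin:nmax) {
    if (length(tokens) < n) break
    i <- 1:(length(tokens) - n + 1)
    out <- c(out, vapply(i, function(s) paste(tokens[s:(s + n - 1)], collapse = " "), ""))
  }
  out
}

#' Build a TF-IDF n-gram vector space
#'
#' Vocabulary is every contiguous n-gram (n in `ngram_min:ngram_max`) over
#' each document's kept tokens, occurring in at least `min_df` documents.
#' Weighting: tf = raw count, idf(t) = ln((1 + N) / (1 + df(t))) + 1 with N
#' the number of documents; each nonzero row is L2-normalized. N-grams are
#' formed over the filtered token sequence, so gaps left by removed tokens
#' close up.
#'
#' @param docs list of `tokenized_doc`s (from [preprocess_responses()]), or
#'   a plain list of character vectors of tokens.
#' @param ngram_min,ngram_max n-gram range (defaults 1 and 3).
#' @param min_df minimum document frequency for a term (default 1).
#' @return A `vector_space`: list with `vocab`, `idf`, `dtm` (dense docs ×
#'   terms matrix, rownames = doc keys), `doc_keys`, `empty_docs` (logical:
#'   all-zero rows) and `params`.
#' @export
build_vector_space <- function(docs, ngram_min = 1L, ngram_max = 3L, min_df = 1L) {
  if (length(docs) == 0) stop("no documents")
  tok_lists <- lapply(docs, function(d) {
    if (inherits(d, "tokenized_doc")) d$kept_tokens else as.character(d)
  })
  keys <- vapply(seq_along(docs), function(i) {
    d <- docs[[i]]
    if (inherits(d, "tokenized_doc")) d$doc_key else paste0("doc", i)
  }, "")
  grams <- lapply(tok_lists, ngrams_of, nmin = ngram_min, nmax = ngram_max)
  n_docs <- length(docs)
  df_tab <- table(unlist(lapply(grams, unique), use.names = FALSE))
  vocab <- sort(names(df_tab[df_tab >= min_df]))
  if (length(vocab) == 0) stop("all documents empty after preprocessing")
  dfreq <- as.integer(df_tab[vocab])
  idf <- log((1 + n_docs) / (1 + dfreq)) + 1
  dtm <- matrix(0, n_docs, length(vocab), dimnames = list(keys, vocab))
  for (i in seq_len(n_docs)) {
    if (length(grams[[i]]) == 0) next
    tf <- table(grams[[i]])
    terms <- intersect(names(tf), vocab)
    if (length(terms) == 0) next
    dtm[i, terms] <- as.numeric(tf[terms]) * idf[match(terms, vocab)]
  }
  nrm <- sqrt(rowSums(dtm^2))
  nz <- nrm > 0
  dtm[nz, ] <- dtm[nz, , drop = FALSE] / nrm[nz]
  structure(list(
    vocab = vocab, idf = stats::setNames(idf, vocab), dtm = dtm,
    doc_keys = keys, empty_docs = !nz,
    params = list(ngram_min = ngram_min, ngram_max = ngram_max,
                  min_df = min_df, tf = "raw count",
                  idf = "ln((1+N)/(1+df))+1", row_norm = "l2")
  ), class = "vector_space")
}

#' Project new documents into an existing vector space
#'
#' Applies the stored vocabulary and IDF weights (terms outside the
#' vocabulary are ignored), with the same L2 row normalization. Used to
#' vectorize unseen texts for a fitted classifier.
#'
#' @param docs as in [build_vector_space()].
#' @param space a fitted `vector_space`.
#' @return Dense docs × terms matrix aligned to `space$vocab`.
#' @export
project_vector_space <- function(docs, space) {
  stopifnot(inherits(space, "vector_space"))
  tok_lists <- lapply(docs, function(d) {
    if (inherits(d, "tokenized_doc")) d$kept_tokens else as.character(d)
  })
  p <- space$params
  mat <- matrix(0, length(docs), length(space$vocab),
                dimnames = list(NULL, space$vocab))
  for (i in seq_along(tok_lists)) {
    g <- ngrams_of(tok_lists[[i]], p$ngram_min, p$ngram_max)
    if (length(g) == 0) next
    tf <- table(g)
    terms <- intersect(names(tf), space$vocab)
    if (length(terms) == 0) next
    mat[i, terms] <- as.numeric(tf[terms]) * space$idf[terms]
  }
  nrm <- sqrt(rowSums(mat^2))
  nz <- nrm > 0
  mat[nz, ] <- mat[nz, , drop = FALSE] / nrm[nz]
  mat
}
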