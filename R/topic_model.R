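# NNDSVDa initialization (Boutsidis & Gallopoulos): SVD-based nonnegative
# init, with zeros replaced by the matrix mean so multiplicative updates
# cannot lock them at zero. Fully deterministic.
nndsvda_init <- function(X, k) {
  pospart <- function(v) pmax(v, 0)
  negpart <- function(v) pmax(-v, 0)
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pospart(u); un <- negpart(u)
      vp <- pospart(v); vn <- negpart(v)
      n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
      n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
      termp <- n_up * n_vp; termn <- n_un * n_vn
      if (termp >= termn && termp > 0) {
        W[, j] <- sqrt(s$d[j] * termp) * up / n_up
        H[j, ] <- sqrt(s$d[j] * termp) * vp / n_vp
      } else if (termn > 0) {
        W[, j] <- sqrt(s$d[j] * termn) * un / n_un
        H[j, ] <- sqrt(s$d[j] * termn) * vn / n_vn
      }
    }
  }
  avg <- mean(X)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorization
#'
#' Approximates a nonnegative matrix `X` as `W %*% H` with `W`, `H`
#' entrywise nonnegative, minimizing the Frobenius residual by
#' Lee–Seung multiplicative updates from a deterministic NNDSVDa
#' initialization. The objective is non-increasing over iterations; the
#' residual trajectory is returned for inspection.
#'
#' @param X nonnegative numeric matrix (documents x terms).
#' @param k number of factors, `2 <= k <= min(dim(X))` (k = 1 allowed for
#'   degenerate inputs).
#' @param seed integer seed (kept for the determinism contract and recorded;
#'   the fit itself is deterministic).
#' @param max_iter maximum multiplicative-update iterations (default 400).
#' @param tol relative-change stopping tolerance on the residual
#'   (default 1e-4).
#' @return List with `W` (docs x k), `H` (k x terms), `k`, `seed`,
#'   `iterations`, `residuals` (Frobenius residual per logged iteration) and
#'   `rel_error` (final relative residual).
#' @export
fit_nmf <- function(X, k, seed = 1L, max_iter = 400L, tol = 1e-4) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be entrywise nonnegative")
  k <- as.integer(k)
  if (k > min(dim(X))) {
    stop("k (", k, ") exceeds min(dim(X)) = ", min(dim(X)))
  }
  if (k < 1) stop("k must be >= 1")
  norm_x <- sqrt(sum(X^2))
  if (norm_x == 0) {
    return(list(W = matrix(0, nrow(X), k), H = matrix(0, k, ncol(X)),
                k = k, seed = seed, iterations = 0L, residuals = 0,
                rel_error = 0))
  }
  set.seed(seed)
  init <- nndsvda_init(X, k)
  W <- init$W; H <- init$H
  eps <- 1e-12
  residuals <- numeric(0)
  prev <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (iter %% 10L == 0L || iter == max_iter) {
      res <- sqrt(sum((X - W %*% H)^2))
      residuals <- c(residuals, res)
      if (is.finite(prev) && (prev - res) / norm_x < tol) break
      prev <- res
    }
  }
  res <- sqrt(sum((X - W %*% H)^2))
  list(W = W, H = H, k = k, seed = seed, iterations = iter,
       residuals = residuals, rel_error = res / norm_x)
}

embed_term <- function(term, embeddings) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  hit <- words[words %in% rownames(embeddings$vectors)]
  if (length(hit) == 0) return(NULL)
  v <- colMeans(embeddings$vectors[hit, , drop = FALSE])
  n <- sqrt(sum(v^2))
  if (n == 0) return(NULL)
  v / n
}

#' Embedding coherence of one topic
#'
#' Each top term (an n-gram) is embedded as the renormalized mean of its
#' in-vocabulary word vectors; terms with no in-vocabulary word are skipped.
#' Coherence is the mean pairwise cosine similarity over the embeddable
#' terms — exact duplicates contribute 1 and synonyms (nearby vectors) a
#' high value, so the score rewards semantically tight topics.
#'
#' @param topic_terms character vector of the topic's top n-grams.
#' @param embeddings an [embedding_table()].
#' @return A number in \[-1, 1\]; 0 (with a warning) when fewer than two
#'   terms can be embedded.
#' @export
topic_coherence <- function(topic_terms, embeddings) {
  vecs <- Filter(Negate(is.null), lapply(topic_terms, embed_term, embeddings))
  if (length(vecs) < 2) {
    warning("fewer than 2 embeddable terms; coherence set to 0")
    return(0)
  }
  V <- do.call(rbind, vecs)
  S <- tcrossprod(V)  # rows are unit vectors, so this is cosine
  mean(S[upper.tri(S)])
}

top_terms_of_row <- function(h_row, vocab, top_n = 10L) {
  nz <- which(h_row > 0)
  if (length(nz) == 0) return(character(0))
  # ties in weight break lexicographically for determinism
  ord <- nz[order(-h_row[nz], vocab[nz])]
  vocab[utils::head(ord, top_n)]
}

# distinct words occurring in the top-n terms of an H row, for coherence:
# scoring words (not n-grams) stops repeats of one word across its n-grams
# from counting as many perfect-similarity pairs
top_words_of_row <- function(h_row, vocab, top_n = 10L) {
  unique(unlist(strsplit(top_terms_of_row(h_row, vocab, top_n), " ",
                         fixed = TRUE), use.names = FALSE))
}

#' Select the number of topics by embedding coherence
#'
#' Fits one NMF per candidate k (the range is clipped to `min(dim(X))`),
#' scores each model as the mean of its per-topic coherences, and returns
#' the model with maximal coherence; exact ties go to the smallest k. Every
#' (k, coherence) pair is kept in the result for audit.
#'
#' A topic's coherence is computed over the distinct *words* occurring in
#' its `top_n` highest-weight n-grams (`coherence_on = "words"`, the
#' default): scoring words matches the idea of semantic similarity of the
#' words within a topic, and stops n-gram repeats of a single word (whose
#' embeddings are identical) from inflating the score of a degenerate,
#' over-split topic. `coherence_on = "ngrams"` scores the n-grams
#' themselves, each embedded as the mean of its word vectors.
#'
#' @param X nonnegative docs x terms matrix (TF-IDF rows).
#' @param vocab character vector naming the columns of `X`.
#' @param embeddings an [embedding_table()] for coherence.
#' @param k_range candidate topic counts (default 2:15).
#' @param seed integer seed passed to every [fit_nmf()] (no warm starts).
#' @param top_n number of top terms scored per topic (default 10).
#' @param coherence_on score the distinct `"words"` of the top terms
#'   (default) or the `"ngrams"` themselves.
#' @param max_iter,tol passed to [fit_nmf()].
#' @return A `topic_model`: the selected fit plus `k`, `coherence`,
#'   `per_topic_coherence`, `candidates` (data frame of k vs coherence),
#'   `vocab`, `seed`.
#' @export
select_k <- function(X, vocab, embeddings, k_range = 2:15, seed = 1L,
                     top_n = 10L, coherence_on = c("words", "ngrams"),
                     max_iter = 400L, tol = 1e-4) {
  stopifnot(ncol(X) == length(vocab))
  coherence_on <- match.arg(coherence_on)
  n_eff <- sum(rowSums(X) > 0)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= min(dim(X))]
  if (n_eff < 3 || length(k_range) == 0) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf("stratum too small (%d non-empty docs)", n_eff)),
                     class = c("skipped_stratum", "topic_model")))
  }
  candidates <- data.frame(k = k_range, coherence = NA_real_)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- fit_nmf(X, k_range[i], seed = seed, max_iter = max_iter, tol = tol)
    per_topic <- vapply(seq_len(fit$k), function(j) {
      terms <- if (coherence_on == "words") {
        top_words_of_row(fit$H[j, ], vocab, top_n)
      } else {
        top_terms_of_row(fit$H[j, ], vocab, top_n)
      }
      suppressWarnings(topic_coherence(terms, embeddings))
    }, 0)
    fit$per_topic_coherence <- per_topic
    fit$coherence <- mean(per_topic)
    fits[[i]] <- fit
    candidates$coherence[i] <- fit$coherence
  }
  best <- which(candidates$coherence == max(candidates$coherence))[1]  # tie -> smallest k
  out <- fits[[best]]
  out$candidates <- candidates
  out$vocab <- vocab
  out$coherence_on <- coherence_on
  out$skipped <- FALSE
  class(out) <- "topic_model"
  out
}

#' @export
print.topic_model <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<topic_model> skipped:", x$reason, "\n")
  } else {
    cat(sprintf("<topic_model> k = %d, coherence = %.3f (%d docs, %d terms)\n",
                x$k, x$coherence, nrow(x$W), length(x$vocab)))
  }
  invisible(x)
}

#' Assign documents to topics
#'
#' Each document goes to the argmax of its row of `W`; ties take the lowest
#' topic index. A document whose row is all zero (e.g. emptied by
#' preprocessing) is `NA` — unassigned. An optional minimum-weight threshold
#' `tau` also unassigns rows whose maximum weight is below it.
#'
#' @param W docs x k nonnegative weight matrix (rownames = doc keys).
#' @param tau minimum top weight for assignment (default 0 = zero-row rule).
#' @return Integer vector of topic indices in `1:k`, `NA` for unassigned,
#'   named by doc key when `W` has rownames.
#' @export
assign_topics <- function(W, tau = 0) {
  idx <- apply(W, 1, function(r) {
    m <- max(r)
    if (m <= 0 || m < tau) NA_integer_ else which.max(r)
  })
  out <- as.integer(idx)
  names(out) <- rownames(W)
  out
}

# TRUE if tokens `a` occur within tokens `b` in order (gaps allowed):
# "went well" is covered by "went very well"
is_token_subseq <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na >= nb) return(FALSE)
  j <- 1L
  for (i in seq_len(nb)) {
    if (b[i] == a[j]) {
      j <- j + 1L
      if (j > na) return(TRUE)
    }
  }
  FALSE
}

#' Human-readable topic descriptors
#'
#' From one topic's term weights: take the `top_terms` highest-weight
#' n-grams (weight ties break lexicographically), sort them by word count
#' descending (ties keep the weight order), drop any term whose tokens all
#' occur, in order, within a longer retained term (so a list never holds
#' both "went very well" and "went well"), and return the first `show`.
#'
#' @param h_row one row of `H` (length = vocabulary size).
#' @param vocab the vocabulary.
#' @param top_terms candidate pool size (default 10).
#' @param show maximum descriptors returned (default 5).
#' @return Character vector of at most `show` n-grams; empty (with a
#'   warning) for an all-zero row.
#' @export
topic_descriptors <- function(h_row, vocab, top_terms = 10L, show = 5L) {
  stopifnot(length(h_row) == length(vocab))
  top <- top_terms_of_row(h_row, vocab, top_terms)
  if (length(top) == 0) {
    warning("all-zero topic row; no descriptors")
    return(character(0))
  }
  toks <- strsplit(top, " ", fixed = TRUE)
  nwords <- lengths(toks)
  ord <- order(-nwords, seq_along(top))  # stable: weight order breaks ties
  top <- top[ord]; toks <- toks[ord]
  keep <- rep(TRUE, length(top))
  for (i in seq_along(top)) {
    if (!keep[i]) next
    for (j in seq_along(top)) {
      if (i == j || !keep[j]) next
      if (is_token_subseq(toks[[j]], toks[[i]])) keep[j] <- FALSE
    }
  }
  utils::head(top[keep], show)
}

#' Fit topic models for every (question, sentiment) stratum
#'
#' Splits labeled answers into strata — one per question and sentiment in
#' \{positive, negative\}; neutral answers are never modeled — builds a
#' TF-IDF space per stratum and runs coherence-based model selection.
#' Strata with fewer than `min_docs` non-empty documents are reported as
#' skipped, not an error.
#'
#' @param responses a [response_set()].
#' @param labels data frame from [predict_sentiment()] (or gold labels) with
#'   `respondent_id`, `question_id`, `label`.
#' @param embeddings an [embedding_table()].
#' @param lexicon optional [frequency_lexicon()] for spelling correction.
#' @param config a [normalizer_config()].
#' @param plugin lemmatizer plugin.
#' @param k_range,seed,top_n,max_iter,tol passed to [select_k()].
#' @param min_docs minimum non-empty documents to model a stratum (default 3).
#' @param ngram_max,min_df vector-space parameters (defaults 3 and 1).
#' @return A named list of strata; each element holds `question_id`,
#'   `sentiment`, `doc_keys`, `model` (a `topic_model`, possibly skipped),
#'   `assignment` (from [assign_topics()]), `descriptors` and `counts`
#'   (per-topic document counts plus `unassigned`).
#' @export
fit_strata <- function(responses, labels, embeddings, lexicon = NULL,
                       config = normalizer_config(), plugin = identity_plugin(),
                       k_range = 2:15, seed = 1L, top_n = 10L,
                       max_iter = 400L, tol = 1e-4, min_docs = 3L,
                       ngram_max = 3L, min_df = 1L) {
  stopifnot(inherits(responses, "response_set"))
  key_r <- doc_key(responses$respondent_id, responses$question_id)
  key_l <- doc_key(labels$respondent_id, labels$question_id)
  lab <- labels$label[match(key_r, key_l)]
  if (anyNA(lab)) {
    stop("labels missing for keys: ",
         paste(utils::head(key_r[is.na(lab)], 5), collapse = ", "))
  }
  schema <- attr(responses, "schema")
  out <- list()
  for (q in schema$question_id) {
    for (s in c("positive", "negative")) {
      sel <- responses$question_id == q & lab == s & !responses$empty
      if (!any(sel)) next
      sub <- responses[sel, , drop = FALSE]
      attr(sub, "schema") <- schema
      class(sub) <- c("response_set", "data.frame")
      docs <- preprocess_responses(sub, lexicon, config, plugin)
      keys <- vapply(docs, `[[`, "", "doc_key")
      stratum <- list(question_id = q, sentiment = s, doc_keys = keys)
      nonempty_docs <- sum(lengths(lapply(docs, `[[`, "kept_tokens")) > 0)
      if (nonempty_docs < min_docs) {
        stratum$model <- structure(
          list(skipped = TRUE,
               reason = sprintf("stratum too small (%d non-empty docs)", nonempty_docs)),
          class = c("skipped_stratum", "topic_model"))
        stratum$assignment <- stats::setNames(rep(NA_integer_, length(keys)), keys)
        stratum$descriptors <- list()
        stratum$counts <- list(topic = integer(0), unassigned = length(keys))
      } else {
        space <- build_vector_space(docs, ngram_min = 1L, ngram_max = ngram_max,
                                    min_df = min_df)
        model <- select_k(space$dtm, space$vocab, embeddings, k_range = k_range,
                          seed = seed, top_n = top_n, max_iter = max_iter, tol = tol)
        if (isTRUE(model$skipped)) {
          stratum$model <- model
          stratum$assignment <- stats::setNames(rep(NA_integer_, length(keys)), keys)
          stratum$descriptors <- list()
          stratum$counts <- list(topic = integer(0), unassigned = length(keys))
        } else {
          rownames(model$W) <- space$doc_keys
          assignment <- assign_topics(model$W)
          descriptors <- lapply(seq_len(model$k), function(j) {
            suppressWarnings(topic_descriptors(model$H[j, ], model$vocab,
                                               top_terms = top_n))
          })
          counts <- vapply(seq_len(model$k), function(j) {
            sum(assignment == j, na.rm = TRUE)
          }, 0L)
          stratum$model <- model
          stratum$assignment <- assignment
          stratum$descriptors <- descriptors
          stratum$counts <- list(topic = counts, unassigned = sum(is.na(assignment)))
        }
      }
      out[[paste(q, s, sep = ".")]] <- stratum
    }
  }
  out
}
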