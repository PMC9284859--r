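#' Bag-of-words linear classifier backend
#'
#' Default binary classifier behind the sentiment cascade: TF-IDF
#' unigram+bigram features into an L2-regularized (ridge) logistic
#' regression via glmnet, with inverse-frequency class weights so the
#' minority class (negative answers are rare in satisfied patient groups)
#' is not swamped by the intercept. The backend satisfies the pluggable
#' contract used by [train_cascade()]: any object with `backend_fit()` and
#' `backend_predict()` methods (deterministic given a training seed) can
#' replace it, e.g. a transformer-based classifier.
#'
#' @param ngram_max maximum n-gram length of the features (default 2).
#' @param lambda ridge penalty used at prediction time (default 0.001).
#' @param balanced use inverse-class-frequency observation weights
#'   (default `TRUE`).
#' @return An unfitted `bow_backend`.
#' @export
bow_backend <- function(ngram_max = 2L, lambda = 0.001, balanced = TRUE) {
  structure(list(name = "bow-ridge", ngram_max = as.integer(ngram_max),
                 lambda = lambda, balanced = isTRUE(balanced),
                 is_fitted = FALSE),
            class = c("bow_backend", "classifier_backend"))
}

#' Fit / predict generics of the classifier-backend contract
#'
#' @param backend a classifier backend.
#' @param texts character vector of raw answer texts.
#' @param labels binary labels, parallel to `texts` (exactly two classes).
#' @param seed integer training seed; fits are deterministic given it.
#' @return `backend_fit` returns the fitted backend; `backend_predict` a
#'   character vector of predicted labels.
#' @export
backend_fit <- function(backend, texts, labels, seed = 1L) UseMethod("backend_fit")

#' @rdname backend_fit
#' @export
backend_predict <- function(backend, texts) UseMethod("backend_predict")

#' @export
backend_fit.bow_backend <- function(backend, texts, labels, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop("backend_fit needs exactly 2 classes, got ", length(classes))
  }
  toks <- lapply(texts, tokenize)
  space <- build_vector_space(toks, ngram_min = 1L,
                              ngram_max = backend$ngram_max, min_df = 1L)
  x <- space$dtm
  y <- as.integer(labels == classes[2])
  w <- if (backend$balanced) {
    length(y) / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  } else {
    rep(1, length(y))
  }
  set.seed(seed)
  fit <- glmnet::glmnet(x, factor(y, levels = 0:1), family = "binomial",
                        alpha = 0, lambda = c(1, 0.1, backend$lambda),
                        weights = w, standardize = FALSE)
  backend$space <- space
  backend$fit <- fit
  backend$classes <- classes
  backend$seed <- seed
  backend$is_fitted <- TRUE
  backend
}

#' @export
backend_predict.bow_backend <- function(backend, texts) {
  if (!isTRUE(backend$is_fitted)) stop("backend is not fitted")
  toks <- lapply(texts, tokenize)
  x <- project_vector_space(toks, backend$space)
  p <- as.numeric(stats::predict(backend$fit, newx = x, s = backend$lambda,
                                 type = "response"))
  backend$classes[(p > 0.5) + 1L]
}

#' Train the two-stage sentiment cascade
#'
#' Stage A is a binary classifier for negative vs non-negative, fitted on
#' all annotated non-empty answers; stage B separates positive from neutral
#' and is fitted only on the gold non-negative subset, mirroring the cascade
#' at inference time. Annotated answers are split once into training and
#' held-out sets (default 80/20) by the given seed, and each stage is
#' evaluated on its held-out portion.
#'
#' @param annotated data frame with columns `text` and `label`
#'   (negative/neutral/positive); empty texts are dropped before training.
#' @param backend_factory zero-argument function returning a fresh unfitted
#'   backend (default [bow_backend()]).
#' @param split_fraction fraction of data used for training (default 0.8).
#' @param seed integer seed controlling the split and backend training.
#' @return A list: `model` (a `cascade_model`), `eval_a` and `eval_b`
#'   (`eval_report`s for the two stages on the held-out split).
#' @export
train_cascade <- function(annotated, backend_factory = bow_backend,
                          split_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(annotated), all(c("text", "label") %in% names(annotated)))
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)")
  }
  annotated <- annotated[nzchar(trimws(annotated$text)), , drop = FALSE]
  if (nrow(annotated) == 0) stop("no non-empty annotated answers")
  bad <- !(annotated$label %in% c("negative", "neutral", "positive"))
  if (any(bad)) stop("invalid label: ", annotated$label[which(bad)[1]])

  set.seed(seed)
  n <- nrow(annotated)
  idx_train <- sort(sample.int(n, size = floor(split_fraction * n)))
  idx_val <- setdiff(seq_len(n), idx_train)
  if (length(idx_val) == 0 || length(idx_train) == 0) {
    stop("split leaves an empty training or validation set")
  }
  train <- annotated[idx_train, ]
  val <- annotated[idx_val, ]

  # stage A: negative vs non-negative, on everything
  ya_train <- ifelse(train$label == "negative", "negative", "non_negative")
  if (length(unique(ya_train)) < 2) {
    stop("degenerate training set for stage A (negative vs non-negative): only one class")
  }
  stage_a <- backend_fit(backend_factory(), train$text, ya_train, seed = seed)

  # stage B: positive vs neutral, on the gold non-negative subset
  train_b <- train[train$label != "negative", ]
  if (nrow(train_b) == 0 || length(unique(train_b$label)) < 2) {
    stop("degenerate training set for stage B (positive vs neutral): only one class")
  }
  stage_b <- backend_fit(backend_factory(), train_b$text, train_b$label, seed = seed)

  model <- structure(list(stage_a = stage_a, stage_b = stage_b,
                          split_fraction = split_fraction, seed = seed),
                     class = "cascade_model")

  ya_val <- ifelse(val$label == "negative", "negative", "non_negative")
  pred_a <- backend_predict(stage_a, val$text)
  eval_a <- eval_report(ya_val, pred_a, n_train = nrow(train), n_val = nrow(val))

  val_b <- val[val$label != "negative", ]
  pred_b <- backend_predict(stage_b, val_b$text)
  eval_b <- eval_report(val_b$label, pred_b,
                        n_train = nrow(train_b), n_val = nrow(val_b))

  list(model = model, eval_a = eval_a, eval_b = eval_b)
}

#' Predict three-class sentiment with the cascade
#'
#' A text is negative iff stage A says negative; otherwise the label is
#' stage B's positive/neutral prediction. Empty answers get the neutral
#' label by convention (they describe no situation) and never reach the
#' classifiers.
#'
#' @param model a fitted `cascade_model`.
#' @param responses a [response_set()], or a character vector of texts.
#' @return Data frame with `respondent_id`, `question_id` (when available),
#'   `text` and `label`; one row per input answer.
#' @export
predict_sentiment <- function(model, responses) {
  stopifnot(inherits(model, "cascade_model"))
  if (!isTRUE(model$stage_a$is_fitted) || !isTRUE(model$stage_b$is_fitted)) {
    stop("cascade model is not fitted")
  }
  if (inherits(responses, "response_set")) {
    out <- data.frame(respondent_id = responses$respondent_id,
                      question_id = responses$question_id,
                      text = responses$text, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(text = as.character(responses), stringsAsFactors = FALSE)
  }
  label <- rep("neutral", nrow(out))
  nonempty <- nzchar(trimws(out$text))
  if (any(nonempty)) {
    texts <- out$text[nonempty]
    a <- backend_predict(model$stage_a, texts)
    lab <- ifelse(a == "negative", "negative", NA_character_)
    todo <- is.na(lab)
    if (any(todo)) lab[todo] <- backend_predict(model$stage_b, texts[todo])
    label[nonempty] <- lab
  }
  out$label <- label
  out
}

#' Precision, recall and F1 for one target class
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn), F1 = 2pr/(p+r); each is 0
#' when its denominator is 0.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param target_class the class scored as positive.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
eval_metrics <- function(true_labels, predicted_labels, target_class) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(predicted_labels), ")")
  }
  tp <- sum(true_labels == target_class & predicted_labels == target_class)
  fp <- sum(true_labels != target_class & predicted_labels == target_class)
  fn <- sum(true_labels == target_class & predicted_labels != target_class)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Per-class evaluation report
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param n_train,n_val split sizes recorded in the report.
#' @return An `eval_report`: per-class precision/recall/F1 data frame,
#'   confusion table, macro F1, split sizes.
#' @export
eval_report <- function(true_labels, predicted_labels,
                        n_train = NA_integer_, n_val = length(true_labels)) {
  classes <- sort(unique(c(true_labels, predicted_labels)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    m <- eval_metrics(true_labels, predicted_labels, cl)
    data.frame(class = cl, precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]],
               support = sum(true_labels == cl), stringsAsFactors = FALSE)
  }))
  structure(list(
    per_class = per_class,
    confusion = table(true = factor(true_labels, classes),
                      predicted = factor(predicted_labels, classes)),
    macro_f1 = mean(per_class$f1),
    n_train = n_train, n_val = n_val
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n_val = %d, macro F1 = %.3f\n", x$n_val, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Percent agreement between two annotators
#'
#' The fraction of aligned items on which both annotators gave the same
#' label. If `keys_a`/`keys_b` are given, the vectors are aligned on them
#' first and a mismatch in key sets is an error.
#'
#' @param labels_a,labels_b label vectors.
#' @param keys_a,keys_b optional alignment keys (e.g. respondent::question).
#' @return A number in \[0, 1\].
#' @export
percent_agreement <- function(labels_a, labels_b, keys_a = NULL, keys_b = NULL) {
  if (!is.null(keys_a) || !is.null(keys_b)) {
    extra_a <- setdiff(keys_a, keys_b)
    extra_b <- setdiff(keys_b, keys_a)
    if (length(extra_a) || length(extra_b)) {
      stop("annotator key sets differ; only in A: {",
           paste(extra_a, collapse = ", "), "}; only in B: {",
           paste(extra_b, collapse = ", "), "}")
    }
    labels_b <- labels_b[match(keys_a, keys_b)]
  }
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0) {
    stop("label vectors must be non-empty and of equal length")
  }
  mean(labels_a == labels_b)
}
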