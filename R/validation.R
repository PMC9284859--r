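#' Stratified sampling plan for manual topic review
#'
#' For each topic, the review sample holds all documents when the topic has
#' fewer than `min_n`, and otherwise `max(ceiling(frac * size), min_n)`
#' documents drawn without replacement. Defaults mirror reviewing 20% of
#' the answers per topic with a minimum of ten texts.
#'
#' @param assignments named integer vector from [assign_topics()] (names =
#'   doc keys, `NA` = unassigned; unassigned docs are not sampled).
#' @param frac sampling fraction in (0, 1\] (default 0.2).
#' @param min_n minimum sample per topic (default 10).
#' @param seed integer seed; the plan is deterministic given it.
#' @return A `sampling_plan`: list with `samples` (per topic, the sampled
#'   doc keys), `sizes` (data frame topic/size/sampled), `frac`, `min_n`,
#'   `seed`.
#' @export
make_sampling_plan <- function(assignments, frac = 0.2, min_n = 10L, seed = 1L) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (is.null(names(assignments))) stop("assignments must be named by doc key")
  assigned <- assignments[!is.na(assignments)]
  topics <- sort(unique(assigned))
  set.seed(seed)
  samples <- list()
  sizes <- data.frame(topic = integer(0), size = integer(0), sampled = integer(0))
  for (t in topics) {
    keys <- names(assigned)[assigned == t]
    n <- length(keys)
    take <- sampling_plan_size(n, frac, min_n)
    samples[[as.character(t)]] <- sort(sample(keys, take))
    sizes <- rbind(sizes, data.frame(topic = t, size = n, sampled = take))
  }
  structure(list(samples = samples, sizes = sizes,
                 frac = frac, min_n = as.integer(min_n), seed = seed),
            class = "sampling_plan")
}

#' Closed-form review-sample size
#'
#' @param n topic size.
#' @param frac,min_n as in [make_sampling_plan()].
#' @return `n` if `n < min_n`, else `max(ceiling(frac * n), min_n)`.
#' @export
sampling_plan_size <- function(n, frac = 0.2, min_n = 10L) {
  ifelse(n < min_n, n, pmax(ceiling(frac * n), min_n))
}

#' Representativeness rates from fit judgments
#'
#' Representativeness of a topic is the fraction of its reviewed texts that
#' the judge deemed to fit the topic. Stratum and overall rates pool counts
#' (sum of fits over sum judged), not averages of rates.
#'
#' @param judgments data frame with columns `doc_key`, `stratum`, `topic`,
#'   `judge_id`, `fits` (logical or 0/1).
#' @param judge_id the judge whose judgments are scored.
#' @param plan optional [make_sampling_plan()] (or a named list of plans per
#'   stratum); when given, missing judgments for planned samples are an
#'   error.
#' @return List with `per_topic` (data frame stratum/topic/fits/judged/rate),
#'   `per_stratum`, and `overall` (pooled rate in \[0, 1\]).
#' @export
representativeness <- function(judgments, judge_id, plan = NULL) {
  need <- c("doc_key", "stratum", "topic", "judge_id", "fits")
  stopifnot(all(need %in% names(judgments)))
  j <- judgments[judgments$judge_id == judge_id, , drop = FALSE]
  if (nrow(j) == 0) stop("no judgments for judge ", judge_id)
  if (anyDuplicated(j[, c("doc_key", "topic", "stratum")])) {
    stop("duplicate judgment for a (doc, topic) pair")
  }
  if (!is.null(plan)) {
    plans <- if (inherits(plan, "sampling_plan")) list(plan) else plan
    planned <- unlist(lapply(plans, function(p) unlist(p$samples)), use.names = FALSE)
    gaps <- setdiff(planned, j$doc_key)
    if (length(gaps)) {
      stop("missing judgments for planned docs: ",
           paste(utils::head(gaps, 5), collapse = ", "),
           if (length(gaps) > 5) sprintf(" (and %d more)", length(gaps) - 5) else "")
    }
  }
  fits <- as.logical(j$fits)
  grp <- interaction(j$stratum, j$topic, drop = TRUE, sep = "\r")
  per_topic <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(stratum = parts[1], topic = parts[2],
               fits = sum(fits[sel]), judged = sum(sel),
               rate = sum(fits[sel]) / sum(sel), stringsAsFactors = FALSE)
  }))
  per_stratum <- do.call(rbind, lapply(unique(j$stratum), function(s) {
    sel <- j$stratum == s
    data.frame(stratum = s, fits = sum(fits[sel]), judged = sum(sel),
               rate = sum(fits[sel]) / sum(sel), stringsAsFactors = FALSE)
  }))
  list(per_topic = per_topic, per_stratum = per_stratum,
       overall = sum(fits) / length(fits))
}

#' Proportion of manual topics matched by automatic topics
#'
#' The matching itself is expert input (a pairing of manual to automatic
#' topics); the proportion is the number of distinct matched manual topics
#' over the number of manual topics.
#'
#' @param manual_topics character vector of manual topic names.
#' @param matches data frame with columns `manual_topic`, `auto_topic` (or a
#'   character vector of matched manual topic names).
#' @return A proportion in \[0, 1\].
#' @export
topic_overlap <- function(manual_topics, matches) {
  if (length(manual_topics) == 0) stop("no manual topics")
  matched <- if (is.data.frame(matches)) matches$manual_topic else as.character(matches)
  unknown <- setdiff(matched, manual_topics)
  if (length(unknown)) {
    stop("match names unknown manual topic(s): ", paste(unknown, collapse = ", "))
  }
  length(unique(matched)) / length(unique(manual_topics))
}

#' Two-sample comparison of matched numeric scores
#'
#' Independent-samples t-test between the structured scores of the positive
#' and negative sentiment groups, from raw scores or from summary
#' statistics. The pooled (Student) variant is the default; Welch is
#' selectable and both report t, degrees of freedom and the two-sided p.
#'
#' @param scores_pos,scores_neg numeric score vectors, or summary lists
#'   `list(n =, mean =, sd =)`.
#' @param variant `"pooled"` or `"welch"`.
#' @param question_id optional id recorded in the result.
#' @return A `group_comparison`: list with `n_pos`, `n_neg`, `mean_pos`,
#'   `mean_neg`, `sd_pos`, `sd_neg`, `t`, `df`, `p`, `variant`,
#'   `question_id`.
#' @export
compare_groups <- function(scores_pos, scores_neg,
                           variant = c("pooled", "welch"), question_id = NA) {
  variant <- match.arg(variant)
  summarize <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("n", "mean", "sd") %in% names(x)))
      list(n = x$n, m = x$mean, s = x$sd)
    } else {
      if (length(x) < 2) stop("each group needs at least 2 observations")
      list(n = length(x), m = mean(x), s = stats::sd(x))
    }
  }
  a <- summarize(scores_pos); b <- summarize(scores_neg)
  if (a$n < 2 || b$n < 2) stop("each group needs at least 2 observations")
  if (a$s < 0 || b$s < 0) stop("standard deviations must be nonnegative")
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$s^2 / a$n; vb <- b$s^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  if (se == 0) {
    t_stat <- if (a$m == b$m) 0 else sign(a$m - b$m) * Inf
    p <- if (a$m == b$m) 1 else 0
    if (variant == "welch") df <- a$n + b$n - 2  # zero-variance fallback
  } else {
    t_stat <- (a$m - b$m) / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(question_id = question_id,
                 n_pos = a$n, n_neg = b$n,
                 mean_pos = a$m, mean_neg = b$m,
                 sd_pos = a$s, sd_neg = b$s,
                 t = t_stat, df = df, p = p, variant = variant),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison%s> pos %d (%.2f +/- %.2f) vs neg %d (%.2f +/- %.2f): t = %.3f, df = %.2f, p = %.3g [%s]\n",
              if (is.na(x$question_id)) "" else paste0(" ", x$question_id),
              x$n_pos, x$mean_pos, x$sd_pos, x$n_neg, x$mean_neg, x$sd_neg,
              x$t, x$df, x$p, x$variant))
  invisible(x)
}

#' Compare matched scores per question between sentiment groups
#'
#' Joins structured scores to predicted (or gold) sentiment labels and runs
#' [compare_groups()] per question. No multiple-testing correction is
#' applied across questions; that is recorded in the result.
#'
#' @param scores data frame from [load_scores()].
#' @param labels data frame with `respondent_id`, `question_id`, `label`.
#' @param variant `"pooled"` or `"welch"`.
#' @return Data frame with one row per question that has at least two
#'   scores in each group, plus attribute `multiple_testing = "none"`.
#' @export
compare_scores_by_sentiment <- function(scores, labels,
                                        variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  key_s <- doc_key(scores$respondent_id, scores$question_id)
  key_l <- doc_key(labels$respondent_id, labels$question_id)
  lab <- labels$label[match(key_s, key_l)]
  rows <- list()
  for (q in unique(scores$question_id)) {
    pos <- scores$score[scores$question_id == q & lab == "positive" & !is.na(lab)]
    neg <- scores$score[scores$question_id == q & lab == "negative" & !is.na(lab)]
    if (length(pos) < 2 || length(neg) < 2) next
    cmp <- compare_groups(pos, neg, variant = variant, question_id = q)
    rows[[q]] <- data.frame(question_id = q, n_pos = cmp$n_pos, n_neg = cmp$n_neg,
                            mean_pos = cmp$mean_pos, mean_neg = cmp$mean_neg,
                            sd_pos = cmp$sd_pos, sd_neg = cmp$sd_neg,
                            t = cmp$t, df = cmp$df, p = cmp$p,
                            variant = cmp$variant, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(question_id = character(0))
  rownames(out) <- NULL
  attr(out, "multiple_testing") <- "none"
  out
}
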