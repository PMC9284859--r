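round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble the three-stage hierarchical report
#'
#' Stage 1 summarizes sentiment per question (counts and percentages of
#' positive and negative answers over all respondents who received the
#' question, including neutral and empty — the fixed denominator). Stage 2
#' lists, per (question, sentiment) stratum, the topics with their
#' descriptors and document counts plus the unassigned count, ordered by
#' count descending. Stage 3 holds the verbatim answers per topic, so a
#' reader can drill from the overview down to the original texts.
#'
#' @param responses a [response_set()].
#' @param labels data frame with `respondent_id`, `question_id`, `label`
#'   covering every response.
#' @param strata result of [fit_strata()].
#' @param manifest optional named list recorded verbatim (seeds, config).
#' @return A `prem_report` list with fields `stage1`, `stage2`, `stage3`,
#'   `manifest`, `schema_version`.
#' @export
build_report <- function(responses, labels, strata = list(), manifest = list()) {
  stopifnot(inherits(responses, "response_set"))
  key_r <- doc_key(responses$respondent_id, responses$question_id)
  key_l <- doc_key(labels$respondent_id, labels$question_id)
  lab <- labels$label[match(key_r, key_l)]
  if (anyNA(lab)) {
    stop("labels missing for keys: ",
         paste(utils::head(key_r[is.na(lab)], 5), collapse = ", "))
  }
  schema <- attr(responses, "schema")
  stage1 <- do.call(rbind, lapply(schema$question_id, function(q) {
    sel <- responses$question_id == q
    n <- sum(sel)
    n_empty <- sum(sel & responses$empty)
    n_pos <- sum(sel & !responses$empty & lab == "positive")
    n_neg <- sum(sel & !responses$empty & lab == "negative")
    n_neu <- sum(sel & !responses$empty & lab == "neutral")
    data.frame(question_id = q, n_total = n, n_positive = n_pos,
               n_negative = n_neg, n_neutral = n_neu, n_empty = n_empty,
               pct_positive = if (n > 0) round_half_up(100 * n_pos / n) else 0,
               pct_negative = if (n > 0) round_half_up(100 * n_neg / n) else 0,
               all_empty = n > 0 && n_empty == n,
               stringsAsFactors = FALSE)
  }))

  text_of <- stats::setNames(responses$text, key_r)
  stage2 <- list(); stage3 <- list()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    if (isTRUE(st$model$skipped)) {
      stage2[[nm]] <- list(question_id = st$question_id, sentiment = st$sentiment,
                           skipped = TRUE, reason = st$model$reason,
                           topics = list(), unassigned = st$counts$unassigned)
      next
    }
    missing_keys <- setdiff(st$doc_keys, names(st$assignment))
    if (length(missing_keys)) {
      stop("assignments missing for keys: ",
           paste(utils::head(missing_keys, 5), collapse = ", "))
    }
    ord <- order(-st$counts$topic, seq_along(st$counts$topic))
    topics <- lapply(ord, function(j) {
      list(topic = j, descriptors = as.list(st$descriptors[[j]]),
           count = st$counts$topic[j])
    })
    stage2[[nm]] <- list(question_id = st$question_id, sentiment = st$sentiment,
                         skipped = FALSE, k = st$model$k,
                         coherence = st$model$coherence,
                         topics = topics, unassigned = st$counts$unassigned)
    stage3[[nm]] <- lapply(seq_len(st$model$k), function(j) {
      keys <- names(st$assignment)[!is.na(st$assignment) & st$assignment == j]
      list(topic = j,
           texts = lapply(keys, function(k)
             list(doc_key = k, text = unname(text_of[k]))))
    })
  }
  structure(list(schema_version = "1.0", stage1 = stage1,
                 stage2 = stage2, stage3 = stage3, manifest = manifest),
            class = "prem_report")
}

#' @export
print.prem_report <- function(x, ...) {
  cat("<prem_report> stage 1 (sentiment per question):\n")
  print(x$stage1[, c("question_id", "n_total", "n_positive", "n_negative",
                     "pct_positive", "pct_negative")], row.names = FALSE)
  cat(sprintf("stage 2: %d strata with topic models\n", length(x$stage2)))
  invisible(x)
}

#' Export / import a report as schema-versioned JSON
#'
#' The JSON round-trips losslessly: `import_report(export_json(r)) `
#' reproduces every field of `r`, including the manifest.
#'
#' @param report a `prem_report`.
#' @param path output (input) path.
#' @return `export_json` returns `path` invisibly; `import_report` a
#'   `prem_report`.
#' @export
export_json <- function(report, path) {
  stopifnot(inherits(report, "prem_report"))
  payload <- list(schema_version = report$schema_version,
                  stage1 = report$stage1, stage2 = report$stage2,
                  stage3 = report$stage3, manifest = report$manifest)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) stop("cannot write report JSON to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname export_json
#' @export
import_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stage1 <- do.call(rbind, lapply(raw$stage1, function(r)
    data.frame(question_id = r$question_id, n_total = r$n_total,
               n_positive = r$n_positive, n_negative = r$n_negative,
               n_neutral = r$n_neutral, n_empty = r$n_empty,
               pct_positive = r$pct_positive, pct_negative = r$pct_negative,
               all_empty = r$all_empty, stringsAsFactors = FALSE)))
  stage2 <- lapply(raw$stage2, function(s) {
    s$topics <- lapply(s$topics, function(t) {
      t$descriptors <- lapply(t$descriptors, identity)
      t
    })
    s
  })
  structure(list(schema_version = raw$schema_version, stage1 = stage1,
                 stage2 = stage2, stage3 = raw$stage3,
                 manifest = raw$manifest),
            class = "prem_report")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# radar-plot polygon points for one percentage series on a 0-100% scale
spider_points <- function(pct, cx = 200, cy = 200, r = 150) {
  n <- length(pct)
  ang <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
  paste(sprintf("%.1f,%.1f", cx + r * (pct / 100) * cos(ang),
                cy + r * (pct / 100) * sin(ang)), collapse = " ")
}

#' Render the report as a static HTML page
#'
#' Stage 1 is an inline-SVG spider (radar) plot of the positive and
#' negative percentages per question; stages 2 and 3 are progressive
#' disclosure (`<details>`) panels per stratum: topic descriptors with
#' counts, expandable to the verbatim answers. Entirely self-contained —
#' no scripts, no server.
#'
#' @param report a `prem_report`.
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
render_html <- function(report, path) {
  stopifnot(inherits(report, "prem_report"))
  s1 <- report$stage1
  n_q <- nrow(s1)
  ang <- 2 * pi * (seq_len(n_q) - 1) / n_q - pi / 2
  axis_lines <- paste(sprintf(
    '<line x1="200" y1="200" x2="%.1f" y2="%.1f" stroke="#ccc"/><text x="%.1f" y="%.1f" font-size="12" text-anchor="middle">%s</text>',
    200 + 150 * cos(ang), 200 + 150 * sin(ang),
    200 + 168 * cos(ang), 200 + 168 * sin(ang), html_escape(s1$question_id)),
    collapse = "\n")
  rings <- paste(sprintf(
    '<circle cx="200" cy="200" r="%d" fill="none" stroke="#eee"/>',
    c(37, 75, 112, 150)), collapse = "\n")
  svg <- sprintf(paste0(
    '<svg viewBox="0 0 400 400" width="400" height="400" role="img">\n%s\n%s\n',
    '<polygon points="%s" fill="rgba(46,139,87,0.25)" stroke="seagreen"/>\n',
    '<polygon points="%s" fill="rgba(178,34,34,0.25)" stroke="firebrick"/>\n</svg>'),
    rings, axis_lines,
    spider_points(s1$pct_positive), spider_points(s1$pct_negative))

  panels <- character(0)
  for (nm in names(report$stage2)) {
    s2 <- report$stage2[[nm]]
    head_txt <- sprintf("%s \u2014 %s answers", s2$question_id, s2$sentiment)
    if (isTRUE(s2$skipped)) {
      panels <- c(panels, sprintf(
        '<details class="stratum"><summary>%s (not modeled: %s)</summary></details>',
        html_escape(head_txt), html_escape(s2$reason)))
      next
    }
    topic_blocks <- vapply(s2$topics, function(t) {
      texts <- report$stage3[[nm]][[t$topic]]$texts
      verbatim <- paste(vapply(texts, function(x)
        sprintf("<li>%s</li>", html_escape(x$text)), ""), collapse = "\n")
      sprintf(paste0(
        '<details class="topic"><summary>Topic %d (%d texts): %s</summary>',
        '<ul>%s</ul></details>'),
        t$topic, t$count,
        html_escape(paste(unlist(t$descriptors), collapse = ", ")), verbatim)
    }, "")
    panels <- c(panels, sprintf(
      '<details class="stratum"><summary>%s (%d topics, %d unassigned)</summary>\n%s\n</details>',
      html_escape(head_txt), s2$k, s2$unassigned,
      paste(topic_blocks, collapse = "\n")))
  }

  tbl_rows <- paste(sprintf(
    "<tr><td>%s</td><td>%d</td><td>%d (%.1f%%)</td><td>%d (%.1f%%)</td><td>%d</td><td>%d</td></tr>",
    html_escape(s1$question_id), s1$n_total, s1$n_positive, s1$pct_positive,
    s1$n_negative, s1$pct_negative, s1$n_neutral, s1$n_empty), collapse = "\n")

  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\"><head><meta charset=\"utf-8\">",
    "<title>Patient experience report</title>\n<style>",
    "body{font-family:sans-serif;max-width:60em;margin:2em auto;padding:0 1em}",
    "table{border-collapse:collapse}td,th{border:1px solid #ddd;padding:.3em .6em}",
    "details.stratum{margin:.5em 0;border:1px solid #ddd;padding:.4em}",
    "details.topic{margin:.3em 1em}footer{color:#888;font-size:.8em;margin-top:2em}",
    "</style></head><body>\n",
    "<h1>Patient experience report</h1>\n",
    "<h2>Stage 1 \u2014 sentiment per question</h2>\n", svg, "\n",
    "<table><tr><th>Question</th><th>N</th><th>Positive</th><th>Negative</th>",
    "<th>Neutral</th><th>Empty</th></tr>\n", tbl_rows, "</table>\n",
    "<h2>Stage 2/3 \u2014 topics and verbatim answers</h2>\n",
    paste(panels, collapse = "\n"), "\n",
    "<footer>Positive and negative series share one 0\u2013100% radial scale.",
    " Schema version ", report$schema_version, ".</footer>\n",
    "</body></html>\n")
  ok <- tryCatch(writeLines(html, path, useBytes = TRUE),
                 error = function(e) stop("cannot write HTML to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Convenience wrapper tying the stages together: train the sentiment
#' cascade on the annotations, predict labels for every answer, fit
#' per-stratum topic models with coherence-based k selection, and build the
#' three-stage report.
#'
#' @param responses a [response_set()].
#' @param annotated data frame with `text`, `label` for cascade training.
#' @param embeddings an [embedding_table()].
#' @param lexicon optional [frequency_lexicon()].
#' @param k_range candidate topic numbers (default 2:15).
#' @param seed integer seed for the split and the topic models.
#' @param config a [normalizer_config()].
#' @param ... passed to [fit_strata()].
#' @return List with `model`, `eval_a`, `eval_b`, `labels`, `strata`,
#'   `report`.
#' @export
run_pipeline <- function(responses, annotated, embeddings, lexicon = NULL,
                         k_range = 2:15, seed = 1L,
                         config = normalizer_config(), ...) {
  trained <- train_cascade(annotated, split_fraction = 0.8, seed = seed)
  labels <- predict_sentiment(trained$model, responses)
  strata <- fit_strata(responses, labels, embeddings, lexicon = lexicon,
                       config = config, k_range = k_range, seed = seed, ...)
  report <- build_report(responses, labels, strata,
                         manifest = list(seed = seed,
                                         k_range = range(k_range),
                                         backend = trained$model$stage_a$name))
  list(model = trained$model, eval_a = trained$eval_a, eval_b = trained$eval_b,
       labels = labels, strata = strata, report = report)
}
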