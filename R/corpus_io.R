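#' Define a survey schema
#'
#' A schema is the ordered list of open-ended questions on the questionnaire.
#' Question ids are short tokens (e.g. `"Q1"`); the prompt is the question
#' text shown to respondents and `examples` the optional example hints.
#'
#' @param question_id character vector of unique, non-empty question ids.
#' @param prompt character vector of question prompts (recycled if length 1).
#' @param examples optional character vector of example hints.
#' @return A `survey_schema` object (a data frame with one row per question,
#'   order preserved).
#' @examples
#' survey_schema(c("Q1", "Q2"), c("How was the information?", "How was the contact?"))
#' @export
survey_schema <- function(question_id, prompt = "", examples = "") {
  question_id <- as.character(question_id)
  if (length(question_id) == 0) stop("schema needs at least one question")
  if (anyDuplicated(question_id)) stop("duplicate question_id in schema")
  if (any(!nzchar(question_id))) stop("empty question_id in schema")
  out <- data.frame(
    question_id = question_id,
    prompt = rep_len(as.character(prompt), length(question_id)),
    examples = rep_len(as.character(examples), length(question_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("survey_schema", "data.frame")
  out
}

#' Construct a response set
#'
#' Bundles free-text answers with their schema. One row per
#' (respondent, question); answers are stored verbatim — no preprocessing is
#' applied at rest. Whitespace-only answers are flagged empty but retained,
#' so per-question denominators stay fixed.
#'
#' @param respondent_id,question_id,text parallel vectors, one element per answer.
#' @param schema a [survey_schema()].
#' @param source answer provenance, `"digital"` or `"transcribed"`.
#' @return A `response_set`: data frame with columns `respondent_id`,
#'   `question_id`, `text`, `source`, `empty`, and the schema in
#'   `attr(, "schema")`.
#' @export
response_set <- function(respondent_id, question_id, text, schema,
                         source = "digital") {
  stopifnot(inherits(schema, "survey_schema"))
  respondent_id <- as.character(respondent_id)
  question_id <- as.character(question_id)
  text <- as.character(text)
  n <- length(text)
  if (length(respondent_id) != n || length(question_id) != n) {
    stop("respondent_id, question_id and text must have equal length")
  }
  source <- rep_len(as.character(source), n)
  bad_src <- setdiff(unique(source), c("digital", "transcribed"))
  if (length(bad_src)) stop("unknown source value: ", paste(bad_src, collapse = ", "))
  unknown <- !(question_id %in% schema$question_id)
  if (any(unknown)) {
    stop("unknown question_id ", paste(unique(question_id[unknown]), collapse = ", "),
         " (first offending row ", which(unknown)[1], ")")
  }
  key <- paste(respondent_id, question_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (respondent_id, question_id) key: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  }
  text[is.na(text)] <- ""
  out <- data.frame(
    respondent_id = respondent_id, question_id = question_id,
    text = text, source = source,
    empty = !nzchar(trimws(text)),
    stringsAsFactors = FALSE
  )
  attr(out, "schema") <- schema
  class(out) <- c("response_set", "data.frame")
  out
}

#' @export
print.response_set <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("<response_set> %d answers, %d questions, %d respondents (%d empty)\n",
              nrow(x), nrow(sch), length(unique(x$respondent_id)), sum(x$empty)))
  invisible(x)
}

doc_key <- function(respondent_id, question_id) {
  paste(respondent_id, question_id, sep = "::")
}

#' Read questionnaire responses from CSV or JSON
#'
#' CSV files need a header with columns `respondent_id`, `question_id`,
#' `text` and optionally `source`; JSON files hold an array of objects with
#' the same fields. Every `question_id` must exist in the schema and
#' (respondent, question) keys must be unique.
#'
#' @param path path to a UTF-8 CSV or JSON file (dispatch on extension).
#' @param schema a [survey_schema()].
#' @return A [response_set()].
#' @export
load_responses <- function(path, schema) {
  if (!file.exists(path)) stop("cannot read responses file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (is.null(dim(df))) stop("JSON responses must be an array of objects")
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  }
  need <- c("respondent_id", "question_id", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("responses file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  src <- if ("source" %in% names(df)) df$source else "digital"
  response_set(df$respondent_id, df$question_id, df$text, schema, source = src)
}

#' Write responses to CSV
#'
#' Inverse of [load_responses()]: a written file reloads to the same records
#' (text byte-identical).
#'
#' @param responses a [response_set()].
#' @param path output CSV path.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_set"))
  df <- responses[, c("respondent_id", "question_id", "text", "source")]
  class(df) <- "data.frame"
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per word, rownames are the words.
#'   Rows are rescaled to unit L2 norm; zero rows are an error.
#' @return An `embedding_table` with fields `vectors` (unit rows) and `dim`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) stop("duplicate words in embedding table")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) {
    stop("zero-norm embedding vector for word: ",
         rownames(vectors)[which(nrm == 0)[1]])
  }
  out <- list(vectors = vectors / nrm, dim = ncol(vectors))
  class(out) <- "embedding_table"
  out
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read word embeddings in word2vec text format
#'
#' Expects the classic text dialect: a header line `"<vocab_size> <dim>"`
#' followed by one `"<word> <v1> ... <vd>"` line per word. Vectors are
#' unit-normalized on load.
#'
#' @param path path to the embedding file.
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop("cannot read embeddings file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty embeddings file")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed word2vec header line: ", lines[1])
  }
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != n) {
    stop("header declares ", n, " words but file has ", length(body), " vector lines")
  }
  words <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(parts) != d + 1) {
      stop("line ", i + 1, ": expected ", d, " components, found ", length(parts) - 1)
    }
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) stop("line ", i + 1, ": non-numeric vector component")
    words[i] <- parts[1]
    mat[i, ] <- v
  }
  rownames(mat) <- words
  embedding_table(mat)
}

#' Read a word-frequency lexicon
#'
#' Two-column plain text, one `"word count"` pair per line. Words are
#' lowercased on load; counts must be positive integers. The lexicon drives
#' Norvig spelling correction ([correct_spelling()]).
#'
#' @param path path to the lexicon file.
#' @return A `frequency_lexicon`: named integer vector (names are words).
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("cannot read lexicon file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty lexicon file: ", path)
    return(frequency_lexicon(character(), integer()))
  }
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad)) stop("lexicon line ", bad[1], " is not 'word count'")
  words <- vapply(parts, `[[`, "", 1)
  counts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(counts) || any(counts != floor(counts))) {
    stop("non-integer count in lexicon at line ",
         which(is.na(counts) | counts != floor(counts))[1])
  }
  frequency_lexicon(words, as.integer(counts))
}

#' Construct a frequency lexicon from vectors
#'
#' @param words character vector (lowercased on construction).
#' @param counts positive integer counts, parallel to `words`.
#' @return A `frequency_lexicon` object.
#' @export
frequency_lexicon <- function(words, counts) {
  words <- tolower(as.character(words))
  counts <- as.integer(counts)
  stopifnot(length(words) == length(counts))
  if (length(counts) && any(counts < 1L)) stop("lexicon counts must be >= 1")
  if (anyDuplicated(words)) {
    counts <- vapply(split(counts, words), sum, 1L)
    words <- names(counts)
  }
  out <- stats::setNames(counts, words)
  class(out) <- "frequency_lexicon"
  out
}

#' Read matched structured-questionnaire scores
#'
#' Scores from the closed-ended comparison instrument (1–10 scale), matched
#' per respondent and open-ended question. CSV columns: `respondent_id`,
#' `question_id`, `score`; several matched scores per key are allowed.
#'
#' @param path scores CSV path.
#' @param schema a [survey_schema()].
#' @return Data frame with columns `respondent_id`, `question_id`, `score`.
#' @export
load_scores <- function(path, schema) {
  stopifnot(inherits(schema, "survey_schema"))
  if (!file.exists(path)) stop("cannot read scores file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("respondent_id", "question_id", "score")
  if (!all(need %in% names(df))) {
    stop("scores file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) stop("non-numeric score at row ", which(is.na(score))[1])
  out_of_range <- score < 1 | score > 10
  if (any(out_of_range)) {
    stop("score out of [1, 10] at row ", which(out_of_range)[1],
         " (value ", score[which(out_of_range)[1]], ")")
  }
  unknown <- !(df$question_id %in% schema$question_id)
  if (any(unknown)) {
    stop("unknown question_id in scores file: ",
         paste(unique(df$question_id[unknown]), collapse = ", "))
  }
  data.frame(
    respondent_id = as.character(df$respondent_id),
    question_id = as.character(df$question_id),
    score = score, stringsAsFactors = FALSE
  )
}

#' Read a sentiment annotation file
#'
#' CSV columns: `respondent_id`, `question_id`, `label` (one of `negative`,
#' `neutral`, `positive`) and `annotator_id`.
#'
#' @param path annotations CSV path.
#' @param schema a [survey_schema()].
#' @return Data frame of annotations.
#' @export
load_annotations <- function(path, schema) {
  stopifnot(inherits(schema, "survey_schema"))
  if (!file.exists(path)) stop("cannot read annotations file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  need <- c("respondent_id", "question_id", "label", "annotator_id")
  if (!all(need %in% names(df))) {
    stop("annotations file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- !(df$label %in% c("negative", "neutral", "positive"))
  if (any(bad)) stop("invalid sentiment label at row ", which(bad)[1], ": ",
                     df$label[which(bad)[1]])
  unknown <- !(df$question_id %in% schema$question_id)
  if (any(unknown)) {
    stop("unknown question_id in annotations: ",
         paste(unique(df$question_id[unknown]), collapse = ", "))
  }
  df[, need]
}
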