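Package: premtext
Title: Sentiment-Stratified Topic Analysis of Open-Ended Patient Experience Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for free-text answers to open-ended
    patient-reported experience measures (PREMs). Answers are labeled by a
    cascade of two binary sentiment classifiers (negative versus
    non-negative, then positive versus neutral), preprocessed with Norvig
    spelling correction and lemma/stopword/part-of-speech filtering,
    vectorized as TF-IDF weighted 1- to 3-grams, and summarized per question
    and sentiment by non-negative matrix factorization topic models whose
    number of topics is selected by word-embedding coherence. Includes
    validation statistics (stratified representativeness sampling,
    topic-overlap proportion, two-sample comparison of matched numeric
    scores), ground-truthed synthetic corpus and embedding generators, and a
    three-stage hierarchical report exported as JSON and static HTML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
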