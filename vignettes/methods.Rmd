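---
title: "Methods: sentiment-stratified topic analysis of open-ended patient experience surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment-stratified topic analysis of open-ended patient experience surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premtext)
```

## The analysis problem

Closed-ended patient-experience questionnaires (PREMs) are easy to score but
constrain what patients can say; open-ended questions capture what actually
mattered to a patient, at the cost of reading hundreds of free-text answers.
`premtext` automates that reading for short-answer clinical surveys. The
pipeline has four stages:

1. **Sentiment cascade** — every non-empty answer is labeled
   negative / neutral / positive by two binary classifiers run in sequence:
   stage A separates *negative* from *non-negative*; stage B splits the
   non-negatives into *positive* vs *neutral*. The cascade, rather than one
   three-class model, lets each stage specialize, and the first stage —
   finding the rare dissatisfied answers — is the clinically urgent one.
2. **Preprocessing** — tokenization, Norvig spelling correction against a
   frequency lexicon, lemmatization and filtering (stopwords, words shorter
   than three letters, parts of speech other than verbs, adverbs, nouns and
   adjectives), then TF-IDF vectorization of all 1- to 3-grams.
3. **Topic models per stratum** — one non-negative matrix factorization
   (NMF) per (question × sentiment) stratum, neutral answers excluded. The
   number of topics $k$ is chosen per stratum by refitting for
   $k = 2, \dots, 15$ and keeping the model with the highest word-embedding
   coherence. NMF is preferred over LDA because answers are very short
   (median two words).
4. **Report** — a three-stage drill-down: per-question sentiment
   percentages (spider plot), topics with descriptors and counts per
   stratum, and the verbatim answers behind every topic.

## Models and formulas

**TF-IDF dialect.** For term $t$ in document $d$:
$\mathrm{tfidf}(t,d) = \mathrm{tf}(t,d)\cdot\left(\ln\frac{1+N}{1+\mathrm{df}(t)}+1\right)$
with raw counts for tf and $N$ documents; every nonzero document row is then
L2-normalized. The smoothed idf never vanishes, so terms present in every
document keep a small weight. N-grams are formed over the *filtered* token
sequence — gaps left by removed tokens close up, which is the only reading
consistent with filtering before vectorization.

**Spelling correction.** Classic Norvig: a token found in the lexicon is
kept; otherwise the highest-frequency lexicon word reachable by one edit
(deletion, adjacent transposition, substitution, insertion), then by two
edits, wins; otherwise the token is returned unchanged. Frequency ties break
lexicographically so runs are reproducible. Correction is per token and
context-free; a context-sensitive corrector could be substituted behind the
same signature.

**NMF.** $X \approx WH$ with $X$ the docs × terms TF-IDF matrix and $W, H
\ge 0$, minimizing $\|X - WH\|_F$ by Lee–Seung multiplicative updates
(max 400 iterations, relative-change tolerance $10^{-4}$) from an NNDSVDa
initialization. NNDSVDa is deterministic, so a (matrix, $k$) pair always
yields bit-identical factors; the multiplicative updates guarantee a
non-increasing objective, which the tests assert. Zeros in the NNDSVD
initialization are replaced by the matrix mean (the "a" variant) because
multiplicative updates cannot move a weight off an exact zero.

**Coherence and model selection.** Each candidate model is scored by the
mean over topics of the mean pairwise cosine similarity between the
embedded top terms of the topic. Two choices deserve comment:

* *Words, not n-grams.* The top 10 n-grams of a topic are reduced to their
  distinct words before embedding. Scoring the n-grams themselves lets a
  degenerate topic whose top terms are n-gram variants of a single word
  ("waiting", "waiting waiting", …) collect many identical-vector pairs and
  scores near 1; such over-split models then win the selection. Word-level
  scoring matches the intent — semantic similarity of the words within a
  topic — and removes that failure mode. The n-gram variant remains
  available (`coherence_on = "ngrams"`).
* *Two-level mean.* Coherence is averaged per topic, then across topics, so
  each topic contributes equally regardless of how many terms were
  embeddable. The per-topic values and the whole (k, coherence) path are
  kept in the fitted object for audit.

Ties in the selection go to the smallest $k$; the candidate range is
clipped to $\min(\text{docs}, \text{terms})$; strata with fewer than three
non-empty documents are reported as skipped rather than failing the run.

**Topic assignment.** Each document goes to the argmax of its row of $W$;
an all-zero row (typically a document emptied by preprocessing) is
*unassigned* and counted separately. No minimum-weight threshold is applied
by default — the zero-row rule is parameter-free — but a threshold `tau` is
available for stricter assignment.

**Descriptors.** Per topic, the ten highest-weight n-grams are sorted by
word count (longest first), terms whose tokens occur in order within a
longer retained term are dropped (a list never holds both "went very well"
and "went well"), and the first five survivors are shown. In-order rather
than strictly contiguous matching is required for exactly that canonical
example: "went well" skips a word of "went very well".

**Validation statistics.** Review samples per topic take all documents when
the topic has fewer than 10, otherwise $\max(\lceil 0.2\,n\rceil, 10)$,
without replacement. Representativeness rates pool counts
($\sum \text{fits} / \sum \text{judged}$) — not averages of per-topic
rates, which would weight a 3-document topic like a 40-document one.
Topic overlap is the share of distinct manually identified topics matched
(by expert pairing, which is input, not computed) to an automatic topic.
The positive-vs-negative comparison of matched 1–10 structured scores is an
independent-samples t-test, pooled-variance by default with Welch
selectable, accepting raw scores or printed summaries $(n, \mu, \sigma)$;
no multiple-testing correction is applied across questions, and that fact
is recorded in the output.

## The classifier backend

The shipped backend is deliberately light: TF-IDF unigram+bigram features
into a ridge-penalized logistic regression (glmnet, $\lambda = 0.001$),
with inverse-class-frequency observation weights. The weighting matters:
positive answers outnumber neutral ones roughly four to one in this data
regime, and an unweighted fit pushes single-token neutral answers to the
majority class through the intercept alone (neutral recall 0.24 vs 0.84
weighted, on held-out synthetic data). The cascade itself is
backend-agnostic — any object implementing `backend_fit()` /
`backend_predict()` deterministically under a seed satisfies the contract,
so a fine-tuned transformer can replace the default without touching the
surrounding pipeline. Empty answers are never classified: they are labeled
neutral by convention and excluded from training, keeping per-question
denominators fixed in the report.

The 80/20 train/validation split is seed-controlled and the seed is a
required, logged parameter. Stage B trains only on gold non-negative
answers, mirroring what it sees at inference time downstream of stage A.

## What the synthetic generator emulates — and what it does not

`corpus_spec()` encodes the data regime of a short-answer clinical survey:

* **Length** — a discretized log-normal, $\min(\max(1,
  \text{round}(e^{Z})), 192)$ with $Z \sim N(\log 2.2, 2.4^2)$, reproducing
  the observed summary: median 2 tokens, interquartile range [1, 11],
  maximum 192.
* **Sentiment mix** — per-question proportions over positive / negative /
  neutral / empty; the default (67/5/18/10%) mirrors a strongly satisfied
  patient population where negative answers are rare.
* **Planted topics** — per (question × sentiment) stratum, `k` disjoint
  topic lexicons of 10 words each. Every non-empty positive or negative
  answer starts with a word of its planted topic, then mixes topic words,
  sentiment markers and noise words at rates 0.5 / 0.3 / 0.2. The lexicon
  size equals the 10-term window used by coherence, so a pure factor fills
  its window exactly, a split factor pads it with unrelated words, and a
  merged factor mixes two lexicons — all three mistakes are visible to the
  selection criterion.
* **Vocabulary geometry** — synthetic words are constructed at pairwise
  edit distance ≥ 2, as in a natural vocabulary, so a single-character typo
  never lands on another valid word.
* **Embeddings** — group-structured random vectors with expected
  within-lexicon cosine 0.8. For corpus-matched embeddings the background
  cosine between unrelated words defaults to 0.25 rather than 0, mimicking
  the anisotropy of trained word2vec spaces; with exactly orthogonal
  unrelated words, a topic contaminated by markers is indistinguishable in
  coherence from a genuinely merged topic, which no real embedding space
  exhibits.
* **Injected noise** — `corrupt_spelling()` applies single-character edits
  at a configurable per-token rate with a full typo log;
  `generate_scores()` emits 1–10 scores shifted by sentiment (means
  9.7 / 9.0 / 8.1, sd 0.9 / 1.2 / 2.4) for exercising the score
  comparison.

All randomness flows from one spec seed through named substreams
(sentiment, topic, length, tokens, typo), so components are individually
reproducible.

The generator deliberately has **no linguistic realism**: no grammar, no
morphology, no code-switching, no correlation between answer length and
sentiment, and topic lexicons are disjoint (an overlap knob would make
recovery ill-defined as ground truth). Passing the recovery benchmarks
therefore shows that the machinery — cascade, vectorizer, NMF, coherence
selection, bookkeeping — behaves correctly under a known truth; it does not
show that a bag-of-words backend matches a fine-tuned language model on
real clinical text, nor that coherence selection finds "the right" k when
real topics overlap and nest.

## Benchmark scale and numerical choices

The planted-structure benchmark uses one question, 470 respondents with a
balanced positive/negative mix (about 200 non-empty documents per stratum),
4 planted topics, and 10 corpus seeds; the recovery experiments in the test
suite and the acceptance script run at exactly this scale. On it, the modal
selected k equals the planted 4, mean assignment purity is ≈ 0.9, and the
cascade's three-class macro-F1 on a freshly generated corpus is ≈ 0.95.

Other numerical conventions: displayed percentages round half-up to one
decimal with raw counts always carried alongside; argmax ties in topic
assignment take the lowest index; coherence of a topic with fewer than two
embeddable terms is 0 with a warning; a zero-variance two-sample comparison
with equal means reports $t = 0, p = 1$; NMF on an all-zero matrix returns
zero factors with zero residual.

## Known limitations

* Sentiment is assigned per answer, not per sentence; an answer mixing
  praise and complaint gets one label (negative dominates by construction
  of the cascade).
* The spelling corrector is context-free and lexicon-driven; it will not
  fix a typo that happens to be another valid word.
* The identity lemmatizer default means inflected forms count as distinct
  words unless a rule-list or external tagger plugin is supplied.
* Coherence-based selection inherits the embedding table's notion of
  similarity; out-of-vocabulary top terms are silently skipped (logged as
  fewer embeddable terms).
* The t-test on matched structured scores treats scores as interval data
  and applies no multiple-testing correction across questions.
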