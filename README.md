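# premtext

Automated analysis of free-text answers to open-ended patient-reported
experience measures (PREMs).

Hospitals increasingly ask patients *"How was the provided information?"*
instead of *"Rate the information from 1 to 10"* — open answers say what
actually mattered, but somebody has to read hundreds of them. `premtext`
turns a table of (respondent, question, answer) records into a three-stage
drill-down report a care team can act on:

1. **sentiment per question** — every non-empty answer is labeled
   negative / neutral / positive by a *cascade* of two binary classifiers
   (negative vs non-negative, then positive vs neutral on the
   non-negatives), and each question gets its positive/negative
   percentages on a spider plot;
2. **topics per (question × sentiment)** — answers are spell-corrected
   (Norvig), filtered, vectorized as TF-IDF 1–3-grams, and factorized with
   non-negative matrix factorization; the number of topics *k* ∈ 2…15 is
   selected per stratum by word-embedding coherence (mean pairwise cosine
   of each topic's top words), and each topic is summarized by at most five
   deduplicated, longest-first n-gram descriptors with document counts;
3. **verbatim answers per topic** — the original texts, one click below.

Core model: per stratum, the docs × terms TF-IDF matrix X is factorized as
X ≈ WH with W, H ≥ 0 (Lee–Seung multiplicative updates from a
deterministic NNDSVDa start); documents go to `argmax` of their row of W,
all-zero rows are reported *unassigned*; candidate models k = 2…15 are
ranked by coherence(k) = mean over topics of mean pairwise
cos(v<sub>i</sub>, v<sub>j</sub>) over the embedded top-10 words of the
topic.

The package also ships the validation toolkit used to audit such a
pipeline (stratified review-sampling plans — 20% per topic, minimum 10;
pooled representativeness rates; manual/automatic topic-overlap
proportion; pooled or Welch t-tests on matched 1–10 scores, from raw data
or printed summaries) and a fully ground-truthed synthetic corpus +
embedding generator, so every stage is testable offline.

## Worked example

```r
library(premtext)

# a ground-truthed synthetic survey: 150 respondents x 5 questions
spec   <- corpus_spec(n_respondents = 150, seed = 11)
corpus <- generate_corpus(spec)
corpus$responses
#> <response_set> 750 answers, 5 questions, 150 respondents (83 empty)

annotated <- with(corpus, data.frame(
  text  = responses$text,
  label = ifelse(truth$sentiment == "empty", "neutral", truth$sentiment)))
annotated <- annotated[nzchar(trimws(annotated$text)), ]

res <- run_pipeline(corpus$responses, annotated,
                    embeddings_for_corpus(spec),
                    lexicon = lexicon_for_corpus(spec),
                    k_range = 2:6, seed = 11)
res$report
#> <prem_report> stage 1 (sentiment per question):
#>  question_id n_total n_positive n_negative pct_positive pct_negative
#>           Q1     150        108          4         72.0          2.7
#>           Q2     150         95          8         63.3          5.3
#>           Q3     150        100          5         66.7          3.3
#>           Q4     150        100          9         66.7          6.0
#>           Q5     150         98          9         65.3          6.0
#> stage 2: 10 strata with topic models
```

Percentages use all respondents who received the question (including
neutral and empty answers) as denominator, so 108/150 = 72.0%. Stage 2
holds one topic model per stratum; for the positive answers to Q1 the
selection picked k = 4 (the planted number), coherence 0.75, and its
largest topic covers 46 documents described by five planted-lexicon words:

```r
res$report$stage2[["Q1.positive"]]$topics[[1]]
#> $topic       : 1
#> $descriptors : "topaappaagg" "topaappaahh" "topaappaadd" "topaappaaff" "topaappaajj"
#> $count       : 46
```

(Synthetic "words" encode their planted topic; on real data these are the
patient's own n-grams.) Export for sharing:

```r
export_json(res$report, "report.json")   # lossless, schema-versioned
render_html(res$report, "report.html")   # static page: spider plot + drill-down
```

Validation statistics work from printed summaries too — here the matched
structured scores of positive vs negative answers to one question
(n = 359, 9.7 ± 0.9 vs n = 26, 8.1 ± 2.4):

```r
compare_groups(list(n = 359, mean = 9.7, sd = 0.9),
               list(n = 26,  mean = 8.1, sd = 2.4))
#> <group_comparison> pos 359 (9.70 +/- 0.90) vs neg 26 (8.10 +/- 2.40):
#>   t = 7.401, df = 383.00, p = 8.65e-13 [pooled]
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","premtext.R",package="premtext"))')" \
  simulate --seed 7 --out demo/
# then: analyze --responses demo/responses.csv --annotations demo/annotations.csv \
#       --embeddings demo/embeddings.txt --lexicon demo/lexicon.txt --out out/
```

Subcommands: `simulate`, `train-sentiment`, `analyze`, `validate`,
`report`. Every run writes a `manifest.json` with options, seeds and the
package version.

## Package layout

| module | contents |
|---|---|
| `R/corpus_io.R` | schema/response/score/annotation/lexicon/embedding types and readers |
| `R/sentiment.R` | classifier-backend contract, cascade training/prediction, metrics, agreement |
| `R/text_prep.R` | tokenizer, Norvig corrector, normalizer plugins, TF-IDF vector space |
| `R/topic_model.R` | NMF, coherence, k-selection, assignment, descriptors, per-stratum driver |
| `R/validation.R` | sampling plans, representativeness, topic overlap, score comparisons |
| `R/synthetic.R` | corpus / embedding / typo / score generators with ground truth |
| `R/report.R` | three-stage report, JSON round-trip, static HTML |
| `inst/cli/premtext.R` | command-line entry point |

See `vignettes/methods.Rmd` for the full model description, parameter
defaults and their rationale, and known limitations.
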