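# mrim

Hybrid machine-learning + rule-based triage of emergency microblogs.

During a disaster, microblogging platforms fill with short posts, only a
minority of which can directly support rescue work — an exact address, a
phone number, a concrete need. `mrim` classifies such posts as *useful* or
*useless* for rescue by combining two arms that err differently:

* **A text classifier.** TF-IDF over a unigram vocabulary (terms with total
  frequency ≥ 3), with the weights

  tf(i,j) = n(i,j) / Σₖ n(k,j),  idf(i) = log₁₀( |D| / (1 + df(i)) ),
  tfidf = tf × idf,

  applied literally (no length normalization; ubiquitous terms get slightly
  negative idf), feeding a linear maximum-margin classifier (libsvm via
  `e1071`, unit cost) evaluated by stratified ten-fold cross-validation with
  per-fold vocabularies. A useful verdict scores 100, useless 0.

* **An expert-rule scorer.** Six weighted judgment dimensions — attention
  (likes, comments, shares; each `min(x/10, 33.3)`), author history (prior
  posts, followers, fans; each `min(x/100, 33.3)`), sentiment magnitude,
  word count, exact-address flag, contact flag — weighted
  0.20/0.10/0.05/0.05/0.20/0.40 and summed; a post is useful when the total
  reaches the boundary score 40 (inclusive). Sentiment comes from a
  lexicon traversal with degree-adverb multipliers and negation sign flips;
  addresses are detected by a five-level feature-word suffix inventory;
  contacts by phone-shaped patterns.

* **Integration.** The union rule — useless only if *both* arms say useless
  — which can only raise recall; plus a weighted blend
  `(1−w)·svm + w·rule ≥ 40` with a sweep over a 0.01 grid of `w`.

Because the kind of corpus this method targets is generally not
redistributable, the package also ships a calibrated synthetic-corpus
generator (`generate_corpus()`, `default_study_profile()`) that reproduces
the statistical shape of a labelled disaster corpus — 7979 posts, 24.3%
useful, address/contact strata 5461:1202:331:985, heavy-tailed engagement
counts, corrupted addresses, high-attention useless media reports — so the
entire pipeline is testable end to end.

## Worked example

```r
library(mrim)
res <- run_pipeline(spec = generator_spec(n = 1500, token_signal = 0.8,
                                          seed = 42),
                    k = 5, sweep = TRUE)
print(res$overall, digits = 3)
#> # A tibble: 3 × 4
#>   method precision recall f_measure
#>   <chr>      <dbl>  <dbl>     <dbl>
#> 1 svm        0.711  0.306     0.428
#> 2 rule       0.247  0.870     0.385
#> 3 mrim       0.264  0.960     0.414
cat("best w:", attr(res$sweep, "best_w"),
    " F at best w:", round(max(res$sweep$f_measure), 3), "\n")
#> best w: 0.61  F at best w: 0.537
```

The pattern to read off: the text arm is precision-heavy and recall-poor
(0.71 / 0.31 — it only trusts strong vocabulary evidence), the rule arm is
the opposite (a contact number alone crosses the boundary, so it flags most
contact-bearing posts and recall reaches 0.87), and the union keeps almost
every useful post (recall 0.96) at the rule arm's precision. Per-group
tables (`res$by_word_count`, `res$by_address_contact`,
`res$by_attention`) show F rising with word count for both arms — short
posts simply carry too little evidence.

A thin CLI covers the same operations file-to-file:

```sh
exec/mrim generate --n 2000 --seed 1 -o corpus.csv --truth truth.csv
exec/mrim validate corpus.csv
exec/mrim extract corpus.csv -o features.csv
exec/mrim rule-score corpus.csv -o scores.csv
exec/mrim cv corpus.csv --folds 10 --seed 1 -o folds.csv
```

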