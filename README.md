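# adrdist

Distance-based filtering of adverse-drug-reaction (ADR) mentions in patient
forum posts.

## The problem

Forum posts that mention both a drug and a disorder are the raw material of
social-media pharmacovigilance — but most such co-occurrences are not
adverse reactions. The disorder is often the indication ("I had a headache
so I took aspirin"), a comorbidity, or someone else's experience; in
annotated forum samples only ~11% of (drug, disorder) pairs are genuine
ADRs. `adrdist` implements a lightweight statistical pre-filter for this
false-positive burden that uses nothing but *where* the two mentions sit in
the text.

## The method

For a drug mention *a* and disorder mention *b* with 1-based token
positions, the signed word distance is

```
distance(a, b) = pos(b) − pos(a)
```

(negative when the disorder precedes the drug; punctuation marks count as
words and stop words are never removed). Distances are pooled over the
corpus and modelled as a univariate Gaussian mixture

```
f(x) = Σₖ πₖ φ(x; μₖ, σₖ²),   K = 3,
```

fitted by expectation-maximization (deterministic quantile initialization,
log-sum-exp likelihoods, variance floor). Each pair is assigned to the
component maximizing πₖ φ(x; μₖ, σₖ²). Because the components share similar
means but very different spreads, the assignment regions form nested
interval unions: a tight inner cluster around the drug name, a mid-range
cluster flanking it, and the far tails. ADRs concentrate in the tight
cluster, so removing the outer clusters discards mostly non-ADRs.

Reported scores use the false-positive-removal convention: the positive
class is the *removed non-ADR* pair, so precision is the purity of what was
filtered out and recall (= the reduction rate) is the fraction of all
non-ADRs removed.

The package provides the full pipeline: preprocessing and tokenization with
positions, MedDRA-style disorder lexicon and drug-list loading, stemmed and
fuzzy-keyed dictionary NER, pair construction with minimum-|distance|
deduplication, EM fitting, exact MAP decision-boundary intervals,
cluster-merge filtering with precision/recall evaluation, and a synthetic
forum-corpus generator with planted ground truth (real annotated corpora in
this domain are proprietary).

## Worked example

```r
library(adrdist)

# lexicons (synthetic fixtures shipped with the package; real MedDRA-derived
# tables are user-supplied CSVs with the same schema)
lex   <- load_disorder_lexicon(system.file("extdata", "disorder_lexicon_synthetic.csv", package = "adrdist"))
drugs <- load_drug_list(system.file("extdata", "drugs_synthetic.csv", package = "adrdist"))
dix   <- build_index(drugs, mode = "fuzzy")
xix   <- build_index(lex, mode = "exact-stemmed")

# one message, misspelled drug included
ts <- preprocess_text("hier j'ai pris du zolpidme et depuis un mal de tête terrible")[[1]]
m  <- recognize_entities(ts, dix, xix, "m1")
enumerate_pairs(m, length(ts$tokens))[, c("drug_name", "llt_label", "distance", "relative_position")]
#>   drug_name   llt_label distance relative_position
#> 1  zolpidem mal de tête        4             after
```

The drug is recognized despite the transposed letters (fuzzy-key matching of
stems), the three-token disorder is matched after stemming, and the signed
distance is 4 words.

Filtering metrics from the packaged reference contingency table
(3 clusters × {non-ADR, ADR}; 1654 pairs of which 189 ADRs):

```r
tab <- read_contingency_csv(system.file("extdata", "table1_contingency.csv", package = "adrdist"))
apply_strategy(tab, c(1, 3), name = "strategy1")   # keep only the tight cluster
#> <filter strategy strategy1>
#>   removed: 733 non-ADR + 32 ADR; kept: 732 non-ADR + 157 ADR
#>   precision 95.8170%  recall/reduction 50.0341%  ADR coverage of kept 83.0688%
apply_strategy(tab, 3, name = "strategy2")         # drop only the far cluster
#> <filter strategy strategy2>
#>   removed: 321 non-ADR + 3 ADR; kept: 1144 non-ADR + 186 ADR
#>   precision 99.0741%  recall/reduction 21.9113%  ADR coverage of kept 98.4127%
```

Strategy 1 halves the false-positive burden at 95.8% filtering precision;
strategy 2 removes a fifth of it at 99.07% precision while keeping 98.4% of
true ADRs.

End to end on a synthetic corpus:

```r
sim <- generate_corpus(sim_config(n_messages = 400, seed = 1))
dir.create(d <- tempfile()); write_corpus_jsonl(sim$messages, file.path(d, "corpus.jsonl"))
write_gold_csv(sim$gold, file.path(d, "gold.csv"))
res <- run_pipeline(pipeline_config(
  corpus = file.path(d, "corpus.jsonl"), gold = file.path(d, "gold.csv"),
  disorders = system.file("extdata", "disorder_lexicon_synthetic.csv", package = "adrdist"),
  drugs = system.file("extdata", "drugs_synthetic.csv", package = "adrdist"),
  out_dir = file.path(d, "out"), seed = 1, strategy = 1))
res$fit$model
#> <Gaussian mixture, K=3 (components in ascending sd)>
#>  cluster weight     mean      sd
#>        1 0.6261   -0.541  69.245
#>        2 0.2283 -229.038 346.838
#>        3 0.1456  311.592 405.075
res$report
#> <filter strategy strategy1>
#>   removed: 265 non-ADR + 0 ADR; kept: 559 non-ADR + 126 ADR
#>   precision 100.0000%  recall/reduction 32.1602%  ADR coverage of kept 100.0000%
```

On this clean synthetic corpus every planted ADR lands in the tightest
cluster, so removing the two wide clusters cuts 32% of the false-positive
pairs at 100% filtering precision. (Note the two wide components split the
far tail by sign here — a perfectly valid mixture solution; the tight
component around zero is what the filter relies on.)

A command-line wrapper with `preprocess`, `ner`, `pairs`, `fit`, `assign`,
`regions`, `evaluate`, `simulate` and `run` subcommands is installed at
`system.file("cli", "adrdist.R", package = "adrdist")`.

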