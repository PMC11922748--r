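# etymolex

Quantifying speech formality through word etymology, for clinical speech
research.

English splits into a Germanic-origin core ("ask", "smart") and a layer of
words that entered via Old French after 1066 ("inquire", "intelligent").
Speakers reach for the Old-French layer to convey formality, so the share of
a speaker's content words drawn from each layer indexes the formality of
their speech — a quantity of interest in psychosis research, where
communication differences track role functioning. `etymolex` implements this
measurement for interview transcripts:

* **Etymology proportions.** Content words (nouns, verbs, adjectives,
  adverbs) are lemmatized and classified against an etymology lexicon into
  exclusively-Germanic, exclusively-Old-French, mixed (BOTH), NEITHER or
  UNKNOWN classes. The reported proportions are
  `p_G = n_Germanic / n_content` and `p_OF = n_OldFrench / n_content`, with
  all content tokens in the denominator.
* **Honoré's statistic** of lexical diversity on the whole lemmatized text:
  `R = 100·log(N) / (1 − V₁/V)` with N tokens, V types, V₁ hapaxes.
* **First-order (unigram) perplexity** of the content lemmas against a
  reference frequency table: `Π = exp(−(1/n)·Σ log wᵢ)` with `wᵢ` the
  corpus probability of lemma i.
* **HC-anchored covariate adjustment**: sequential tests (sex, age, site,
  education, race, maternal education, IQ) with adjustments fitted on the
  healthy-comparison cohort only — median offsets for categorical
  covariates, OLS residualization for continuous ones — plus an audit log.
* **Group statistics**: one-way ANOVA with pairwise pooled t tests, Pearson
  correlation matrices, standardized multiple regression, Spearman clinical
  correlations, Bonferroni control.
* **A seeded synthetic-data generator** producing lexicons, Zipfian
  frequency tables, speaker-labelled transcripts and participant metadata
  with known ground truth, so every stage is testable without restricted
  clinical data.

## Worked example

```r
library(etymolex)

lex <- etymology_lexicon(list(
  ask       = "Old English",
  inquire   = "Old French",
  talkative = c("Old English", "Old French"),
  karaoke   = "Japanese",
  dog       = "Old English",
  run       = "Old English",
  week      = "Old English",
  busy      = "Old English",
  quickly   = "Old English"))
classify_lemma(lex, c("ask", "inquire", "talkative", "karaoke", "zzz"))
#> [1] "GERMANIC_ONLY"   "OLD_FRENCH_ONLY" "BOTH"            "NEITHER"
#> [5] "UNKNOWN"

t <- raw_transcript("demo", data.frame(
  speaker = c("interviewer", "participant", "participant"),
  text = c("How have things been going?",
           "Busy week! The dogs ran quickly.",
           "I won't inquire why the dog ran.")))
pp <- preprocess_transcript(t)
pp$tokens$lemma
#>  [1] "busy"    "week"    "the"     "dog"     "run"     "quickly" "i"
#>  [8] "wont"    "inquire" "why"     "the"     "dog"     "run"

ft <- frequency_table(c(busy = 300, week = 1500, dog = 2000, run = 3000,
                        quickly = 400, inquire = 50), total = 1e6)
lexical_profile(pp$tokens, lex, ft, transcript_id = "demo")
#>   transcript_id n_tokens n_content p_germanic p_old_french n_both n_neither
#> 1          demo       13         8      0.875        0.125      0         0
#>   n_unknown honore_R perplexity mean_log_prob n_scored oov_count
#> 1         0 854.9831   1151.282     -7.048632        8         0
```

Seven of the eight content tokens (busy, week, and dog/run/quickly with
repeats counted per token) are exclusively Germanic and one (inquire)
exclusively Old French, giving proportions 0.875 and 0.125. Honoré's R of
855 reflects a short text in which most lemmas occur once; the perplexity
of 1151 is the inverse geometric mean of the eight content lemmas' corpus
probabilities (all are rare in this toy frequency table).

A full synthetic study, end to end:

```r
sim  <- generate_cohort(generator_spec(), seed = 1)   # 164 HC / 134 CHR / 86 ROP
prof <- cohort_profiles(sim)
res  <- run_compare(prof, sim$participants)
res$comparisons$p_germanic
#> <group_comparison> p_germanic: F(2, 381) = 21.130, p = 1.984e-09
#>  group1 group2          t  df            p
#>      HC    CHR -5.9689082 296 6.820475e-09
#>      HC    ROP -4.6600939 248 5.162261e-06
#>     CHR    ROP  0.5528044 218 5.809637e-01
```

The clinical cohorts use significantly more Germanic-origin words than the
healthy comparison cohort after covariate adjustment, and do not differ
from each other — the generator's built-in ground truth, recovered by the
pipeline.

There is a thin command-line wrapper in `inst/cli/etymolex.R` with
`profile`, `compare` and `simulate` subcommands.

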